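# Hermetic fixture simulator: builds a reference, a donor haplotype pair
# with implanted SVs of known genotype, samples long reads with
# substitution errors, and synthesizes the alignments directly from the
# known donor->reference block map (split records carry SA tags). No
# external aligner is involved, so fixtures are exact and deterministic.

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulation configuration
#'
#' Defaults describe a HiFi-like experiment: 10 kb reads at 30-fold
#' coverage with 0.2% substitution errors and no indel errors (so CIGAR
#' truth stays crisp).
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param ref_length Reference contig length per locus, bases.
#' @param depth Total fold coverage (split evenly across the two
#'   haplotypes).
#' @param read_length Read length, bases.
#' @param sv_specs data.frame with columns `type`
#'   (`DEL`/`INS`/`DUP`/`INV`/`TRA`), `pos` (0-based), `length`,
#'   `genotype` (`"0/1"` or `"1/1"`); for `TRA`, `pos` is the junction on
#'   the first arm and `length` is ignored.
#' @param error_rate Per-base substitution probability.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, ref_length = 30000, depth = 30,
                       read_length = 10000, sv_specs = NULL,
                       error_rate = 0.002) {
  if (is.null(sv_specs)) {
    sv_specs <- data.frame(type = "DEL", pos = floor(ref_length / 2) - 250,
                           length = 500, genotype = "0/1",
                           stringsAsFactors = FALSE)
  }
  stopifnot(depth > 0, read_length > 0, ref_length > 0,
            all(sv_specs$genotype %in% c("0/1", "1/1")),
            all(sv_specs$type %in% c("DEL", "INS", "DUP", "INV", "TRA")))
  ok <- sv_specs$type == "TRA" |
    (sv_specs$pos >= 0 & sv_specs$pos + sv_specs$length <= ref_length)
  if (!all(ok)) stop("SV positions/lengths must lie inside the reference")
  if (nrow(sv_specs) > 1L) {
    iv <- sv_specs[order(sv_specs$pos), ]
    if (any(iv$pos[-1] < (iv$pos + pmax(iv$length, 1))[-nrow(iv)])) {
      stop("SVs must not overlap one another")
    }
  }
  structure(list(seed = seed, ref_length = ref_length, depth = depth,
                 read_length = read_length, sv_specs = sv_specs,
                 error_rate = error_rate),
            class = "sim_config")
}

# ---- donor haplotype construction -----------------------------------------
# A haplotype is a list of donor contigs; each contig is
# list(seq = string, blocks = data.frame(d_start, d_end, chrom, r_start,
# r_end, strand)) where chrom = NA marks inserted (unmapped) sequence.
# Donor and reference coordinates are 0-based half-open.

.identity_hap <- function(refs) {
  lapply(refs, function(s) {
    n <- nchar(s)
    list(seq = s, blocks = data.frame(
      d_start = 0, d_end = n, chrom = NA_character_, r_start = 0, r_end = n,
      strand = "+", stringsAsFactors = FALSE))
  })
}

.substr0 <- function(s, from, to) substr(s, from + 1L, to)  # 0-based half-open

# variant haplotype of one contig carrying non-TRA SVs
.variant_contig <- function(chrom, refseq, svs) {
  G <- nchar(refseq)
  svs <- svs[order(svs$pos), , drop = FALSE]
  pieces <- character(); blocks <- list()
  cur_ref <- 0; cur_d <- 0
  emit <- function(seq, r_start, r_end, strand) {
    pieces[[length(pieces) + 1L]] <<- seq
    blocks[[length(blocks) + 1L]] <<- data.frame(
      d_start = cur_d, d_end = cur_d + nchar(seq),
      chrom = if (is.na(r_start)) NA_character_ else chrom,
      r_start = if (is.na(r_start)) NA_real_ else r_start,
      r_end = if (is.na(r_start)) NA_real_ else r_end,
      strand = strand, stringsAsFactors = FALSE)
    cur_d <<- cur_d + nchar(seq)
  }
  for (i in seq_len(nrow(svs))) {
    s <- svs$pos[i]; l <- svs$length[i]; ty <- svs$type[i]
    if (ty == "DEL") {
      if (s > cur_ref) emit(.substr0(refseq, cur_ref, s), cur_ref, s, "+")
      cur_ref <- s + l
    } else if (ty == "INS") {
      if (s > cur_ref) emit(.substr0(refseq, cur_ref, s), cur_ref, s, "+")
      emit(.random_dna(l), NA, NA, "+")
      cur_ref <- s
    } else if (ty == "INV") {
      if (s > cur_ref) emit(.substr0(refseq, cur_ref, s), cur_ref, s, "+")
      emit(.revcomp(.substr0(refseq, s, s + l)), s, s + l, "-")
      cur_ref <- s + l
    } else if (ty == "DUP") {
      # first copy stays in the leading reference block
      if (s + l > cur_ref) emit(.substr0(refseq, cur_ref, s + l), cur_ref, s + l, "+")
      emit(.substr0(refseq, s, s + l), s, s + l, "+")
      cur_ref <- s + l
    }
  }
  if (G > cur_ref) emit(.substr0(refseq, cur_ref, G), cur_ref, G, "+")
  list(seq = paste(pieces, collapse = ""), blocks = do.call(rbind, blocks))
}

# balanced-translocation variant haplotype over two arms A and B
.tra_contigs <- function(chromA, seqA, posA, chromB, seqB, posB) {
  t1 <- list(seq = paste0(.substr0(seqA, 0, posA), .substr0(seqB, posB, nchar(seqB))),
             blocks = rbind(
               data.frame(d_start = 0, d_end = posA, chrom = chromA,
                          r_start = 0, r_end = posA, strand = "+",
                          stringsAsFactors = FALSE),
               data.frame(d_start = posA, d_end = posA + nchar(seqB) - posB,
                          chrom = chromB, r_start = posB, r_end = nchar(seqB),
                          strand = "+", stringsAsFactors = FALSE)))
  t2 <- list(seq = paste0(.substr0(seqB, 0, posB), .substr0(seqA, posA, nchar(seqA))),
             blocks = rbind(
               data.frame(d_start = 0, d_end = posB, chrom = chromB,
                          r_start = 0, r_end = posB, strand = "+",
                          stringsAsFactors = FALSE),
               data.frame(d_start = posB, d_end = posB + nchar(seqA) - posA,
                          chrom = chromA, r_start = posA, r_end = nchar(seqA),
                          strand = "+", stringsAsFactors = FALSE)))
  list(t1 = t1, t2 = t2)
}

# fix identity-hap block chroms (NA placeholder above)
.set_block_chrom <- function(hap) {
  for (nm in names(hap)) hap[[nm]]$blocks$chrom <- nm
  hap
}

# ---- read sampling and alignment synthesis --------------------------------

# intersect a donor read interval [a, b) with the contig's block map
.read_pieces <- function(blocks, a, b) {
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    x <- max(a, blocks$d_start[i]); y <- min(b, blocks$d_end[i])
    if (y <= x) next
    bl <- blocks[i, ]
    if (is.na(bl$chrom)) {
      out[[length(out) + 1L]] <- list(q_start = x - a, q_end = y - a,
                                      chrom = NA_character_)
    } else if (bl$strand == "+") {
      off <- x - bl$d_start
      out[[length(out) + 1L]] <- list(
        q_start = x - a, q_end = y - a, chrom = bl$chrom,
        r_start = bl$r_start + off, r_end = bl$r_start + off + (y - x),
        strand = "+")
    } else {
      out[[length(out) + 1L]] <- list(
        q_start = x - a, q_end = y - a, chrom = bl$chrom,
        r_start = bl$r_end - (y - bl$d_start),
        r_end = bl$r_end - (x - bl$d_start),
        strand = "-")
    }
  }
  out
}

# group pieces into alignment segments; ops are kept in READ orientation.
# Forward pieces on one chromosome merge across non-negative reference
# gaps (D ops) and across inserted sequence (I ops); any other transition
# (strand flip, chromosome change, reference re-visit) breaks the
# alignment into a new segment, exactly as an aligner would split it.
.pieces_to_segments <- function(pieces, min_piece = 20L) {
  segs <- list(); cur <- NULL; pending_ins <- 0L
  flush <- function() {
    if (!is.null(cur) && sum(vapply(cur$ops, function(o) {
      if (o[[1]] == "M") as.numeric(o[[2]]) else 0
    }, 0)) >= min_piece) {
      segs[[length(segs) + 1L]] <<- cur
    }
    cur <<- NULL
  }
  for (p in pieces) {
    if (is.na(p$chrom)) { pending_ins <- pending_ins + (p$q_end - p$q_start); next }
    if (!is.null(cur) && cur$chrom == p$chrom && cur$strand == "+" &&
        p$strand == "+" && p$r_start >= cur$r_end) {
      if (pending_ins > 0L) {
        cur$ops[[length(cur$ops) + 1L]] <- list("I", pending_ins)
        cur$q_end <- cur$q_end + pending_ins
      }
      gap <- p$r_start - cur$r_end
      if (gap > 0) cur$ops[[length(cur$ops) + 1L]] <- list("D", gap)
      cur$ops[[length(cur$ops) + 1L]] <- list("M", p$q_end - p$q_start)
      cur$r_end <- p$r_end
      cur$q_end <- p$q_end
    } else {
      flush()
      cur <- list(chrom = p$chrom, strand = p$strand,
                  r_start = p$r_start, r_end = p$r_end,
                  q_start = p$q_start, q_end = p$q_end,
                  ops = list(list("M", p$q_end - p$q_start)))
    }
    pending_ins <- 0L
  }
  flush()
  segs
}

# mirror a segment list to the opposite sequencing strand of the read
.flip_segments <- function(segs, read_length) {
  lapply(segs, function(s) {
    list(chrom = s$chrom, strand = if (s$strand == "+") "-" else "+",
         r_start = s$r_start, r_end = s$r_end,
         q_start = read_length - s$q_end, q_end = read_length - s$q_start,
         ops = rev(s$ops))
  })
}

.ops_string <- function(ops) {
  paste(vapply(ops, function(o) paste0(o[[2]], o[[1]]), ""), collapse = "")
}

# record-orientation CIGAR, SEQ and NM for one segment of one read
.emit_record_parts <- function(seg, read, refs) {
  RL <- nchar(read)
  if (seg$strand == "+") {
    left <- seg$q_start; right <- RL - seg$q_end
    ops <- seg$ops
    seq <- read
  } else {
    left <- RL - seg$q_end; right <- seg$q_start
    ops <- rev(seg$ops)
    seq <- .revcomp(read)
  }
  cigar <- paste0(if (left > 0) paste0(left, "S") else "",
                  .ops_string(ops),
                  if (right > 0) paste0(right, "S") else "")
  nm <- 0L
  q <- left; r <- seg$r_start
  refseq <- refs[[seg$chrom]]
  for (o in ops) {
    len <- as.numeric(o[[2]])
    if (o[[1]] == "M") {
      a <- utf8ToInt(.substr0(seq, q, q + len))
      b <- utf8ToInt(.substr0(refseq, r, r + len))
      nm <- nm + sum(a != b)
      q <- q + len; r <- r + len
    } else if (o[[1]] == "D") {
      nm <- nm + len; r <- r + len
    } else if (o[[1]] == "I") {
      nm <- nm + len; q <- q + len
    }
  }
  list(cigar = cigar, seq = seq, nm = nm)
}

.apply_errors <- function(read, error_rate) {
  n <- nchar(read)
  k <- stats::rbinom(1L, n, error_rate)
  if (!k) return(read)
  pos <- sample.int(n, k)
  for (p in pos) {
    old <- substr(read, p, p)
    substr(read, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
  read
}

# synthesize all SAM records of one read; returns a data.frame
.read_records <- function(read_name, read, segs, refs, mapq = 60L) {
  if (!length(segs)) return(NULL)
  parts <- lapply(segs, .emit_record_parts, read = read, refs = refs)
  msum <- vapply(segs, function(s) {
    sum(vapply(s$ops, function(o) if (o[[1]] == "M") as.numeric(o[[2]]) else 0, 0))
  }, 0)
  primary <- which.max(msum)
  qual <- strrep("?", nchar(read))  # Q30 throughout
  n <- length(segs)
  sa_entry <- vapply(seq_len(n), function(i) {
    sprintf("%s,%d,%s,%s,%d,%d", segs[[i]]$chrom, segs[[i]]$r_start + 1L,
            segs[[i]]$strand, parts[[i]]$cigar, mapq, parts[[i]]$nm)
  }, "")
  rows <- lapply(seq_len(n), function(i) {
    flag <- 0L
    if (segs[[i]]$strand == "-") flag <- flag + 16L
    if (i != primary) flag <- flag + 2048L
    tags <- sprintf("NM:i:%d", parts[[i]]$nm)
    if (n > 1L) {
      others <- paste0(paste(sa_entry[-i], collapse = ";"), ";")
      tags <- paste(tags, sprintf("SA:Z:%s", others), sep = "\t")
    }
    data.frame(qname = read_name, flag = flag, rname = segs[[i]]$chrom,
               pos = segs[[i]]$r_start + 1L, mapq = mapq,
               cigar = parts[[i]]$cigar, seq = parts[[i]]$seq, qual = qual,
               tags = tags, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# sample reads from one haplotype contig and synthesize their records
.contig_reads <- function(contig, refs, cfg, prefix) {
  len <- nchar(contig$seq)
  rl <- min(cfg$read_length, len)
  n <- max(1L, round(len * (cfg$depth / 2) / rl))
  starts <- if (len == rl) rep(0L, n) else
    sort(sample.int(len - rl + 1L, n, replace = TRUE) - 1L)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    a <- starts[i]; b <- a + rl
    read <- .apply_errors(.substr0(contig$seq, a, b), cfg$error_rate)
    segs <- .pieces_to_segments(.read_pieces(contig$blocks, a, b))
    if (stats::runif(1) < 0.5) {
      read <- .revcomp(read)
      segs <- .flip_segments(segs, rl)
    }
    recs[[i]] <- .read_records(sprintf("%s_r%04d", prefix, i), read, segs, refs)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) NULL else do.call(rbind, recs)
}

# ---- locus assembly -------------------------------------------------------

# build reference contigs, haplotype pair, truth rows for one locus
.locus_build <- function(cfg, locus_id, contig) {
  svs <- cfg$sv_specs
  is_tra <- any(svs$type == "TRA")
  if (is_tra && nrow(svs) > 1L) {
    stop("a TRA locus carries exactly one SV spec")
  }
  if (is_tra) {
    chromA <- paste0(contig, "a"); chromB <- paste0(contig, "b")
    refs <- list(.random_dna(cfg$ref_length), .random_dna(cfg$ref_length))
    names(refs) <- c(chromA, chromB)
    posA <- svs$pos[1]; posB <- svs$pos[1]
    var_hap <- .tra_contigs(chromA, refs[[chromA]], posA,
                            chromB, refs[[chromB]], posB)
    ref_hap <- .set_block_chrom(.identity_hap(refs))
    truth <- data.frame(id = locus_id, chrom = chromA, pos = posA,
                        type = "TRA", length = 0,
                        genotype = svs$genotype[1],
                        chrom2 = chromB, pos2 = posB,
                        stringsAsFactors = FALSE)
  } else {
    refs <- list(.random_dna(cfg$ref_length)); names(refs) <- contig
    var_hap <- list(.variant_contig(contig, refs[[contig]], svs))
    names(var_hap) <- contig
    ref_hap <- .set_block_chrom(.identity_hap(refs))
    truth <- data.frame(id = sprintf("%s_%d", locus_id, seq_len(nrow(svs))),
                        chrom = contig, pos = svs$pos, type = svs$type,
                        length = svs$length, genotype = svs$genotype,
                        chrom2 = NA_character_, pos2 = NA_real_,
                        stringsAsFactors = FALSE)
    if (nrow(svs) == 1L) truth$id <- locus_id
  }
  hap1 <- if (all(svs$genotype == "1/1")) var_hap else ref_hap
  hap2 <- var_hap
  records <- list()
  for (h in c(1L, 2L)) {
    hap <- if (h == 1L) hap1 else hap2
    for (ci in seq_along(hap)) {
      prefix <- sprintf("%s_h%d_c%d", locus_id, h, ci)
      records[[length(records) + 1L]] <-
        .contig_reads(hap[[ci]], refs, cfg, prefix)
    }
  }
  records <- records[!vapply(records, is.null, logical(1))]
  list(refs = refs, records = do.call(rbind, records), truth = truth)
}

.truth_vcf_lines <- function(truth, refs_len, sample = "SIM") {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(refs_len), refs_len),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (or mate position for TRA)\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Mate chromosome for TRA\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  body <- vapply(seq_len(nrow(truth)), function(i) {
    t <- truth[i, ]
    info <- if (t$type == "TRA") {
      sprintf("SVTYPE=TRA;CHR2=%s;END=%d", t$chrom2, t$pos2 + 1L)
    } else if (t$type == "INS") {
      sprintf("SVTYPE=INS;END=%d;SVLEN=%d", t$pos + 1L, t$length)
    } else {
      svlen <- if (t$type == "DEL") -t$length else t$length
      sprintf("SVTYPE=%s;END=%d;SVLEN=%d", t$type, t$pos + t$length, svlen)
    }
    paste(t$chrom, t$pos + 1L, t$id, "N", sprintf("<%s>", t$type), ".",
          "PASS", info, "GT", t$genotype, sep = "\t")
  }, "")
  c(header, body)
}

.write_sim_files <- function(refs, records, truth, dir, stem) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, paste0(stem, ".fa"))
  seqs <- Biostrings::DNAStringSet(unlist(refs))
  names(seqs) <- names(refs)
  Biostrings::writeXStringSet(seqs, fasta)
  Rsamtools::indexFa(fasta)

  sam <- file.path(dir, paste0(stem, ".sam"))
  refs_len <- vapply(refs, nchar, 0L)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(refs_len), refs_len))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\t%s",
                   records$qname, records$flag, records$rname, records$pos,
                   records$mapq, records$cigar, records$seq, records$qual,
                   records$tags)
  writeLines(c(header, lines), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, stem), overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)

  vcf <- file.path(dir, paste0(stem, ".truth.vcf"))
  writeLines(.truth_vcf_lines(truth, refs_len), vcf)
  list(fasta = fasta, bam = bam, vcf = vcf)
}

#' Simulate one locus with implanted SVs
#'
#' Writes an indexed reference FASTA, a coordinate-sorted indexed BAM of
#' synthesized long-read alignments, and a truth VCF recording each SV
#' with its genotype. Reads crossing breakpoints carry split records
#' with SA tags (or D/I CIGAR operations for deletions/insertions),
#' constructed exactly from the simulation coordinates.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory.
#' @param stem Output file stem (default `"sim"`).
#' @param contig Reference contig name (TRA loci get `a`/`b` arms).
#' @return List with `fasta`, `bam`, `vcf` paths, the `truth` data.frame
#'   (0-based positions) and `n_records`.
#' @export
simulate_locus <- function(cfg, dir, stem = "sim", contig = "locus1") {
  built <- .with_seed(cfg$seed, .locus_build(cfg, stem, contig))
  paths <- .write_sim_files(built$refs, built$records, built$truth, dir, stem)
  c(paths, list(truth = built$truth, n_records = nrow(built$records)))
}

#' Simulate a cohort of independent SV loci
#'
#' Generates `n_loci` loci cycling through the five SV types with
#' alternating heterozygous/homozygous genotypes, each on its own contig,
#' concatenated into one reference, one BAM and one truth VCF. SV
#' lengths are drawn uniformly from `length_range`; each SV sits at the
#' center of its contig.
#'
#' @param n_loci Number of loci (>= 1).
#' @param dir Output directory.
#' @param template A [sim_config()] supplying depth, read length, contig
#'   length and error rate.
#' @param seed Integer seed for the whole cohort.
#' @param types SV types to cycle through.
#' @param length_range Range (bases) from which SV lengths are drawn.
#' @return List with `fasta`, `bam`, `vcf` paths and the `manifest`
#'   data.frame (truth per locus, 0-based positions).
#' @export
simulate_cohort <- function(n_loci, dir, template = sim_config(), seed = 1,
                            types = c("DEL", "INS", "DUP", "INV", "TRA"),
                            length_range = c(100, 1000)) {
  stopifnot(n_loci >= 1)
  built <- .with_seed(seed, {
    all_refs <- list(); all_rec <- list(); all_truth <- list()
    for (i in seq_len(n_loci)) {
      ty <- types[((i - 1L) %% length(types)) + 1L]
      gt <- if ((((i - 1L) %/% length(types)) %% 2L) == 0L) "0/1" else "1/1"
      len <- floor(stats::runif(1, length_range[1], length_range[2] + 1))
      pos <- floor(template$ref_length / 2 - len / 2)
      cfg <- sim_config(seed = 0, ref_length = template$ref_length,
                        depth = template$depth,
                        read_length = template$read_length,
                        sv_specs = data.frame(type = ty, pos = pos,
                                              length = len, genotype = gt,
                                              stringsAsFactors = FALSE),
                        error_rate = template$error_rate)
      lb <- .locus_build(cfg, sprintf("sv%03d", i), sprintf("locus%03d", i))
      all_refs <- c(all_refs, lb$refs)
      all_rec[[i]] <- lb$records
      all_truth[[i]] <- lb$truth
    }
    list(refs = all_refs, records = do.call(rbind, all_rec),
         truth = do.call(rbind, all_truth))
  })
  paths <- .write_sim_files(built$refs, built$records, built$truth, dir,
                            "cohort")
  c(paths, list(manifest = built$truth))
}
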