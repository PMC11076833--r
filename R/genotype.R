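# Force-calling: genotype candidate SVs from read-level structures.
#
# Per candidate, reads in the padded evaluation window are kept only if
# they cover >= min_overlap_frac of the SV interval (for point-like SVs,
# of the +-breakend_flank neighborhood) and align >= min_region_align_len
# bases inside the window. A kept read supports the SV when it carries a
# same-type event whose breakpoints all fall within max_bp_disparity of
# the candidate's; the remaining kept reads are reference reads.
# AF = support / (support + reference); GT is 1/1 above hom_af, 0/1 above
# het_af (strict inequalities), else 0/0; ./. with no informative reads.

#' Genotyping configuration
#'
#' @param min_overlap_frac Minimum fraction of the SV interval (or of the
#'   breakend neighborhood for INS/TRA) a read's aligned span must cover.
#' @param max_bp_disparity Maximum distance (bases) between a read
#'   breakpoint and the candidate breakpoint for the read to support it;
#'   also the window padding.
#' @param min_region_align_len Minimum aligned bases inside the window.
#' @param het_af AF strictly above which a genotype is at least `0/1`.
#' @param hom_af AF strictly above which the genotype is `1/1`.
#' @param breakend_flank Half-width (bases) of the neighborhood used as
#'   the coverage denominator for point-like SVs (INS, breakends).
#' @param min_clip_len For point-like SVs (INS/TRA) only: a
#'   non-supporting read whose alignment ends in a terminal clip of at
#'   least this many bases within `max_bp_disparity` of the breakend is
#'   ambiguous (it likely truncates inside the unrepresented sequence)
#'   and is excluded rather than counted as reference.
#' @return An object of class `genotype_config`.
#' @export
genotype_config <- function(min_overlap_frac = 0.5, max_bp_disparity = 1000,
                            min_region_align_len = 100, het_af = 0.3,
                            hom_af = 0.8, breakend_flank = 500,
                            min_clip_len = 50) {
  stopifnot(het_af >= 0, het_af < hom_af, hom_af <= 1,
            min_overlap_frac >= 0, min_overlap_frac <= 1,
            max_bp_disparity >= 0, min_region_align_len >= 0)
  structure(list(min_overlap_frac = min_overlap_frac,
                 max_bp_disparity = max_bp_disparity,
                 min_region_align_len = min_region_align_len,
                 het_af = het_af, hom_af = hom_af,
                 breakend_flank = breakend_flank,
                 min_clip_len = min_clip_len),
            class = "genotype_config")
}

.sv_query <- function(id, chrom, start, end, sv_type, sv_length = NA,
                      mate_chrom = NA, mate_pos = NA) {
  data.frame(id = id, chrom = chrom, start = start, end = end,
             sv_type = sv_type, sv_length = sv_length,
             mate_chrom = mate_chrom, mate_pos = mate_pos,
             stringsAsFactors = FALSE)
}

#' Evaluation window(s) of a candidate SV
#'
#' The SV interval padded by `max_bp_disparity` on both sides; for
#' insertions a window around the insertion point, for translocations one
#' window per breakend (on each chromosome). Windows are clipped at
#' position 0; clipping at the contig end happens at load time.
#'
#' @param query One row of a query table (see [read_sv_queries()]).
#' @param cfg A [genotype_config()].
#' @return List of [region_spec()] objects (length 2 for TRA).
#' @export
evaluation_window <- function(query, cfg = genotype_config()) {
  pad <- cfg$max_bp_disparity
  mk <- function(chrom, s, e) region_spec(chrom, max(0, s), e)
  if (identical(query$sv_type, "TRA")) {
    list(mk(query$chrom, query$start - pad, query$start + pad),
         mk(query$mate_chrom, query$mate_pos - pad, query$mate_pos + pad))
  } else if (identical(query$sv_type, "INS")) {
    list(mk(query$chrom, query$start - pad, query$start + pad))
  } else {
    list(mk(query$chrom, query$start - pad, query$end + pad))
  }
}

# width of the read's aligned span (min start to max end across segments
# on chrom, split-alignment gaps included) restricted to [s, e); a
# split-read deletion spans its gap exactly as a CIGAR-D alignment does
.span_overlap <- function(seg, chrom, s, e) {
  k <- seg$chrom == chrom
  if (!any(k)) return(0)
  max(0, min(max(seg$ref_end[k]), e) - max(min(seg$ref_start[k]), s))
}

# width of the union of a read's segment ref intervals restricted to
# [s, e) on chrom
.union_overlap <- function(seg, chrom, s, e) {
  k <- seg$chrom == chrom & seg$ref_end > s & seg$ref_start < e
  if (!any(k)) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(
    start = pmax(seg$ref_start[k], s) + 1, end = pmin(seg$ref_end[k], e)))
  sum(IRanges::width(ir))
}

.event_matches_query <- function(ev, query, cfg) {
  D <- cfg$max_bp_disparity
  if (ev$type != query$sv_type &&
      !(ev$type == "TRA" && query$sv_type == "TRA")) return(FALSE)
  if (query$sv_type == "TRA") {
    direct <- ev$chrom_a == query$chrom && abs(ev$pos_a - query$start) <= D &&
      ev$chrom_b == query$mate_chrom && abs(ev$pos_b - query$mate_pos) <= D
    swapped <- ev$chrom_b == query$chrom && abs(ev$pos_b - query$start) <= D &&
      ev$chrom_a == query$mate_chrom && abs(ev$pos_a - query$mate_pos) <= D
    return(direct || swapped)
  }
  if (ev$chrom_a != query$chrom) return(FALSE)
  ok <- if (query$sv_type == "INS") {
    abs(ev$pos_a - query$start) <= D
  } else {
    abs(ev$pos_a - query$start) <= D && abs(ev$pos_b - query$end) <= D
  }
  if (!ok) return(FALSE)
  # read/query SV length agreement, to avoid counting nested or unrelated
  # events near the same spot (not applicable to TRA junctions)
  if (!is.na(query$sv_length) && query$sv_length > 0 && ev$length > 0) {
    tol <- max(0.5 * query$sv_length, D)
    if (abs(ev$length - query$sv_length) > tol) return(FALSE)
  }
  TRUE
}

#' Partition window reads into supporting and reference reads
#'
#' Applies the coverage, disparity and effective-alignment-length
#' exclusions, then labels each surviving read as supporting (it carries
#' a matching same-type event) or reference.
#'
#' @param groups List of `read_group` objects restricted to the
#'   evaluation window(s).
#' @param structures Matching list of `read_structure` objects.
#' @param query One query row.
#' @param cfg A [genotype_config()].
#' @return `list(support = <names>, reference = <names>)`.
#' @export
collect_informative_reads <- function(groups, structures, query,
                                      cfg = genotype_config()) {
  windows <- evaluation_window(query, cfg)
  cov_iv <- if (query$sv_type %in% c("INS", "TRA")) {
    ends <- list(c(query$chrom, query$start))
    if (query$sv_type == "TRA") {
      ends <- c(ends, list(c(query$mate_chrom, query$mate_pos)))
    }
    lapply(ends, function(e) {
      s <- max(0, as.numeric(e[2]) - cfg$breakend_flank)
      list(chrom = e[1], start = s, end = as.numeric(e[2]) + cfg$breakend_flank)
    })
  } else {
    list(list(chrom = query$chrom, start = query$start, end = query$end))
  }

  support <- character(); reference <- character()
  for (g in groups) {
    seg <- g$segments
    covs <- vapply(cov_iv, function(iv) {
      w <- iv$end - iv$start
      if (w <= 0) return(0)
      .span_overlap(seg, iv$chrom, iv$start, iv$end) / w
    }, 0)
    if (max(covs) < cfg$min_overlap_frac) next
    aln <- sum(vapply(windows, function(wd) {
      .union_overlap(seg, wd$chrom, wd$start, wd$end)
    }, 0))
    if (aln < cfg$min_region_align_len) next
    st <- structures[[g$read_name]]
    ev <- st$events
    hit <- FALSE
    if (!is.null(ev) && nrow(ev)) {
      for (k in seq_len(nrow(ev))) {
        if (.event_matches_query(ev[k, ], query, cfg)) { hit <- TRUE; break }
      }
    }
    if (hit) {
      support <- c(support, g$read_name)
    } else if (query$sv_type %in% c("INS", "TRA") &&
               .clip_near_breakend(seg, cov_iv, cfg)) {
      # ambiguous: read truncates in a long clip at the breakend
      next
    } else {
      reference <- c(reference, g$read_name)
    }
  }
  list(support = support, reference = reference)
}

# TRUE when any segment carries a terminal clip >= min_clip_len whose
# position falls within max_bp_disparity of a breakend
.clip_near_breakend <- function(seg, cov_iv, cfg) {
  ends <- vapply(cov_iv, function(iv) (iv$start + iv$end) / 2, 0)
  chroms <- vapply(cov_iv, function(iv) iv$chrom, "")
  for (i in seq_len(nrow(seg))) {
    ce <- cigar_events(seg$cigar[i], seg$ref_start[i], cfg$min_clip_len)
    ce <- ce[ce$kind == "CLIP", , drop = FALSE]
    if (!nrow(ce)) next
    for (k in seq_len(nrow(ce))) {
      near <- chroms == seg$chrom[i] &
        abs(ce$ref_pos[k] - ends) <= cfg$max_bp_disparity
      if (any(near)) return(TRUE)
    }
  }
  FALSE
}

#' Assign a genotype from support/reference read counts
#'
#' `AF = n_support / (n_support + n_ref)`. The genotype is `1/1` when AF
#' strictly exceeds `hom_af`, `0/1` when it strictly exceeds `het_af`,
#' `0/0` otherwise, and `./.` when there are no informative reads at all.
#'
#' @param n_support Supporting read count.
#' @param n_ref Informative non-supporting read count.
#' @param cfg A [genotype_config()].
#' @return An object of class `genotype_result`: `n_support`, `n_ref`,
#'   `af`, `genotype`.
#' @export
assign_genotype <- function(n_support, n_ref, cfg = genotype_config()) {
  stopifnot(n_support >= 0, n_ref >= 0)
  n <- n_support + n_ref
  if (n == 0) {
    af <- NA_real_; gt <- "./."
  } else {
    af <- n_support / n
    gt <- if (af > cfg$hom_af) "1/1" else if (af > cfg$het_af) "0/1" else "0/0"
  }
  structure(list(n_support = n_support, n_ref = n_ref, af = af,
                 genotype = gt),
            class = "genotype_result")
}

#' @export
print.genotype_result <- function(x, ...) {
  cat("<genotype> ", x$genotype, "  DV=", x$n_support, " DR=", x$n_ref,
      " AF=", ifelse(is.na(x$af), "NA", sprintf("%.3f", x$af)), "\n", sep = "")
  invisible(x)
}

#' Force-call one candidate SV against a BAM
#'
#' @param bam Path to an indexed BAM.
#' @param query One query row (see [read_sv_queries()]).
#' @param cfg A [genotype_config()].
#' @param fcfg A [filter_config()] for read ingest.
#' @param min_sv_length Minimum per-read event length.
#' @return A `genotype_result` with the read name sets attached as
#'   attributes `support` and `reference`.
#' @export
genotype_sv <- function(bam, query, cfg = genotype_config(),
                        fcfg = filter_config(), min_sv_length = 50) {
  windows <- evaluation_window(query, cfg)
  groups <- load_regions_reads(bam, windows, fcfg, keep_seq = FALSE)
  structures <- classify_reads(groups, min_sv_length)
  part <- collect_informative_reads(groups, structures, query, cfg)
  res <- assign_genotype(length(part$support), length(part$reference), cfg)
  attr(res, "support") <- part$support
  attr(res, "reference") <- part$reference
  res
}

#' Read candidate SVs from VCF or BED
#'
#' VCF records are interpreted through `SVTYPE`, `END`, `SVLEN` and
#' `CHR2` (or a BND `ALT`); BED columns are
#' `chrom, start, end[, type[, length]]` (0-based half-open). Records
#' whose SV type cannot be determined get `sv_type = NA` and are passed
#' through genotyping as `./.`.
#'
#' @param path Input file.
#' @param format `"vcf"` or `"bed"` (default guessed from the extension).
#' @return data.frame with columns `id`, `chrom`, `start`, `end`
#'   (0-based half-open), `sv_type`, `sv_length`, `mate_chrom`,
#'   `mate_pos`.
#' @export
read_sv_queries <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "vcf"
  }
  format <- match.arg(format, c("vcf", "bed"))
  if (format == "bed") return(.queries_from_bed(path))
  .queries_from_vcf(vcfR::read.vcfR(path, verbose = FALSE))
}

.info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
}

.queries_from_vcf <- function(vcf) {
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (!n) return(.sv_query(character(), character(), numeric(), numeric(),
                           character())[0, ])
  info <- vcf@fix[, "INFO"]
  svtype <- .info_field(info, "SVTYPE")
  svlen <- suppressWarnings(abs(as.numeric(.info_field(info, "SVLEN"))))
  endf <- suppressWarnings(as.numeric(.info_field(info, "END")))
  chr2 <- .info_field(info, "CHR2")
  pos <- as.numeric(fix[, "POS"])
  alt <- fix[, "ALT"]
  out <- vector("list", n)
  for (i in seq_len(n)) {
    id <- fix[i, "ID"]
    if (is.na(id) || id == ".") id <- sprintf("%s_%d_%d", fix[i, "CHROM"], pos[i], i)
    ty <- svtype[i]
    start <- pos[i] - 1
    mate_chrom <- NA_character_; mate_pos <- NA_real_
    if (!is.na(ty) && ty == "BND") {
      m <- regmatches(alt[i], regexec("[\\[\\]]([^:\\[\\]]+):([0-9]+)[\\[\\]]",
                                      alt[i], perl = TRUE))[[1]]
      if (length(m) == 3L) {
        ty <- "TRA"; mate_chrom <- m[2]; mate_pos <- as.numeric(m[3]) - 1
      } else ty <- NA_character_
    } else if (!is.na(ty) && ty == "TRA") {
      mate_chrom <- chr2[i]
      mate_pos <- if (!is.na(endf[i])) endf[i] - 1 else NA_real_
      if (is.na(mate_chrom) || is.na(mate_pos)) ty <- NA_character_
    }
    if (!is.na(ty) && !ty %in% c("DEL", "INS", "DUP", "INV", "TRA")) {
      ty <- NA_character_
    }
    if (is.na(ty)) {
      out[[i]] <- .sv_query(id, fix[i, "CHROM"], start, start + 1, NA_character_)
      next
    }
    len <- svlen[i]
    end <- if (ty %in% c("INS", "TRA")) start + 1
           else if (!is.na(endf[i])) endf[i]
           else if (!is.na(len)) start + len
           else start + 1
    if (is.na(len) && !ty %in% c("INS", "TRA")) len <- end - start
    out[[i]] <- .sv_query(id, fix[i, "CHROM"], start, end, ty, len,
                          mate_chrom, mate_pos)
  }
  do.call(rbind, out)
}

.queries_from_bed <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = paste0("V", 1:5), fill = TRUE)
  n <- nrow(tb)
  ty <- if (ncol(tb) >= 4) as.character(tb$V4) else rep(NA_character_, n)
  ty[!ty %in% c("DEL", "INS", "DUP", "INV", "TRA")] <- NA_character_
  len <- if (ncol(tb) >= 5) suppressWarnings(abs(as.numeric(tb$V5))) else rep(NA_real_, n)
  len[is.na(len)] <- (tb$V3 - tb$V2)[is.na(len)]
  .sv_query(sprintf("%s_%d_%d", tb$V1, tb$V2, seq_len(n)),
            as.character(tb$V1), tb$V2, tb$V3, ty, len)
}

#' Force-call every record of a candidate VCF
#'
#' Re-genotypes each record against one or more BAMs and (optionally)
#' writes an annotated VCF preserving record order and all non-genotype
#' fields, with `FORMAT` fields `GT` (genotype), `DV` (supporting reads),
#' `DR` (reference reads) and `AF`. Records whose `SVTYPE` cannot be
#' parsed pass through with `GT = ./.` and a warning.
#'
#' @param bams Character vector of indexed BAM paths (one output sample
#'   column each).
#' @param vcf_path Candidate VCF.
#' @param out_vcf Output path for the annotated VCF, or `NULL` to skip
#'   writing.
#' @param cfg A [genotype_config()].
#' @param fcfg A [filter_config()].
#' @param min_sv_length Minimum per-read event length.
#' @return (Invisibly) a data.frame of per-record, per-sample results:
#'   `id`, `sample`, `sv_type`, `n_support`, `n_ref`, `af`, `genotype`.
#' @export
genotype_vcf <- function(bams, vcf_path, out_vcf = NULL,
                         cfg = genotype_config(), fcfg = filter_config(),
                         min_sv_length = 50) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  queries <- .queries_from_vcf(vcf)
  samples <- sub("\\.bam$", "", basename(bams), ignore.case = TRUE)
  rows <- list(); cells <- list()
  for (b in seq_along(bams)) {
    for (i in seq_len(nrow(queries))) {
      q <- queries[i, ]
      if (is.na(q$sv_type)) {
        warning("record ", q$id, ": unparseable SVTYPE; emitted as ./.")
        res <- list(n_support = NA_integer_, n_ref = NA_integer_,
                    af = NA_real_, genotype = "./.")
      } else {
        res <- genotype_sv(bams[b], q, cfg, fcfg, min_sv_length)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id = q$id, sample = samples[b], sv_type = q$sv_type,
        n_support = res$n_support, n_ref = res$n_ref, af = res$af,
        genotype = res$genotype, stringsAsFactors = FALSE)
      cells[[paste(b, i)]] <- sprintf(
        "%s:%s:%s:%s", res$genotype,
        ifelse(is.na(res$n_support), ".", res$n_support),
        ifelse(is.na(res$n_ref), ".", res$n_ref),
        ifelse(is.na(res$af), ".", sprintf("%.4f", res$af)))
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), sample = character(), sv_type = character(),
               n_support = integer(), n_ref = integer(), af = numeric(),
               genotype = character())
  if (!is.null(out_vcf)) {
    gt <- matrix("", nrow = nrow(queries), ncol = length(bams),
                 dimnames = list(NULL, samples))
    for (b in seq_along(bams)) for (i in seq_len(nrow(queries))) {
      gt[i, b] <- cells[[paste(b, i)]]
    }
    .write_genotyped_vcf(vcf, gt, out_vcf)
  }
  invisible(results)
}

# serialize the annotated VCF as plain text (fix fields untouched)
.write_genotyped_vcf <- function(vcf, gt, path) {
  meta <- vcf@meta
  need <- c(
    GT = "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    DV = "##FORMAT=<ID=DV,Number=1,Type=Integer,Description=\"Reads supporting the variant\">",
    DR = "##FORMAT=<ID=DR,Number=1,Type=Integer,Description=\"Informative reference reads\">",
    AF = "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Variant allele frequency among informative reads\">")
  for (k in names(need)) {
    if (!any(grepl(paste0("^##FORMAT=<ID=", k, ","), meta))) {
      meta <- c(meta, need[[k]])
    }
  }
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", colnames(gt)), collapse = "\t")
  fix <- vcf@fix
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  body <- character(nrow(fix))
  for (i in seq_len(nrow(fix))) {
    f <- fix[i, c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")]
    f[is.na(f)] <- "."
    body[i] <- paste(c(f, "GT:DV:DR:AF", gt[i, ]), collapse = "\t")
  }
  writeLines(c(meta, header, body), path)
  invisible(path)
}
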