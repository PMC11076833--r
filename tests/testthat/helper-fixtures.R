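# Fixture builders: everything is constructed in code at test time.

# one SAM record as a data.frame row
sam_rec <- function(qname, flag, rname, pos, cigar, seq, qual = NULL,
                    mapq = 60, tags = "") {
  if (is.null(qual)) qual <- strrep("?", nchar(seq))  # Q30
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, seq = seq, qual = qual,
             tags = tags, stringsAsFactors = FALSE)
}

# write records to a sorted, indexed BAM; returns the BAM path
write_test_bam <- function(records, targets,
                           dir = withr::local_tempdir(.local_envir = parent.frame()),
                           stem = "fixture") {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(targets),
                      as.integer(targets)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
                  records$qname, records$flag, records$rname, records$pos,
                  records$mapq, records$cigar, records$seq, records$qual,
                  ifelse(nzchar(records$tags), paste0("\t", records$tags), ""))
  sam <- file.path(dir, paste0(stem, ".sam"))
  writeLines(c(header, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, stem), overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# quality string with a given mean Phred value
qual_str <- function(n, phred) strrep(intToUtf8(phred + 33L), n)

# a small simulated locus (cheap settings for unit tests)
small_locus <- function(type = "DEL", genotype = "0/1", seed = 42,
                        len = 300,
                        dir = withr::local_tempdir(.local_envir = parent.frame())) {
  cfg <- sim_config(seed = seed, ref_length = 9000, depth = 20,
                    read_length = 3000,
                    sv_specs = data.frame(type = type, pos = 4400,
                                          length = len, genotype = genotype,
                                          stringsAsFactors = FALSE))
  simulate_locus(cfg, dir, stem = paste0(tolower(type), "loc"))
}

# hand-built read-group (bypasses BAM I/O) for classification tests
make_group <- function(segments, read_name = "r1") {
  seg <- do.call(rbind, segments)
  seg <- seg[order(seg$query_start), , drop = FALSE]
  structure(list(read_name = read_name,
                 read_length = max(seg$query_end),
                 segments = seg),
            class = "read_group")
}

make_segment <- function(chrom, ref_start, ref_end, query_start, query_end,
                         strand = "+", cigar = NULL, read_name = "r1",
                         mapq = 60) {
  if (is.null(cigar)) cigar <- paste0(ref_end - ref_start, "M")
  data.frame(read_name = read_name, chrom = chrom, ref_start = ref_start,
             ref_end = ref_end, query_start = query_start,
             query_end = query_end, strand = strand, mapq = mapq,
             mean_baseq = 30, identity = 1, is_supplementary = FALSE,
             cigar = cigar, read_length = query_end, seq = NA_character_,
             stringsAsFactors = FALSE)
}
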