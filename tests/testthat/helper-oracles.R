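# Independent oracles, kept deliberately separate from the package's
# implementation paths.

# brute-force rule table for a 2-segment split configuration
# (the normative signature table, implemented from scratch)
oracle_pair_type <- function(chrom1, chrom2, strand1, strand2, rgap, qgap,
                             j1, j2, L) {
  if (chrom1 != chrom2) return(list(type = "TRA", len = 0))
  if (strand1 != strand2) {
    span <- abs(j2 - j1)
    if (span >= L) return(list(type = "INV", len = span))
    return(list(type = "REF", len = 0))
  }
  if (rgap <= -L) return(list(type = "DUP", len = -rgap))
  if (rgap - qgap >= L) return(list(type = "DEL", len = rgap - qgap))
  if (qgap - rgap >= L) return(list(type = "INS", len = qgap - rgap))
  list(type = "REF", len = 0)
}

# build a 2-segment read group realizing (strand1, strand2, rgap, qgap)
pair_group <- function(strand1, strand2, rgap, qgap, chrom1 = "chr1",
                       chrom2 = "chr1", seg_len = 1000, base = 100000) {
  q1 <- c(0, seg_len)
  q2 <- c(seg_len + qgap, 2 * seg_len + qgap)
  r1 <- c(base, base + seg_len)
  if (strand1 == strand2 && chrom1 == chrom2) {
    if (strand1 == "+") r2 <- c(r1[2] + rgap, r1[2] + rgap + seg_len)
    else r2 <- c(r1[1] - rgap - seg_len, r1[1] - rgap)
  } else {
    # opposite strands / chromosomes: rgap is not defined; place apart
    r2 <- c(base + 3 * seg_len, base + 4 * seg_len)
  }
  make_group(list(
    make_segment(chrom1, r1[1], r1[2], q1[1], q1[2], strand1),
    make_segment(chrom2, r2[1], r2[2], q2[1], q2[2], strand2)))
}

# junction coordinates of a pair group (for the INV oracle span)
pair_junctions <- function(g) {
  s <- g$segments
  j1 <- if (s$strand[1] == "+") s$ref_end[1] else s$ref_start[1]
  j2 <- if (s$strand[2] == "+") s$ref_start[2] else s$ref_end[2]
  c(j1, j2)
}

# mirror a read group to the opposite sequencing strand
reverse_group <- function(g) {
  seg <- g$segments
  RL <- g$read_length
  qs <- RL - seg$query_end
  qe <- RL - seg$query_start
  seg$query_start <- qs
  seg$query_end <- qe
  seg$strand <- ifelse(seg$strand == "+", "-", "+")
  seg <- seg[order(seg$query_start), , drop = FALSE]
  structure(list(read_name = g$read_name, read_length = RL, segments = seg),
            class = "read_group")
}

# sweep-line maximum overlap depth of a span set
oracle_max_overlap <- function(spans) {
  if (!nrow(spans)) return(0L)
  ev <- rbind(data.frame(x = spans$start, d = 1L),
              data.frame(x = spans$end, d = -1L))
  ev <- ev[order(ev$x, ev$d), ]   # ends (-1) before starts at equal x
  max(cumsum(ev$d))
}

# brute-force per-base coverage from a record table (independent of the
# package's coverage path)
oracle_coverage <- function(records, chrom, start, end) {
  cov <- numeric(end - start)
  for (i in seq_len(nrow(records))) {
    if (records$rname[i] != chrom) next
    ops <- gregexpr("\\d+[MIDNSHP=X]", records$cigar[i])[[1]]
    toks <- regmatches(records$cigar[i], list(ops))[[1]]
    r <- records$pos[i] - 1L
    for (tk in toks) {
      len <- as.integer(sub("[A-Z=]$", "", tk))
      op <- sub("^\\d+", "", tk)
      if (op %in% c("M", "=", "X")) {
        lo <- max(r, start); hi <- min(r + len, end)
        if (hi > lo) cov[(lo - start + 1L):(hi - start)] <-
            cov[(lo - start + 1L):(hi - start)] + 1
        r <- r + len
      } else if (op %in% c("D", "N")) r <- r + len
    }
  }
  cov
}
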