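# CIGAR walking. Breakpoint evidence is read directly off the alignment
# cigar, so these helpers are the package's own rather than a wrapper.

.CIGAR_RE <- "(\\d+)([MIDNSHP=X])"

#' Parse a CIGAR string into operations
#'
#' @param cigar A single CIGAR string, e.g. `"50M60D50M"`.
#' @return A data.frame with columns `op` (character) and `len` (integer).
#' @examples
#' parse_cigar("50M60D50M")
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar) || cigar == "*") {
    return(data.frame(op = character(), len = integer()))
  }
  m <- gregexpr(.CIGAR_RE, cigar, perl = TRUE)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(cigar)) {
    stop("malformed CIGAR string: ", cigar)
  }
  data.frame(
    op  = substring(toks, nchar(toks), nchar(toks)),
    len = as.integer(substring(toks, 1L, nchar(toks) - 1L))
  )
}

# bases consumed on the reference
.cigar_ref_len <- function(ops) sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])

# aligned bases of the query (excludes clips)
.cigar_query_aligned <- function(ops) sum(ops$len[ops$op %in% c("M", "I", "=", "X")])

# full read length including soft AND hard clips (so supplementary
# hard-clipped records report the same read length as the primary)
.cigar_read_length <- function(ops) sum(ops$len[ops$op %in% c("M", "I", "S", "H", "=", "X")])

# denominator of the identity fraction: matches + insertions + deletions
.cigar_aligned_len <- function(ops) sum(ops$len[ops$op %in% c("M", "I", "D", "=", "X")])

.cigar_clips <- function(ops) {
  n <- nrow(ops)
  left <- 0L; right <- 0L
  i <- 1L
  while (i <= n && ops$op[i] %in% c("S", "H")) { left <- left + ops$len[i]; i <- i + 1L }
  j <- n
  while (j >= i && ops$op[j] %in% c("S", "H")) { right <- right + ops$len[j]; j <- j - 1L }
  c(left = left, right = right)
}

#' Extract SV-scale events from a CIGAR string
#'
#' Walks the alignment and reports deletions (`D`), insertions (`I`) and
#' terminal clips (`S`/`H`) whose length reaches `min_sv_length`; smaller
#' operations are ignored. Positions are 0-based reference coordinates.
#'
#' @param cigar CIGAR string of one aligned segment.
#' @param ref_start 0-based reference start of the segment.
#' @param min_sv_length Minimum operation length (bases) to report.
#' @return data.frame with columns `kind` (`"DEL"`, `"INS"`, `"CLIP"`),
#'   `ref_pos` (0-based; for `DEL` the first deleted base, for `INS` the
#'   base after which the insertion sits, for `CLIP` the clipped read end),
#'   `length`, and `side` (`"internal"`, `"left"`, `"right"`).
#' @examples
#' cigar_events("50M60D50M", ref_start = 1000, min_sv_length = 50)
#' @export
cigar_events <- function(cigar, ref_start = 0L, min_sv_length = 50L) {
  ops <- parse_cigar(cigar)
  out <- list()
  r <- as.integer(ref_start)
  n <- nrow(ops)
  for (i in seq_len(n)) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("S", "H")) {
      if (len >= min_sv_length) {
        # a clip is terminal by construction; left iff no ref consumed yet
        side <- if (r == ref_start) "left" else "right"
        out[[length(out) + 1L]] <- data.frame(
          kind = "CLIP", ref_pos = r, length = len, side = side)
      }
    } else if (op == "D") {
      if (len >= min_sv_length) {
        out[[length(out) + 1L]] <- data.frame(
          kind = "DEL", ref_pos = r, length = len, side = "internal")
      }
      r <- r + len
    } else if (op == "I") {
      if (len >= min_sv_length) {
        out[[length(out) + 1L]] <- data.frame(
          kind = "INS", ref_pos = r, length = len, side = "internal")
      }
    } else if (op %in% c("M", "=", "X", "N")) {
      r <- r + len
    }
  }
  if (!length(out)) {
    return(data.frame(kind = character(), ref_pos = integer(),
                      length = integer(), side = character()))
  }
  do.call(rbind, out)
}

# exon chain of a spliced alignment: maximal runs of reference-consuming
# non-N ops, split at N (intron) ops; 0-based half-open intervals
.cigar_exons <- function(cigar, ref_start) {
  ops <- parse_cigar(cigar)
  r <- as.integer(ref_start)
  exon_start <- r
  starts <- integer(); ends <- integer()
  open <- FALSE
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "D", "=", "X")) {
      if (!open) { exon_start <- r; open <- TRUE }
      r <- r + len
    } else if (op == "N") {
      if (open) { starts <- c(starts, exon_start); ends <- c(ends, r); open <- FALSE }
      r <- r + len
    }
    # I/S/H consume no reference
  }
  if (open) { starts <- c(starts, exon_start); ends <- c(ends, r) }
  data.frame(start = starts, end = ends)
}
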