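# Read layout: greedy non-overlapping interval scheduling (first-fit on
# start-sorted spans), plus deterministic subsampling of over-dense
# regions with priority to SV-supporting reads.

#' Assign read display spans to rows
#'
#' Spans are sorted by start and each is placed in the lowest-index row
#' whose last occupied end plus `gap` does not exceed the span's start; a
#' new row is opened otherwise. With `gap = 0` this first-fit scheme is
#' optimal for interval graphs: the number of rows equals the maximum
#' interval overlap depth.
#'
#' @param spans data.frame with columns `read_name`, `start`, `end`
#'   (display interval of each read: min ref_start to max ref_end across
#'   its in-window segments, gaps included).
#' @param gap Minimum reference-space gap between reads sharing a row.
#' @param max_rows Row cap; spans that would open a row beyond the cap
#'   are dropped (subsample first to avoid this).
#' @return An object of class `layout_assignment`: the input spans with a
#'   `row` column (1-based), sorted by row then start; dropped reads (if
#'   any) in `attr(, "dropped")`.
#' @export
assign_rows <- function(spans, gap = 5, max_rows = 200) {
  stopifnot(all(c("read_name", "start", "end") %in% names(spans)),
            gap >= 0, max_rows >= 1)
  if (nrow(spans) && any(spans$end <= spans$start)) {
    stop("every span must satisfy end > start")
  }
  spans <- spans[order(spans$start, spans$end, spans$read_name), , drop = FALSE]
  row_end <- numeric(0)
  row <- integer(nrow(spans))
  for (i in seq_len(nrow(spans))) {
    placed <- 0L
    for (r in seq_along(row_end)) {
      if (row_end[r] + gap <= spans$start[i]) { placed <- r; break }
    }
    if (!placed) {
      if (length(row_end) >= max_rows) { row[i] <- NA_integer_; next }
      row_end <- c(row_end, -Inf)
      placed <- length(row_end)
    }
    row_end[placed] <- spans$end[i]
    row[i] <- placed
  }
  spans$row <- row
  dropped <- spans$read_name[is.na(row)]
  out <- spans[!is.na(row), , drop = FALSE]
  out <- out[order(out$row, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("layout_assignment", "data.frame"),
            dropped = dropped, gap = gap, max_rows = max_rows)
}

#' Number of rows used by a layout
#' @param assignment A `layout_assignment`.
#' @return Integer row count.
#' @export
n_rows <- function(assignment) {
  if (!nrow(assignment)) 0L else max(assignment$row)
}

#' Deterministically subsample reads for display
#'
#' Identity when the read count does not exceed `max_reads`. Otherwise
#' all SV-supporting reads (`sv_type != "REF"`) are retained first, up to
#' the cap, and remaining slots are filled with reference reads sampled
#' deterministically by `seed`. The caller's RNG state is left untouched.
#'
#' @param structures List of `read_structure` objects.
#' @param max_reads Retention cap (default 200, the display row cap).
#' @param seed Integer seed for the reference-read sample.
#' @return Character vector of retained read names.
#' @export
subsample_reads <- function(structures, max_reads = 200, seed = 1) {
  stopifnot(max_reads > 0)
  nm <- vapply(structures, `[[`, "", "read_name")
  if (length(nm) <= max_reads) return(unname(nm))
  supporting <- nm[vapply(structures, `[[`, "", "sv_type") != "REF"]
  refs <- setdiff(nm, supporting)
  supporting <- sort(supporting); refs <- sort(refs)
  pick <- .with_seed(seed, {
    if (length(supporting) >= max_reads) {
      sample(supporting, max_reads)
    } else {
      c(supporting, sample(refs, max_reads - length(supporting)))
    }
  })
  unname(pick)
}

# evaluate expr under a private RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Display span of each read group within a region
#'
#' @param groups List of `read_group` objects.
#' @param region Optional [region_spec()]; only segments on its
#'   chromosome contribute (the union interval still includes gaps).
#' @return data.frame `read_name`, `start`, `end`.
#' @export
read_spans <- function(groups, region = NULL) {
  rows <- lapply(groups, function(g) {
    seg <- g$segments
    if (!is.null(region)) seg <- seg[seg$chrom == region$chrom, , drop = FALSE]
    if (!nrow(seg)) return(NULL)
    data.frame(read_name = g$read_name, start = min(seg$ref_start),
               end = max(seg$ref_end), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(read_name = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
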