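# Annotation lane: overlap queried regions with gene / repeat / segdup
# feature tracks supplied as BED or GenePred files.

.EMPTY_FEATURES <- data.frame(chrom = character(), start = numeric(),
                              end = numeric(), name = character(),
                              track = character(), stringsAsFactors = FALSE)

#' Read a feature track (BED or GenePred)
#'
#' BED 3/6 files are read via rtracklayer; GenePred files (UCSC gene
#' models: name, chrom, strand, txStart, txEnd, ...) are parsed directly,
#' optionally gzip-compressed. Gene features span txStart-txEnd.
#'
#' @param path Track file.
#' @param track Track label: `"gene"`, `"repeat"` or `"segdup"`.
#' @param format `"bed"` or `"genepred"`; guessed from the extension by
#'   default (`.genePred`/`.gp` -> genepred).
#' @return data.frame `chrom`, `start`, `end` (0-based half-open), `name`,
#'   `track`.
#' @export
read_features <- function(path, track = c("gene", "repeat", "segdup"),
                          format = NULL) {
  track <- match.arg(track)
  if (is.null(format)) {
    format <- if (grepl("\\.(genepred|gp)(\\.gz)?$", path, ignore.case = TRUE))
      "genepred" else "bed"
  }
  format <- match.arg(format, c("bed", "genepred"))
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    nm <- if (!is.null(gr$name)) as.character(gr$name) else
      sprintf("%s_%d", as.character(GenomicRanges::seqnames(gr)),
              GenomicRanges::start(gr) - 1L)
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1,
                     end = GenomicRanges::end(gr),
                     name = nm, track = track, stringsAsFactors = FALSE)
  } else {
    con <- if (grepl("\\.gz$", path)) gzfile(path) else path
    tb <- utils::read.table(con, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    # UCSC genePred: name chrom strand txStart txEnd cds... (txStart 0-based)
    df <- data.frame(chrom = as.character(tb[[2]]),
                     start = as.numeric(tb[[4]]), end = as.numeric(tb[[5]]),
                     name = as.character(tb[[1]]), track = track,
                     stringsAsFactors = FALSE)
  }
  df
}

#' Features of one or more tracks overlapping a region
#'
#' Missing track files produce an empty lane with a warning (annotation
#' is optional); intersecting features are clipped to the region bounds
#' for display.
#'
#' @param tracks Named list/character vector of track files; names are
#'   track labels (`gene`, `repeat`, `segdup`). Unnamed entries default
#'   to `gene`. Entries may also be feature data.frames as returned by
#'   [read_features()].
#' @param region A [region_spec()] or region string.
#' @return data.frame `chrom`, `start`, `end` (clipped), `name`, `track`.
#' @export
overlap_features <- function(tracks, region) {
  if (is.character(region)) region <- parse_region(region)
  if (is.null(tracks) || !length(tracks)) return(.EMPTY_FEATURES)
  if (is.character(tracks)) tracks <- as.list(tracks)
  labels <- names(tracks)
  if (is.null(labels)) labels <- rep("", length(tracks))
  labels[!nzchar(labels)] <- "gene"
  out <- list(.EMPTY_FEATURES)
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    if (is.character(tr)) {
      if (!file.exists(tr)) {
        warning("annotation track file '", tr, "' not found; lane left empty")
        next
      }
      tr <- read_features(tr, labels[i])
    }
    hit <- tr$chrom == region$chrom & tr$end > region$start & tr$start < region$end
    tr <- tr[hit, , drop = FALSE]
    if (!nrow(tr)) next
    tr$start <- pmax(tr$start, region$start)
    tr$end <- pmin(tr$end, region$end)
    out[[length(out) + 1L]] <- tr
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(res$track, res$start), , drop = FALSE]
}
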