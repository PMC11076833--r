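#' Construct a genomic region
#'
#' Internal coordinates are 0-based half-open throughout the package;
#' 1-based inclusive coordinates appear only at parse/serialize boundaries
#' (region strings, VCF).
#'
#' @param chrom Chromosome name (non-empty).
#' @param start,end 0-based half-open interval, `end > start`.
#' @param label Optional display name.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(chrom, start, end, label = NULL) {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom)) {
    stop("chrom must be a non-empty string")
  }
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || end <= start || start < 0) {
    stop("invalid region interval [", start, ", ", end, ")")
  }
  structure(list(chrom = chrom, start = start, end = end, label = label),
            class = "region_spec")
}

#' Parse a region string
#'
#' Accepts `"chrom:start-end"` with optional thousands separators in the
#' coordinates (1-based inclusive, as in samtools/IGV), or a bare
#' chromosome name (whole-contig region, resolved by the caller).
#'
#' @param text Region string, e.g. `"chr1:1,000-2,000"`.
#' @return A [region_spec()] in 0-based half-open coordinates;
#'   `"chr1:1-10"` gives `start = 0, end = 10`.
#' @export
parse_region <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    stop("region must be a single non-empty string")
  }
  if (!grepl(":", text, fixed = TRUE)) {
    # bare chromosome; end resolved against the BAM header downstream
    return(structure(list(chrom = text, start = 0, end = Inf, label = text),
                     class = "region_spec"))
  }
  m <- regmatches(text, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", text))[[1]]
  if (length(m) != 4L) stop("malformed region string: '", text, "'")
  start1 <- as.numeric(gsub(",", "", m[3], fixed = TRUE))
  end1   <- as.numeric(gsub(",", "", m[4], fixed = TRUE))
  if (is.na(start1) || is.na(end1) || start1 < 1 || start1 > end1) {
    stop("invalid region interval in '", text, "'")
  }
  region_spec(m[2], start1 - 1, end1, label = text)
}

#' @export
format.region_spec <- function(x, ...) {
  sprintf("%s:%s-%s", x$chrom,
          format(x$start + 1, big.mark = ",", scientific = FALSE, trim = TRUE),
          format(x$end, big.mark = ",", scientific = FALSE, trim = TRUE))
}

#' @export
print.region_spec <- function(x, ...) {
  cat("<region> ", format(x), "  (0-based width ", x$end - x$start, ")\n", sep = "")
  invisible(x)
}

.region_width <- function(region) region$end - region$start
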