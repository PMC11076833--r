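# Depth profiles, base-level pileup and isoform exon-chain extraction.
# All three operate on the same filtered read groups as the SV panel, so
# what is plotted is exactly what the classifier saw.

# per-base coverage vector over region from reference+query-consuming ops
# (M/=/X); deletions and introns (D/N) contribute nothing
.per_base_coverage <- function(groups, region) {
  w <- .region_width(region)
  delta <- numeric(w + 1L)
  for (g in groups) {
    seg <- g$segments
    for (i in seq_len(nrow(seg))) {
      if (seg$chrom[i] != region$chrom) next
      ops <- parse_cigar(seg$cigar[i])
      r <- seg$ref_start[i]
      for (k in seq_len(nrow(ops))) {
        op <- ops$op[k]; len <- ops$len[k]
        if (op %in% c("M", "=", "X")) {
          s <- max(r, region$start); e <- min(r + len, region$end)
          if (e > s) {
            delta[s - region$start + 1L] <- delta[s - region$start + 1L] + 1
            delta[e - region$start + 1L] <- delta[e - region$start + 1L] - 1
          }
          r <- r + len
        } else if (op %in% c("D", "N")) {
          r <- r + len
        }
      }
    }
  }
  cumsum(delta)[seq_len(w)]
}

#' Binned depth profile over a region
#'
#' Mean per-base coverage of the quality-filtered reads in each bin.
#' Deletion and intron CIGAR operations do not contribute coverage, so
#' depth dips are alignment facts even below the SV length cutoff.
#'
#' @param bam Path to an indexed BAM.
#' @param region A [region_spec()] or region string.
#' @param bin_size Bin width in bases (default: ~500 bins over the region).
#' @param cfg A [filter_config()].
#' @return An object of class `depth_profile`: `region`, `bin_size`,
#'   `bin_start` (0-based bin starts) and `depth` (mean coverage per bin;
#'   the last bin may be partial and is averaged over its actual width).
#' @export
region_depth <- function(bam, region, bin_size = NULL, cfg = filter_config()) {
  if (is.character(region)) region <- parse_region(region)
  if (is.infinite(region$end)) {
    region$end <- unname(.bam_targets(bam)[[region$chrom]])
  }
  w <- .region_width(region)
  if (is.null(bin_size)) bin_size <- max(1L, ceiling(w / 500))
  stopifnot(bin_size >= 1)
  groups <- load_region_reads(bam, region, cfg, keep_seq = FALSE,
                              fetch_sa = FALSE)
  cov <- .per_base_coverage(groups, region)
  bins <- ceiling(w / bin_size)
  idx <- rep(seq_len(bins), each = bin_size, length.out = w)
  depth <- as.numeric(tapply(cov, idx, mean))
  structure(list(region = region, bin_size = bin_size,
                 bin_start = region$start + (seq_len(bins) - 1L) * bin_size,
                 depth = depth),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("<depth_profile> ", format(x$region), ": ", length(x$depth),
      " bins of ", x$bin_size, " bp, mean depth ",
      sprintf("%.2f", mean(x$depth)), "\n", sep = "")
  invisible(x)
}

#' Per-position base pileup over a short region
#'
#' Counts `A`/`C`/`G`/`T`/`N` from the filtered reads at each reference
#' position, plus deleted-base (`DEL`) counts and insertion events
#' (`INS`) attached to the column immediately left of the insertion.
#' Intended for base-level display; regions above ~200 bp become hard to
#' read and above `max_width` are refused.
#'
#' @param bam Path to an indexed BAM.
#' @param region A [region_spec()] or region string.
#' @param ref Optional indexed FASTA path; populates `ref_base`.
#' @param cfg A [filter_config()].
#' @param max_width Hard cap on region width (default 1000).
#' @return data.frame with columns `pos` (0-based), `ref_base`, `A`,
#'   `C`, `G`, `T`, `N`, `DEL`, `INS`.
#' @export
pileup_bases <- function(bam, region, ref = NULL, cfg = filter_config(),
                         max_width = 1000) {
  if (is.character(region)) region <- parse_region(region)
  w <- .region_width(region)
  if (w > max_width) {
    stop("region width ", w, " exceeds the pileup cap (", max_width, ")")
  }
  if (w > 200) {
    warning("base-level display is intended for intervals under 200 bp")
  }
  groups <- load_region_reads(bam, region, cfg, keep_seq = TRUE,
                              fetch_sa = FALSE)
  bases <- c("A", "C", "G", "T", "N")
  counts <- matrix(0L, nrow = w, ncol = 7L,
                   dimnames = list(NULL, c(bases, "DEL", "INS")))
  for (g in groups) {
    seg <- g$segments
    for (i in seq_len(nrow(seg))) {
      if (seg$chrom[i] != region$chrom || is.na(seg$seq[i])) next
      ops <- parse_cigar(seg$cigar[i])
      r <- seg$ref_start[i]; q <- 0L   # q indexes the record-oriented SEQ
      sq <- seg$seq[i]
      for (k in seq_len(nrow(ops))) {
        op <- ops$op[k]; len <- ops$len[k]
        if (op %in% c("M", "=", "X")) {
          s <- max(r, region$start); e <- min(r + len, region$end)
          if (e > s) {
            piece <- substring(sq, q + (s - r) + 1L, q + (e - r))
            ch <- strsplit(toupper(piece), "", fixed = TRUE)[[1]]
            ch[!ch %in% bases] <- "N"
            for (p in seq_along(ch)) {
              ridx <- s - region$start + p
              counts[ridx, ch[p]] <- counts[ridx, ch[p]] + 1L
            }
          }
          r <- r + len; q <- q + len
        } else if (op == "D") {
          s <- max(r, region$start); e <- min(r + len, region$end)
          if (e > s) {
            rows <- (s - region$start + 1L):(e - region$start)
            counts[rows, "DEL"] <- counts[rows, "DEL"] + 1L
          }
          r <- r + len
        } else if (op == "N") {
          r <- r + len
        } else if (op == "I") {
          anchor <- r - 1L           # left-anchor column of the insertion
          if (anchor >= region$start && anchor < region$end) {
            counts[anchor - region$start + 1L, "INS"] <-
              counts[anchor - region$start + 1L, "INS"] + 1L
          }
          q <- q + len
        } else if (op == "S") {
          q <- q + len
        }
      }
    }
  }
  ref_base <- rep(NA_character_, w)
  if (!is.null(ref)) {
    rb <- tryCatch(.reference_bases(ref, region), error = function(e) {
      warning("reference bases unavailable (", conditionMessage(e),
              "); proceeding without them")
      NULL
    })
    if (!is.null(rb)) ref_base <- rb
  }
  data.frame(pos = region$start + seq_len(w) - 1L, ref_base = ref_base,
             counts, stringsAsFactors = FALSE)
}

.reference_bases <- function(ref, region) {
  fa <- Rsamtools::FaFile(ref)
  if (!file.exists(paste0(ref, ".fai"))) Rsamtools::indexFa(ref)
  gr <- GenomicRanges::GRanges(region$chrom,
                               IRanges::IRanges(region$start + 1, region$end))
  seqs <- Rsamtools::scanFa(fa, param = gr)
  strsplit(toupper(as.character(seqs[[1]])), "", fixed = TRUE)[[1]]
}

#' Extract isoform exon chains from spliced alignments
#'
#' One chain per read: exons are maximal runs of reference-consuming
#' non-`N` CIGAR operations, introns are `N` gaps. Chains are sorted by
#' start so identical chains group together for display.
#'
#' @param bam Path to an indexed BAM of spliced (RNA/iso-seq) alignments.
#' @param region A [region_spec()] or region string.
#' @param cfg A [filter_config()].
#' @return data.frame of class `isoform_chains` with one row per exon:
#'   `read_name`, `strand`, `start`, `end` (0-based half-open).
#' @export
extract_isoforms <- function(bam, region, cfg = filter_config()) {
  if (is.character(region)) region <- parse_region(region)
  groups <- load_region_reads(bam, region, cfg, keep_seq = FALSE,
                              fetch_sa = FALSE)
  rows <- lapply(groups, function(g) {
    seg <- g$segments
    seg <- seg[seg$chrom == region$chrom, , drop = FALSE]
    if (!nrow(seg)) return(NULL)
    ex <- do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
      .cigar_exons(seg$cigar[i], seg$ref_start[i])
    }))
    ex <- ex[order(ex$start), , drop = FALSE]
    data.frame(read_name = g$read_name, strand = seg$strand[1],
               start = ex$start, end = ex$end, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (!length(rows)) {
    data.frame(read_name = character(), strand = character(),
               start = numeric(), end = numeric(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, c(rows, make.row.names = FALSE))
  }
  first <- if (nrow(out)) tapply(out$start, out$read_name, min)[unique(out$read_name)] else NULL
  if (nrow(out)) {
    ord <- order(first[out$read_name], out$read_name, out$start)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("isoform_chains", "data.frame"))
}
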