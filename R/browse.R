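# High-level drivers: one candidate record in, one figure + sidecar out.
# These wire ingest -> classify -> subsample -> layout -> render and are
# what the CLI subcommands call per record.

# display window(s) for a candidate: the SV interval padded for context;
# TRA gets one pane per breakend chromosome
.display_regions <- function(query, flank = NULL) {
  if (identical(query$sv_type, "TRA")) {
    fl <- flank %||% 5000
    list(region_spec(query$chrom, max(0, query$start - fl), query$start + fl),
         region_spec(query$mate_chrom, max(0, query$mate_pos - fl),
                     query$mate_pos + fl))
  } else if (is.na(query$sv_type)) {
    # plain region browse: the requested window is the display window
    fl <- flank %||% 0
    list(region_spec(query$chrom, max(0, query$start - fl), query$end + fl))
  } else {
    w <- max(1, query$end - query$start)
    fl <- flank %||% max(1000, round(0.5 * w))
    list(region_spec(query$chrom, max(0, query$start - fl), query$end + fl))
  }
}

#' Compose and render the SV panel for one candidate
#'
#' @param bams Character vector of indexed BAM paths (one stacked
#'   sub-panel each).
#' @param query One row of a query table ([read_sv_queries()]), or a
#'   [region_spec()]/region string for a plain region browse.
#' @param file Output figure path (sidecar at `<file>.json`).
#' @param spec A [panel_spec()].
#' @param fcfg A [filter_config()].
#' @param min_sv_length Minimum per-read event length.
#' @param max_reads Display read cap (subsampled deterministically).
#' @param gap Row-packing gap in bases.
#' @param tracks Optional annotation tracks ([overlap_features()] input).
#' @param seed Seed for read subsampling.
#' @param flank Display flank override, bases.
#' @return (Invisibly) the sidecar payload.
#' @export
browse_sv <- function(bams, query, file, spec = panel_spec(),
                      fcfg = filter_config(), min_sv_length = 50,
                      max_reads = 200, gap = 5, tracks = NULL, seed = 1,
                      flank = NULL) {
  .check_writable(file)
  if (is.character(query)) query <- parse_region(query)
  if (inherits(query, "region_spec")) {
    query <- .sv_query(query$label %||% format(query), query$chrom,
                       query$start, query$end, NA_character_)
  }
  regions <- .display_regions(query, flank)
  labels <- sub("\\.bam$", "", basename(bams), ignore.case = TRUE)
  samples <- list()
  for (b in seq_along(bams)) {
    groups <- load_regions_reads(bams[b], regions, fcfg, keep_seq = FALSE)
    structures <- classify_reads(groups, min_sv_length)
    keep <- subsample_reads(structures, max_reads, seed)
    groups <- groups[names(groups) %in% keep]
    panes <- lapply(regions, function(r) {
      spans <- read_spans(groups, r)
      list(region = r, assignment = assign_rows(spans, gap, max_reads))
    })
    samples[[labels[b]]] <- list(groups = groups, structures = structures,
                                 panes = panes)
  }
  ann <- if (!is.null(tracks)) overlap_features(tracks, regions[[1]]) else NULL
  render_sv_panel(samples, query, file, spec, annotations = ann,
                  min_sv_length = min_sv_length)
}

#' Compose and render a depth panel for a region
#'
#' @inheritParams browse_sv
#' @param region A [region_spec()] or region string.
#' @param bin_size Bin width in bases (default auto).
#' @return (Invisibly) the sidecar payload.
#' @export
browse_depth <- function(bams, region, file, spec = panel_spec(),
                         fcfg = filter_config(), bin_size = NULL) {
  .check_writable(file)
  labels <- sub("\\.bam$", "", basename(bams), ignore.case = TRUE)
  profiles <- lapply(seq_along(bams), function(b) {
    region_depth(bams[b], region, bin_size, fcfg)
  })
  names(profiles) <- labels
  render_depth_panel(profiles, file, spec)
}

#' Compose and render a base-level pileup panel for a short region
#'
#' @inheritParams browse_depth
#' @param ref Optional indexed FASTA for the reference row.
#' @return (Invisibly) the sidecar payload.
#' @export
browse_pileup <- function(bams, region, file, spec = panel_spec(),
                          fcfg = filter_config(), ref = NULL) {
  .check_writable(file)
  labels <- sub("\\.bam$", "", basename(bams), ignore.case = TRUE)
  cols <- lapply(seq_along(bams), function(b) {
    pileup_bases(bams[b], region, ref, fcfg)
  })
  names(cols) <- labels
  render_pileup_panel(cols, file, spec)
}

#' Compose and render an isoform panel for a region
#'
#' @inheritParams browse_depth
#' @param genepred Optional GenePred gene-model file for the gene lane.
#' @return (Invisibly) the sidecar payload.
#' @export
browse_isoforms <- function(bams, region, file, spec = panel_spec(),
                            fcfg = filter_config(), genepred = NULL) {
  .check_writable(file)
  if (is.character(region)) region <- parse_region(region)
  labels <- sub("\\.bam$", "", basename(bams), ignore.case = TRUE)
  chains <- lapply(seq_along(bams), function(b) {
    extract_isoforms(bams[b], region, fcfg)
  })
  names(chains) <- labels
  features <- if (!is.null(genepred)) {
    overlap_features(stats::setNames(list(genepred), "gene"), region)
  } else NULL
  render_isoform_panel(chains, file, spec, features = features)
}
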