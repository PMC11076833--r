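# Static figure composition. Every figure is accompanied by a JSON
# sidecar carrying the exact read/row/type/length content drawn, so the
# semantics are machine-checkable without pixel comparison and rendering
# can never silently alter analysis results.

#' SV display colors
#'
#' Fixed palette: REF gray, DEL red, INS purple, DUP green, INV blue,
#' TRA orange.
#' @return Named character vector of colors.
#' @export
sv_colors <- function() {
  c(REF = "gray55", DEL = "firebrick2", INS = "mediumpurple3",
    DUP = "forestgreen", INV = "dodgerblue3", TRA = "darkorange2")
}

#' Figure specification
#'
#' @param out_format `"png"` or `"pdf"`.
#' @param width,height Figure size in inches.
#' @param dpi Raster resolution for PNG.
#' @param title Optional figure title.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(out_format = c("png", "pdf"), width = 11,
                       height = 6.5, dpi = 96, title = NULL) {
  out_format <- match.arg(out_format)
  structure(list(out_format = out_format, width = width, height = height,
                 dpi = dpi, title = title), class = "panel_spec")
}

.check_writable <- function(file) {
  d <- dirname(file)
  if (!dir.exists(d)) stop("output directory '", d, "' does not exist")
  if (file.access(d, 2L) != 0L) stop("output directory '", d, "' is not writable")
  invisible(file)
}

.open_device <- function(file, spec) {
  if (spec$out_format == "png") {
    grDevices::png(file, width = spec$width, height = spec$height,
                   units = "in", res = spec$dpi)
  } else {
    grDevices::pdf(file, width = spec$width, height = spec$height)
  }
}

.sidecar_path <- function(file) paste0(file, ".json")

.write_sidecar <- function(file, payload) {
  jsonlite::write_json(payload, .sidecar_path(file), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(.sidecar_path(file))
}

# sub-intervals of a segment split at its DEL cigar events, plus the gaps
.segment_parts <- function(seg_row, min_sv_length) {
  ev <- cigar_events(seg_row$cigar, seg_row$ref_start, min_sv_length)
  dels <- ev[ev$kind == "DEL", , drop = FALSE]
  if (!nrow(dels)) {
    return(list(parts = data.frame(start = seg_row$ref_start,
                                   end = seg_row$ref_end),
                gaps = dels))
  }
  dels <- dels[order(dels$ref_pos), , drop = FALSE]
  starts <- c(seg_row$ref_start, dels$ref_pos + dels$length)
  ends <- c(dels$ref_pos, seg_row$ref_end)
  list(parts = data.frame(start = starts, end = ends), gaps = dels)
}

# draw one sample's read lanes into the current plot; returns sidecar rows
.draw_reads <- function(assignment, structures, groups, region,
                        min_sv_length, cols) {
  side <- list()
  for (i in seq_len(nrow(assignment))) {
    nm <- assignment$read_name[i]
    y <- -assignment$row[i]
    st <- structures[[nm]]
    col <- cols[[st$sv_type]]
    seg <- groups[[nm]]$segments
    seg <- seg[seg$chrom == region$chrom, , drop = FALSE]
    seg <- seg[order(seg$ref_start), , drop = FALSE]
    labels <- numeric(0)
    for (k in seq_len(nrow(seg))) {
      sp <- .segment_parts(seg[k, ], min_sv_length)
      graphics::rect(sp$parts$start, y - 0.34, sp$parts$end, y + 0.34,
                     col = col, border = NA)
      if (nrow(sp$gaps)) {
        # cigar-joined events: solid connector with the length printed
        for (g in seq_len(nrow(sp$gaps))) {
          x0 <- sp$gaps$ref_pos[g]; x1 <- x0 + sp$gaps$length[g]
          graphics::segments(x0, y, x1, y, col = col, lwd = 1.4)
          graphics::text((x0 + x1) / 2, y + 0.42, sp$gaps$length[g],
                         cex = 0.55, col = "purple4")
          labels <- c(labels, sp$gaps$length[g])
        }
      }
      if (seg$strand[k] == "-") {
        graphics::points(seg$ref_start[k], y, pch = "<", cex = 0.6, col = col)
      }
      ce <- cigar_events(seg$cigar[k], seg$ref_start[k], min_sv_length)
      cl <- ce[ce$kind == "CLIP", , drop = FALSE]
      if (nrow(cl)) {
        graphics::points(cl$ref_pos, rep(y, nrow(cl)), pch = 17,
                         col = "red", cex = 0.5)
      }
    }
    # split adjacencies: dashed connector across the gap with the length
    if (nrow(seg) >= 2L) {
      for (k in seq_len(nrow(seg) - 1L)) {
        x0 <- seg$ref_end[k]; x1 <- seg$ref_start[k + 1L]
        graphics::segments(x0, y, x1, y, col = col, lty = 2)
        if (st$sv_length > 0) {
          graphics::text((x0 + x1) / 2, y + 0.42, st$sv_length,
                         cex = 0.55, col = "purple4")
          labels <- c(labels, st$sv_length)
        }
      }
    }
    if (st$sv_type != "REF" && st$sv_length > 0 && nrow(seg) < 2L) {
      labels <- unique(c(labels, st$sv_length))
    }
    side[[length(side) + 1L]] <- list(
      read = nm, row = assignment$row[i],
      start = assignment$start[i], end = assignment$end[i],
      sv_type = st$sv_type, sv_length = st$sv_length,
      labels = as.list(labels))
  }
  side
}

.draw_annotation_lane <- function(features, region, y) {
  if (is.null(features) || !nrow(features)) return(invisible())
  tracks <- unique(features$track)
  for (t in seq_along(tracks)) {
    f <- features[features$track == tracks[t], , drop = FALSE]
    yy <- y - (t - 1) * 0.9
    graphics::rect(f$start, yy - 0.3, f$end, yy + 0.3, col = "gray35",
                   border = NA)
    graphics::text((f$start + f$end) / 2, yy + 0.45, f$name, cex = 0.5)
    graphics::mtext(tracks[t], side = 2, at = yy, las = 1, cex = 0.5)
  }
}

#' Render the SV read panel
#'
#' One horizontal lane per layout row; SV-supporting reads are drawn in
#' their SV-type color with dashed connectors across split-alignment gaps
#' and the event length printed at the midpoint; CIGAR-joined deletions
#' use solid connectors; terminal soft-clips are marked in red.
#' Translocations render two side-by-side chromosome panes with reads
#' paired across panes. A JSON sidecar (same path + `.json`) records the
#' reads, rows, types, lengths and printed labels per pane.
#'
#' @param samples Named list (one entry per BAM label), each a list with
#'   elements `groups` (read groups), `structures` (classified reads) and
#'   `panes` (list per pane: `region` and `assignment`).
#' @param query One query row (see [read_sv_queries()]) or `NULL`.
#' @param file Output figure path.
#' @param spec A [panel_spec()].
#' @param annotations Optional feature data.frame ([overlap_features()]).
#' @param min_sv_length Event length used when splitting segments for
#'   display.
#' @return (Invisibly) the sidecar payload.
#' @export
render_sv_panel <- function(samples, query, file, spec = panel_spec(),
                            annotations = NULL, min_sv_length = 50) {
  .check_writable(file)
  cols <- sv_colors()
  n_panes <- length(samples[[1]]$panes)
  .open_device(file, spec)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(length(samples), n_panes),
                mar = c(2.5, 3.5, 1.6, 0.6))
  payload_samples <- list()
  for (s in names(samples)) {
    sm <- samples[[s]]
    pane_payloads <- list()
    for (p in seq_along(sm$panes)) {
      pane <- sm$panes[[p]]
      region <- pane$region
      assignment <- pane$assignment
      nr <- max(1L, n_rows(assignment))
      ann_rows <- if (!is.null(annotations) && p == 1L)
        length(unique(annotations$track)) else 0L
      graphics::plot(NA, xlim = c(region$start, region$end),
                     ylim = c(-(nr + 1 + ann_rows), 0.6),
                     xlab = "", ylab = "", yaxt = "n", xaxs = "i",
                     main = sprintf("%s | %s", s, format(region)),
                     cex.main = 0.8, cex.axis = 0.7)
      side <- .draw_reads(assignment, sm$structures, sm$groups, region,
                          min_sv_length, cols)
      if (ann_rows) .draw_annotation_lane(annotations, region, -(nr + 1))
      pane_payloads[[p]] <- list(chrom = region$chrom,
                                 start = region$start, end = region$end,
                                 reads = side)
    }
    payload_samples[[s]] <- list(label = s, panes = pane_payloads)
  }
  payload <- list(
    panel = "sv",
    query = if (is.null(query)) NULL else as.list(query),
    colors = as.list(cols),
    samples = payload_samples)
  .write_sidecar(file, payload)
  invisible(payload)
}

#' Render a binned depth panel
#'
#' @param profiles A `depth_profile` or a named list of them (one stacked
#'   sub-panel per sample, in declared order).
#' @param file Output figure path.
#' @param spec A [panel_spec()].
#' @return (Invisibly) the sidecar payload; the sidecar bin values equal
#'   the profile depths exactly.
#' @export
render_depth_panel <- function(profiles, file, spec = panel_spec()) {
  .check_writable(file)
  if (inherits(profiles, "depth_profile")) profiles <- list(sample = profiles)
  .open_device(file, spec)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(length(profiles), 1), mar = c(2.5, 4, 1.6, 0.6))
  entries <- list()
  for (s in names(profiles)) {
    pr <- profiles[[s]]
    x <- pr$bin_start + pr$bin_size / 2
    graphics::plot(x, pr$depth, type = "h", lwd = 2, col = "steelblue4",
                   xlab = "", ylab = "depth",
                   main = sprintf("%s | %s", s, format(pr$region)),
                   cex.main = 0.8, cex.axis = 0.7)
    entries[[s]] <- list(label = s, chrom = pr$region$chrom,
                         bin_size = pr$bin_size,
                         bin_start = pr$bin_start, depth = pr$depth)
  }
  payload <- list(panel = "depth", samples = entries)
  .write_sidecar(file, payload)
  invisible(payload)
}

#' Render a base-level pileup panel
#'
#' Per-base letters and counts, with a reference row when reference bases
#' are available.
#'
#' @param columns data.frame from [pileup_bases()] or a named list of
#'   them (stacked per sample).
#' @param file Output figure path.
#' @param spec A [panel_spec()].
#' @return (Invisibly) the sidecar payload.
#' @export
render_pileup_panel <- function(columns, file, spec = panel_spec()) {
  .check_writable(file)
  if (is.data.frame(columns)) columns <- list(sample = columns)
  base_cols <- c(A = "forestgreen", C = "dodgerblue3", G = "darkorange2",
                 T = "firebrick2", N = "gray40")
  .open_device(file, spec)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(length(columns), 1), mar = c(2.5, 4, 1.6, 0.6))
  entries <- list()
  for (s in names(columns)) {
    cc <- columns[[s]]
    depth_max <- max(1, rowSums(cc[, c("A", "C", "G", "T", "N", "DEL")]))
    graphics::plot(NA, xlim = range(cc$pos) + c(0, 1),
                   ylim = c(-1.5, depth_max),
                   xlab = "", ylab = "count", main = s,
                   cex.main = 0.8, cex.axis = 0.7)
    for (i in seq_len(nrow(cc))) {
      y0 <- 0
      for (b in c("A", "C", "G", "T", "N")) {
        n <- cc[[b]][i]
        if (n > 0) {
          graphics::rect(cc$pos[i], y0, cc$pos[i] + 0.9, y0 + n,
                         col = base_cols[[b]], border = NA)
          y0 <- y0 + n
        }
      }
      if (cc$DEL[i] > 0) {
        graphics::rect(cc$pos[i], y0, cc$pos[i] + 0.9, y0 + cc$DEL[i],
                       col = "gray80", border = NA)
      }
      if (cc$INS[i] > 0) {
        graphics::points(cc$pos[i] + 0.45, -0.4, pch = 6, col = "purple", cex = 0.6)
      }
      if (!is.na(cc$ref_base[i])) {
        graphics::text(cc$pos[i] + 0.45, -1, cc$ref_base[i], cex = 0.5,
                       col = base_cols[[cc$ref_base[i]]] %||% "gray40")
      }
    }
    entries[[s]] <- list(label = s, columns = cc)
  }
  payload <- list(panel = "pileup", samples = entries)
  .write_sidecar(file, payload)
  invisible(payload)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render an isoform panel
#'
#' Exon boxes joined by intron lines, one lane per read chain, with an
#' optional gene-model lane.
#'
#' @param chains An `isoform_chains` data.frame ([extract_isoforms()]) or
#'   a named list of them (stacked per sample).
#' @param file Output figure path.
#' @param spec A [panel_spec()].
#' @param features Optional gene features for the annotation lane.
#' @return (Invisibly) the sidecar payload; sidecar exon coordinates
#'   equal the extraction output.
#' @export
render_isoform_panel <- function(chains, file, spec = panel_spec(),
                                 features = NULL) {
  .check_writable(file)
  if (is.data.frame(chains)) chains <- list(sample = chains)
  .open_device(file, spec)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(length(chains), 1), mar = c(2.5, 3.5, 1.6, 0.6))
  entries <- list()
  for (s in names(chains)) {
    ch <- chains[[s]]
    reads <- unique(ch$read_name)
    nr <- max(1L, length(reads))
    xr <- if (nrow(ch)) range(c(ch$start, ch$end)) else c(0, 1)
    ann_rows <- if (!is.null(features) && nrow(features)) 1L else 0L
    graphics::plot(NA, xlim = xr, ylim = c(-(nr + 1 + ann_rows), 0.5),
                   xlab = "", ylab = "", yaxt = "n", main = s,
                   cex.main = 0.8, cex.axis = 0.7)
    side <- list()
    for (i in seq_along(reads)) {
      e <- ch[ch$read_name == reads[i], , drop = FALSE]
      y <- -i
      graphics::segments(min(e$start), y, max(e$end), y, col = "gray40")
      graphics::rect(e$start, y - 0.3, e$end, y + 0.3, col = "royalblue3",
                     border = NA)
      side[[i]] <- list(read = reads[i], strand = e$strand[1],
                        exons = lapply(seq_len(nrow(e)), function(k) {
                          list(start = e$start[k], end = e$end[k])
                        }))
    }
    if (ann_rows) .draw_annotation_lane(features,
                                        region_spec("x", xr[1], xr[2] + 1),
                                        -(nr + 1))
    entries[[s]] <- list(label = s, chains = side)
  }
  payload <- list(panel = "isoform", samples = entries)
  .write_sidecar(file, payload)
  invisible(payload)
}
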