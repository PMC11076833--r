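# Breakpoint engine: derive breakpoints from CIGAR strings and split
# alignments, then interpret each read's SV structure.
#
# Split-read signatures for a consecutive (query-ordered) segment pair,
# with rgap the signed reference gap along the strand and qgap the signed
# query gap:
#   different chromosomes            -> TRA
#   opposite strands, same chrom     -> INV (span between the junctions)
#   same strand, rgap <= -L          -> DUP (reference re-visit; tandem)
#   same strand, rgap - qgap >=  L   -> DEL
#   same strand, qgap - rgap >=  L   -> INS
# A re-visit also reads as an insertion of the duplicated bases, so the
# DUP test precedes DEL/INS: the tandem-duplication signature wins.

.EMPTY_EVENTS <- data.frame(
  type = character(), chrom_a = character(), pos_a = numeric(),
  chrom_b = character(), pos_b = numeric(), orient = character(),
  source = character(), length = numeric(), stringsAsFactors = FALSE)

.event_row <- function(type, chrom_a, pos_a, chrom_b, pos_b, orient,
                       source, length) {
  # canonical genome ordering of the two joined loci
  if (chrom_a > chrom_b || (chrom_a == chrom_b && pos_a > pos_b)) {
    tmp <- chrom_a; chrom_a <- chrom_b; chrom_b <- tmp
    tmp <- pos_a; pos_a <- pos_b; pos_b <- tmp
  }
  data.frame(type = type, chrom_a = chrom_a, pos_a = pos_a,
             chrom_b = chrom_b, pos_b = pos_b, orient = orient,
             source = source, length = length, stringsAsFactors = FALSE)
}

# junction reference coordinates of a query-ordered segment pair:
# j1 = coordinate of s1 at its query end, j2 = of s2 at its query start
.pair_junctions <- function(s1, s2) {
  j1 <- if (s1$strand == "+") s1$ref_end else s1$ref_start
  j2 <- if (s2$strand == "+") s2$ref_start else s2$ref_end
  c(j1 = j1, j2 = j2)
}

.pair_event <- function(s1, s2, min_sv_length) {
  orient <- paste0(s1$strand, s2$strand)
  j <- .pair_junctions(s1, s2)
  if (s1$chrom != s2$chrom) {
    return(.event_row("TRA", s1$chrom, j[["j1"]], s2$chrom, j[["j2"]],
                      orient, "split", 0))
  }
  if (s1$strand != s2$strand) {
    span <- abs(j[["j2"]] - j[["j1"]])
    type <- if (span >= min_sv_length) "INV" else "NONE"
    return(.event_row(type, s1$chrom, min(j), s1$chrom, max(j), orient,
                      "split", span))
  }
  rgap <- if (s1$strand == "+") s2$ref_start - s1$ref_end
          else s1$ref_start - s2$ref_end
  qgap <- s2$query_start - s1$query_end
  if (rgap <= -min_sv_length) {
    type <- "DUP"; len <- -rgap
  } else if (rgap - qgap >= min_sv_length) {
    type <- "DEL"; len <- rgap - qgap
  } else if (qgap - rgap >= min_sv_length) {
    type <- "INS"; len <- qgap - rgap
  } else {
    type <- "NONE"; len <- abs(j[["j2"]] - j[["j1"]])
  }
  .event_row(type, s1$chrom, min(j), s1$chrom, max(j), orient, "split", len)
}

#' Breakpoints from the split alignments of one read
#'
#' Emits one breakpoint per consecutive (query-ordered) segment pair,
#' joining the two reference coordinates at the adjacency; intra-
#' chromosomal breakpoints are reported in canonical genome order.
#'
#' @param group A `read_group` with at least two segments.
#' @param min_sv_length Minimum event length used for typing.
#' @return data.frame with columns `chrom_a`, `pos_a`, `chrom_b`, `pos_b`,
#'   `orient` (strand pair, e.g. `"++"`), `source` (`"split"`), and the
#'   provisional `type`/`length` of the adjacency (`type = "NONE"` when no
#'   signature reaches `min_sv_length`).
#' @export
split_breakpoints <- function(group, min_sv_length = 50) {
  seg <- group$segments
  if (nrow(seg) < 2L) stop("split_breakpoints needs a group with >= 2 segments")
  out <- lapply(seq_len(nrow(seg) - 1L), function(i) {
    .pair_event(seg[i, ], seg[i + 1L, ], min_sv_length)
  })
  do.call(rbind, out)
}

# all qualifying typed events of one read (cigar + split sources)
.read_events <- function(group, min_sv_length) {
  seg <- group$segments
  ev <- list(.EMPTY_EVENTS)
  for (i in seq_len(nrow(seg))) {
    ce <- cigar_events(seg$cigar[i], seg$ref_start[i], min_sv_length)
    ce <- ce[ce$kind %in% c("DEL", "INS"), , drop = FALSE]
    if (nrow(ce)) {
      orient <- paste0(seg$strand[i], seg$strand[i])
      ev[[length(ev) + 1L]] <- do.call(rbind, lapply(seq_len(nrow(ce)), function(k) {
        pb <- if (ce$kind[k] == "DEL") ce$ref_pos[k] + ce$length[k] else ce$ref_pos[k]
        .event_row(ce$kind[k], seg$chrom[i], ce$ref_pos[k], seg$chrom[i],
                   pb, orient, "cigar", ce$length[k])
      }))
    }
  }
  if (nrow(seg) >= 2L) {
    sp <- split_breakpoints(group, min_sv_length)
    ev[[length(ev) + 1L]] <- sp[sp$type != "NONE", , drop = FALSE]
  }
  do.call(rbind, ev)
}

.read_has_clip <- function(group, min_sv_length) {
  seg <- group$segments
  any(vapply(seq_len(nrow(seg)), function(i) {
    ce <- cigar_events(seg$cigar[i], seg$ref_start[i], min_sv_length)
    any(ce$kind == "CLIP")
  }, logical(1)))
}

#' Interpret the SV structure carried by one read
#'
#' Combines CIGAR-derived deletion/insertion events with split-read
#' signatures over consecutive segment pairs. A read with no qualifying
#' event is `REF`. Multi-event reads keep every breakpoint; the read's
#' label (`sv_type`) is the type of the largest event, with translocation
#' junctions (length 0 by convention) labelling the read only when no
#' sized event is present.
#'
#' @param group A `read_group` from [load_region_reads()].
#' @param min_sv_length Minimum SV length in bases (default 50).
#' @return An object of class `read_structure`: fields `read_name`,
#'   `sv_type` (`REF`/`DEL`/`INS`/`DUP`/`INV`/`TRA`), `sv_length` (0 for
#'   `REF`/`TRA`), `events` (typed breakpoints), `has_clip`.
#' @export
classify_read_structure <- function(group, min_sv_length = 50) {
  ev <- .read_events(group, min_sv_length)
  if (!nrow(ev)) {
    sv_type <- "REF"; sv_length <- 0
  } else {
    sized <- ev[ev$length > 0, , drop = FALSE]
    if (nrow(sized)) {
      best <- sized[which.max(sized$length), ]
      sv_type <- best$type; sv_length <- best$length
    } else {
      sv_type <- "TRA"; sv_length <- 0
    }
  }
  structure(list(read_name = group$read_name,
                 sv_type = sv_type,
                 sv_length = sv_length,
                 events = ev,
                 has_clip = .read_has_clip(group, min_sv_length)),
            class = "read_structure")
}

#' @export
print.read_structure <- function(x, ...) {
  cat("<read_structure> ", x$read_name, ": ", x$sv_type,
      if (x$sv_length > 0) paste0(" (", x$sv_length, " bp)") else "",
      ", ", nrow(x$events), " breakpoint event(s)",
      if (x$has_clip) ", clipped" else "", "\n", sep = "")
  invisible(x)
}

#' Classify every read group
#'
#' @param groups List of `read_group` objects.
#' @param min_sv_length Minimum SV length in bases.
#' @return Named list of `read_structure` objects.
#' @export
classify_reads <- function(groups, min_sv_length = 50) {
  out <- lapply(groups, classify_read_structure, min_sv_length = min_sv_length)
  names(out) <- vapply(out, `[[`, "", "read_name")
  out
}

#' Cluster breakpoints across reads
#'
#' Single-linkage clustering of same-type, same-chromosome-pair
#' breakpoints: two breakpoints link when both coordinates differ by at
#' most `tol`. Each cluster reports median positions and length, the
#' number of breakpoint records, and the distinct supporting reads.
#'
#' @param structures List of `read_structure` objects.
#' @param tol Linkage tolerance in bases (default 1000).
#' @return data.frame with columns `sv_type`, `chrom_a`, `chrom_b`,
#'   `pos_a`, `pos_b`, `sv_length` (medians), `n_bp` (breakpoints in the
#'   cluster), `support` (distinct reads) and `reads`
#'   (comma-separated read names).
#' @export
cluster_breakpoints <- function(structures, tol = 1000) {
  empty <- data.frame(sv_type = character(), chrom_a = character(),
                      chrom_b = character(), pos_a = numeric(),
                      pos_b = numeric(), sv_length = numeric(),
                      n_bp = integer(), support = integer(),
                      reads = character(), stringsAsFactors = FALSE)
  if (!length(structures)) return(empty)
  ev <- do.call(rbind, lapply(structures, function(s) {
    if (!nrow(s$events)) return(NULL)
    cbind(s$events, read_name = s$read_name, stringsAsFactors = FALSE)
  }))
  if (is.null(ev) || !nrow(ev)) return(empty)

  out <- list()
  for (key in unique(paste(ev$type, ev$chrom_a, ev$chrom_b))) {
    e <- ev[paste(ev$type, ev$chrom_a, ev$chrom_b) == key, , drop = FALSE]
    n <- nrow(e)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
      if (abs(e$pos_a[i] - e$pos_a[j]) <= tol &&
          abs(e$pos_b[i] - e$pos_b[j]) <= tol) {
        parent[find(i)] <- find(j)
      }
    }
    comp <- vapply(seq_len(n), find, 0L)
    for (cid in unique(comp)) {
      m <- e[comp == cid, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        sv_type = m$type[1], chrom_a = m$chrom_a[1], chrom_b = m$chrom_b[1],
        pos_a = stats::median(m$pos_a), pos_b = stats::median(m$pos_b),
        sv_length = stats::median(m$length),
        n_bp = nrow(m), support = length(unique(m$read_name)),
        reads = paste(sort(unique(m$read_name)), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom_a, res$pos_a), , drop = FALSE]
}
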