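# Alignment ingest: fetch reads over a region, group primary +
# supplementary segments per read, and apply the per-segment quality
# filters (mean base quality, identity, mapping length, mapq).

#' Quality-filter configuration for alignment ingest
#'
#' Defaults implement the standard long-read evidence filters: mean read
#' quality at least Q20, mapping identity at least 60%, mapped reference
#' span at least 100 bp. `min_mapq` is exposed separately and defaults to
#' 0 (no mapq filter).
#'
#' @param min_mean_baseq Minimum mean Phred base quality per segment.
#' @param min_identity Minimum alignment identity (fraction in `[0,1]`).
#' @param min_map_len Minimum reference span of a segment, in bases.
#' @param min_mapq Minimum mapping quality.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_mean_baseq = 20, min_identity = 0.60,
                          min_map_len = 100, min_mapq = 0) {
  stopifnot(min_mean_baseq >= 0, min_identity >= 0, min_map_len >= 0,
            min_mapq >= 0)
  structure(list(min_mean_baseq = min_mean_baseq,
                 min_identity = min_identity,
                 min_map_len = min_map_len,
                 min_mapq = min_mapq),
            class = "filter_config")
}

#' Mean Phred base quality
#'
#' Arithmetic mean on the Phred scale (not in error-probability space).
#' Reads stored without base qualities (`"*"`, common for PacBio HiFi
#' BAMs) yield `NA` with a warning; such segments pass the quality filter.
#'
#' @param qual Either a numeric vector of Phred scores or a Phred+33
#'   encoded quality string.
#' @return Mean Phred quality, or `NA_real_` when qualities are absent.
#' @export
mean_base_quality <- function(qual) {
  if (is.character(qual)) {
    if (length(qual) != 1L || !nzchar(qual) || qual == "*") {
      warning("missing base qualities; segment passes the quality filter")
      return(NA_real_)
    }
    return(mean(utf8ToInt(qual) - 33L))
  }
  if (!length(qual)) {
    warning("empty quality vector; segment passes the quality filter")
    return(NA_real_)
  }
  mean(as.numeric(qual))
}

#' Alignment identity from CIGAR and edit distance
#'
#' `identity = 1 - NM / aligned_length` with
#' `aligned_length = matches + insertions + deletions` consumed by the
#' alignment, clamped to `[0, 1]`. When the edit-distance (`NM`) tag is
#' unavailable the identity falls back to the CIGAR alone
#' (`1 - (X + I + D)/aligned_length`, so plain-`M` CIGARs score 1) with a
#' warning.
#'
#' @param cigar CIGAR string of the segment.
#' @param edit_distance `NM`-style edit distance, or `NA`.
#' @return Identity fraction in `[0, 1]`.
#' @export
alignment_identity <- function(cigar, edit_distance = NA) {
  ops <- parse_cigar(cigar)
  alen <- .cigar_aligned_len(ops)
  if (alen <= 0) stop("segment has no aligned bases: ", cigar)
  if (is.na(edit_distance)) {
    warning("edit-distance tag missing; identity computed from CIGAR ops only")
    mism <- sum(ops$len[ops$op %in% c("X", "I", "D")])
    return(max(0, min(1, 1 - mism / alen)))
  }
  max(0, min(1, 1 - edit_distance / alen))
}

# --- internal record -> segment construction -------------------------------

.segment_row <- function(read_name, chrom, pos1, strand, mapq, cigar,
                         mean_baseq, nm, is_supp, seq = NA_character_) {
  ops <- parse_cigar(cigar)
  ref_start <- pos1 - 1
  ref_len <- .cigar_ref_len(ops)
  clips <- .cigar_clips(ops)
  q_aln <- .cigar_query_aligned(ops)
  rl <- .cigar_read_length(ops)
  if (strand == "+") { qs <- clips[["left"]]; } else { qs <- clips[["right"]] }
  ident <- suppressWarnings(alignment_identity(cigar, nm))
  data.frame(
    read_name = read_name, chrom = chrom,
    ref_start = ref_start, ref_end = ref_start + ref_len,
    query_start = qs, query_end = qs + q_aln,
    strand = strand, mapq = as.numeric(mapq),
    mean_baseq = mean_baseq, identity = ident,
    is_supplementary = is_supp, cigar = cigar,
    read_length = rl, seq = seq,
    stringsAsFactors = FALSE
  )
}

# parse one SA tag ("chrom,pos,strand,CIGAR,mapQ,NM;...") into segment rows
.sa_segments <- function(read_name, sa, mean_baseq) {
  entries <- strsplit(sa, ";", fixed = TRUE)[[1]]
  entries <- entries[nzchar(entries)]
  rows <- lapply(entries, function(e) {
    f <- strsplit(e, ",", fixed = TRUE)[[1]]
    if (length(f) < 6L) return(NULL)
    .segment_row(read_name, f[1], as.numeric(f[2]), f[3],
                 as.numeric(f[5]), f[4], mean_baseq, as.numeric(f[6]),
                 is_supp = TRUE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) NULL else do.call(rbind, rows)
}

.segment_passes <- function(seg, cfg) {
  (is.na(seg$mean_baseq) | seg$mean_baseq >= cfg$min_mean_baseq) &
    (seg$identity >= cfg$min_identity) &
    ((seg$ref_end - seg$ref_start) >= cfg$min_map_len) &
    (seg$mapq >= cfg$min_mapq)
}

# resolve query-space overlaps between segments of one read: the
# lower-mapq segment is trimmed; ties trim the later (by query) segment
.trim_group_segments <- function(seg) {
  seg <- seg[order(seg$query_start, seg$query_end), , drop = FALSE]
  repeat {
    n <- nrow(seg)
    if (n < 2L) break
    changed <- FALSE
    for (i in 2:n) {
      ov <- seg$query_end[i - 1] - seg$query_start[i]
      if (ov <= 0) next
      victim <- if (seg$mapq[i] < seg$mapq[i - 1]) i else if (seg$mapq[i - 1] < seg$mapq[i]) i - 1L else i
      if (victim == i) {
        seg$query_start[i] <- seg$query_start[i] + ov
        if (seg$strand[i] == "+") seg$ref_start[i] <- seg$ref_start[i] + ov
        else seg$ref_end[i] <- seg$ref_end[i] - ov
      } else {
        seg$query_end[i - 1] <- seg$query_end[i - 1] - ov
        if (seg$strand[i - 1] == "+") seg$ref_end[i - 1] <- seg$ref_end[i - 1] - ov
        else seg$ref_start[i - 1] <- seg$ref_start[i - 1] + ov
      }
      changed <- TRUE
    }
    keep <- seg$query_end > seg$query_start & seg$ref_end > seg$ref_start
    seg <- seg[keep, , drop = FALSE]
    seg <- seg[order(seg$query_start, seg$query_end), , drop = FALSE]
    if (!changed) break
  }
  seg
}

.new_read_group <- function(seg) {
  structure(list(read_name = seg$read_name[1],
                 read_length = max(seg$read_length),
                 segments = seg),
            class = "read_group")
}

#' @export
print.read_group <- function(x, ...) {
  cat("<read_group> ", x$read_name, ": ", nrow(x$segments),
      " segment(s), read length ", x$read_length, "\n", sep = "")
  invisible(x)
}

.bam_index_path <- function(bam) {
  for (cand in c(paste0(bam, ".bai"), sub("\\.bam$", ".bai", bam))) {
    if (file.exists(cand)) return(cand)
  }
  NA_character_
}

.bam_targets <- function(bam) {
  Rsamtools::scanBamHeader(bam)[[1]]$targets
}

#' Load filtered, grouped reads over a region
#'
#' Fetches all primary and supplementary alignments overlapping `region`
#' from a coordinate-sorted, indexed BAM, applies the per-segment quality
#' filters, and groups surviving segments per read. Far-away partner
#' segments of surviving reads (e.g. the other end of a translocation)
#' are reconstructed genome-wide from their `SA` tags so they appear in
#' the group even when outside the region. Query coordinates of every
#' segment are strand-corrected to the original read orientation, so
#' segments of one read order consistently by `query_start`.
#'
#' A read survives if at least one of its segments overlapping the region
#' passes all filters; failing segments are dropped individually.
#'
#' @param bam Path to an indexed BAM file.
#' @param region A [region_spec()] (or region string).
#' @param cfg A [filter_config()].
#' @param keep_seq Keep the record sequences (needed for base-level
#'   pileup; disable to save memory).
#' @param fetch_sa Reconstruct out-of-region partner segments from SA tags.
#' @return A list of `read_group` objects, one per surviving read.
#' @export
load_region_reads <- function(bam, region, cfg = filter_config(),
                              keep_seq = TRUE, fetch_sa = TRUE) {
  groups <- load_regions_reads(bam, list(region), cfg,
                               keep_seq = keep_seq, fetch_sa = fetch_sa)
  groups
}

#' Load filtered, grouped reads over several regions, merged per read
#'
#' Same contract as [load_region_reads()] but segments fetched from all
#' regions are merged into one group per read (used for translocations,
#' whose two breakends live on different chromosomes).
#'
#' @inheritParams load_region_reads
#' @param regions List of [region_spec()] objects (or region strings).
#' @return A list of `read_group` objects.
#' @export
load_regions_reads <- function(bam, regions, cfg = filter_config(),
                               keep_seq = TRUE, fetch_sa = TRUE) {
  if (is.na(.bam_index_path(bam))) {
    stop("BAM index not found for '", bam,
         "'; create one with `samtools index ", bam, "`")
  }
  targets <- .bam_targets(bam)
  regions <- lapply(regions, function(r) {
    if (is.character(r)) r <- parse_region(r)
    if (!r$chrom %in% names(targets)) {
      stop("chromosome '", r$chrom, "' absent from BAM header")
    }
    tlen <- unname(targets[[r$chrom]])
    if (is.infinite(r$end)) r$end <- tlen
    if (r$end > tlen) {
      warning("region ", format(r), " extends past contig end (", tlen,
              "); clipped")
      r$end <- tlen
      if (r$start >= r$end) stop("region lies entirely past contig end")
    }
    r
  })

  which <- GenomicRanges::GRanges(
    vapply(regions, `[[`, "", "chrom"),
    IRanges::IRanges(
      start = vapply(regions, function(r) r$start + 1, 0),
      end = vapply(regions, function(r) r$end, 0)))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "strand", "pos", "mapq", "cigar", "seq", "qual"),
    tag = c("NM", "SA"),
    which = which,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE))
  res <- Rsamtools::scanBam(bam, param = param)

  chroms <- rep(vapply(regions, `[[`, "", "chrom"),
                vapply(res, function(x) length(x$qname), 0L))
  rec <- list(
    qname = unlist(lapply(res, `[[`, "qname"), use.names = FALSE),
    flag = unlist(lapply(res, `[[`, "flag"), use.names = FALSE),
    pos = unlist(lapply(res, `[[`, "pos"), use.names = FALSE),
    mapq = unlist(lapply(res, `[[`, "mapq"), use.names = FALSE),
    cigar = unlist(lapply(res, `[[`, "cigar"), use.names = FALSE),
    seq = unlist(lapply(res, function(x) as.character(x$seq)), use.names = FALSE),
    qual = unlist(lapply(res, function(x) as.character(x$qual)), use.names = FALSE),
    nm = unlist(lapply(res, function(x) {
      v <- x$tag$NM
      if (is.null(v)) rep(NA_real_, length(x$qname)) else as.numeric(v)
    }), use.names = FALSE),
    sa = unlist(lapply(res, function(x) {
      v <- x$tag$SA
      if (is.null(v)) rep(NA_character_, length(x$qname)) else as.character(v)
    }), use.names = FALSE),
    chrom = chroms)
  n <- length(rec$qname)
  if (!n) return(list())

  # the same record can be fetched by two overlapping windows
  key <- paste(rec$qname, rec$chrom, rec$pos, rec$flag, rec$cigar)
  keep <- !duplicated(key)

  segs <- vector("list", n)
  baseq_cache <- new.env(parent = emptyenv())
  for (i in which(keep)) {
    mq <- suppressWarnings(mean_base_quality(rec$qual[i]))
    strand <- if (bitwAnd(rec$flag[i], 16L)) "-" else "+"
    segs[[i]] <- .segment_row(
      rec$qname[i], rec$chrom[i], rec$pos[i], strand, rec$mapq[i],
      rec$cigar[i], mq, rec$nm[i],
      is_supp = bitwAnd(rec$flag[i], 2048L) > 0L,
      seq = if (keep_seq) rec$seq[i] else NA_character_)
    cur <- get0(rec$qname[i], envir = baseq_cache)
    if ((is.null(cur) || is.na(cur)) && !is.na(mq)) {
      assign(rec$qname[i], mq, envir = baseq_cache)
    }
  }
  seg <- do.call(rbind, segs[!vapply(segs, is.null, logical(1))])
  if (is.na(seg$identity[1]) || anyNA(seg$identity)) {
    # only possible when a cigar had no aligned bases; guarded in .segment_row
    seg$identity[is.na(seg$identity)] <- 1
  }
  seg$pass <- .segment_passes(seg, cfg)

  # a read survives if >=1 passing segment overlaps a queried region
  overlaps_region <- vapply(seq_len(nrow(seg)), function(i) {
    any(vapply(regions, function(r) {
      seg$chrom[i] == r$chrom && seg$ref_end[i] > r$start && seg$ref_start[i] < r$end
    }, logical(1)))
  }, logical(1))
  survivors <- unique(seg$read_name[seg$pass & overlaps_region])
  if (!length(survivors)) return(list())
  seg <- seg[seg$read_name %in% survivors & seg$pass, , drop = FALSE]

  # reconstruct out-of-region partners of surviving reads from SA tags
  if (fetch_sa) {
    sa_idx <- which(keep & rec$qname %in% survivors & !is.na(rec$sa))
    extra <- lapply(sa_idx, function(i) {
      mbq <- get0(rec$qname[i], envir = baseq_cache, ifnotfound = NA_real_)
      .sa_segments(rec$qname[i], rec$sa[i], mbq)
    })
    extra <- extra[!vapply(extra, is.null, logical(1))]
    if (length(extra)) {
      extra <- do.call(rbind, extra)
      extra$seq <- NA_character_
      have <- paste(seg$read_name, seg$chrom, seg$ref_start, seg$strand)
      ekey <- paste(extra$read_name, extra$chrom, extra$ref_start, extra$strand)
      extra <- extra[!ekey %in% have & !duplicated(ekey), , drop = FALSE]
      if (nrow(extra)) {
        extra$pass <- .segment_passes(extra, cfg)
        extra <- extra[extra$pass, , drop = FALSE]
        seg <- rbind(seg, extra)
      }
    }
  }
  seg$pass <- NULL

  out <- lapply(split(seg, seg$read_name), function(s) {
    .new_read_group(.trim_group_segments(s))
  })
  out[order(names(out))]
}

#' Combine the segment tables of a list of read groups
#'
#' @param groups List of `read_group` objects.
#' @return A single data.frame of segments.
#' @export
segments_table <- function(groups) {
  if (!length(groups)) {
    return(.segment_row("x", "x", 1, "+", 0, "1M", NA, 0, FALSE)[0, ])
  }
  do.call(rbind, c(lapply(groups, `[[`, "segments"), make.row.names = FALSE))
}
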