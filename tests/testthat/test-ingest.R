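test_that("mean base quality is the arithmetic Phred mean", {
  expect_equal(mean_base_quality(rep(20, 50)), 20)
  expect_equal(mean_base_quality(c(10, 30)), 20)
  expect_equal(mean_base_quality(qual_str(10, 33)), 33)

  set.seed(7)
  q <- sample(0:60, 1000, TRUE)
  qs <- intToUtf8(q + 33L)
  expect_equal(mean_base_quality(qs), sum(q) / length(q))  # brute force

  expect_warning(v <- mean_base_quality("*"), "missing")
  expect_true(is.na(v))
})

test_that("alignment identity uses matches + insertions + deletions", {
  expect_equal(alignment_identity("100M", 0), 1.0)
  expect_equal(alignment_identity("100M", 40), 0.60)  # at-threshold pass
  expect_true(alignment_identity("100M", 40) >= filter_config()$min_identity)

  set.seed(8)
  for (i in 1:20) {
    m1 <- sample(50:200, 1); ins <- sample(0:30, 1); del <- sample(0:30, 1)
    m2 <- sample(50:200, 1); nm <- sample(0:80, 1)
    cig <- paste0(m1, "M", if (ins) paste0(ins, "I"),
                  if (del) paste0(del, "D"), m2, "M")
    alen <- m1 + ins + del + m2
    expect_equal(alignment_identity(cig, nm),
                 max(0, min(1, (alen - nm) / alen)))
  }
  expect_warning(alignment_identity("50M10I50M", NA), "missing")
})

test_that("short, low-quality and low-identity segments are filtered", {
  targets <- c(chr1 = 5000L)
  recs <- rbind(
    sam_rec("ok",      0L, "chr1", 1001L, "150M", rand_dna(150),
            qual_str(150, 30), tags = "NM:i:0"),
    sam_rec("short99", 0L, "chr1", 1001L, "99M", rand_dna(99),
            qual_str(99, 30), tags = "NM:i:0"),
    sam_rec("lowq",    0L, "chr1", 1001L, "150M", rand_dna(150),
            qual_str(150, 19), tags = "NM:i:0"),
    sam_rec("lowid",   0L, "chr1", 1001L, "150M", rand_dna(150),
            qual_str(150, 30), tags = "NM:i:61"),
    sam_rec("edge",    0L, "chr1", 1001L, "100M", rand_dna(100),
            qual_str(100, 20), tags = "NM:i:40"))
  bam <- write_test_bam(recs, targets)
  groups <- load_region_reads(bam, "chr1:900-1400")
  # thresholds are inclusive: Q20, 60% identity, 100 bp all pass at equality
  expect_setequal(names(groups), c("ok", "edge"))
})

test_that("filtering is monotone in every threshold", {
  set.seed(9)
  targets <- c(chr1 = 20000L)
  recs <- do.call(rbind, lapply(1:30, function(i) {
    len <- sample(80:400, 1)
    sam_rec(sprintf("r%02d", i), 0L, "chr1", sample(1000:15000, 1),
            paste0(len, "M"), rand_dna(len),
            qual_str(len, sample(15:40, 1)),
            tags = sprintf("NM:i:%d", sample(0:200, 1)))
  }))
  bam <- write_test_bam(recs, targets)
  region <- "chr1:1-20000"
  count <- function(cfg) length(load_region_reads(bam, region, cfg))
  base <- count(filter_config())
  for (cfg in list(filter_config(min_mean_baseq = 30),
                   filter_config(min_identity = 0.8),
                   filter_config(min_map_len = 250),
                   filter_config(min_mapq = 70))) {
    expect_lte(count(cfg), base)
  }
})

test_that("survivors match an independent brute-force filter pass", {
  set.seed(10)
  targets <- c(chr1 = 20000L)
  qmeans <- sample(c(18:22, 30), 40, TRUE)     # straddle Q20
  nms <- sample(c(55:65, 10), 40, TRUE)        # straddle 60% at len ~150
  lens <- sample(c(95:105, 300), 40, TRUE)     # straddle 100 bp
  recs <- do.call(rbind, lapply(1:40, function(i) {
    sam_rec(sprintf("s%02d", i), 0L, "chr1", 2000L + 10L * i,
            paste0(lens[i], "M"), rand_dna(lens[i]),
            qual_str(lens[i], qmeans[i]),
            tags = sprintf("NM:i:%d", round(nms[i] * lens[i] / 150)))
  }))
  bam <- write_test_bam(recs, targets)
  groups <- load_region_reads(bam, "chr1:1500-7000")

  nm_vals <- round(nms * lens / 150)
  expected <- recs$qname[qmeans >= 20 & (lens - nm_vals) / lens >= 0.6 &
                           lens >= 100]
  expect_setequal(names(groups), expected)
})

test_that("supplementary segments are gathered genome-wide via SA tags", {
  targets <- c(chr1 = 10000L, chr5 = 10000L)
  seq1 <- rand_dna(2000)
  # primary on chr1 (first 1200 bases), supplementary on chr5 (last 800)
  recs <- rbind(
    sam_rec("tra1", 0L, "chr1", 3001L, "1200M800S", seq1,
            tags = "NM:i:0\tSA:Z:chr5,5001,+,1200S800M,60,0;"),
    sam_rec("tra1", 2048L, "chr5", 5001L, "1200S800M", seq1,
            tags = "NM:i:0\tSA:Z:chr1,3001,+,1200M800S,60,0;"))
  bam <- write_test_bam(recs, targets)
  # fetch only the chr1 window: the chr5 partner must still be present
  groups <- load_region_reads(bam, "chr1:3000-4500")
  expect_length(groups, 1L)
  seg <- groups[["tra1"]]$segments
  expect_gte(nrow(seg), 2L)
  expect_setequal(unique(seg$chrom), c("chr1", "chr5"))
  expect_true(all(diff(seg$query_start) > 0))
})

test_that("empty regions and missing indexes are handled explicitly", {
  targets <- c(chr1 = 5000L)
  recs <- sam_rec("a", 0L, "chr1", 101L, "200M", rand_dna(200))
  bam <- write_test_bam(recs, targets)
  expect_length(load_region_reads(bam, "chr1:4000-4500"), 0L)
  expect_error(load_region_reads(bam, "chr9:1-100"), "chr9")
  expect_warning(g <- load_region_reads(bam, "chr1:1-9999"), "clipped")
  expect_length(g, 1L)

  noidx <- file.path(withr::local_tempdir(), "noindex.bam")
  file.copy(bam, noidx)
  expect_error(load_region_reads(noidx, "chr1:1-100"), "samtools index")
})

test_that("query-overlapping segments of one read are trimmed", {
  g <- make_group(list(
    make_segment("chr1", 1000, 2000, 0, 1000, mapq = 60),
    make_segment("chr1", 5000, 6000, 900, 1900, mapq = 30)))
  trimmed <- svlook:::.trim_group_segments(g$segments)
  expect_equal(nrow(trimmed), 2L)
  # lower-mapq (later) segment lost the 100 overlapping bases
  expect_equal(trimmed$query_start[2], 1000)
  expect_equal(trimmed$ref_start[2], 5100)
  expect_true(all(diff(trimmed$query_start) > 0))
})
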