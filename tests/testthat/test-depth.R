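test_that("a single spanning read gives unit depth in every bin", {
  targets <- c(chr1 = 1000L)
  recs <- sam_rec("a", 0L, "chr1", 101L, "300M", rand_dna(300))
  bam <- write_test_bam(recs, targets)
  pr <- region_depth(bam, "chr1:151-250", bin_size = 10)
  expect_length(pr$depth, 10L)
  expect_equal(pr$depth, rep(1, 10))
})

test_that("deleted bases contribute no coverage", {
  targets <- c(chr1 = 1000L)
  recs <- sam_rec("d", 0L, "chr1", 101L, "50M60D50M", rand_dna(100))
  bam <- write_test_bam(recs, targets)
  pr <- region_depth(bam, "chr1:101-260", bin_size = 1,
                     cfg = filter_config(min_map_len = 50))
  # per-base oracle from an independent CIGAR walk
  want <- oracle_coverage(recs, "chr1", 100, 260)
  expect_equal(pr$depth, want)
  expect_equal(sum(pr$depth[51:110]), 0)
})

test_that("binned mass conserves the aligned bases of filtered reads", {
  set.seed(31)
  targets <- c(chr1 = 30000L)
  for (i in 1:10) {
    n <- sample(5:25, 1)
    recs <- do.call(rbind, lapply(seq_len(n), function(j) {
      len1 <- sample(100:800, 1); dlen <- sample(0:100, 1)
      len2 <- sample(100:800, 1)
      cig <- if (dlen > 0) paste0(len1, "M", dlen, "D", len2, "M")
             else paste0(len1 + len2, "M")
      sam_rec(sprintf("f%d_%d", i, j), 0L, "chr1",
              sample(1:20000, 1), cig, rand_dna(len1 + len2))
    }))
    bam <- write_test_bam(recs, targets, stem = sprintf("cons%d", i))
    s <- sample(1:15000, 1); w <- sample(500:5000, 1)
    bin <- sample(c(1, 7, 50, 128), 1)
    pr <- region_depth(bam, region_spec("chr1", s, s + w), bin_size = bin)
    oracle <- oracle_coverage(recs, "chr1", s, s + w)
    # recover total mass from bin means and actual (possibly partial) widths
    widths <- diff(c(pr$bin_start, s + w))
    expect_equal(sum(pr$depth * widths), sum(oracle))
  }
})

test_that("pileup counts bases, deletions and insertion anchors per column", {
  targets <- c(chr1 = 2000L)
  ref <- rand_dna(2000)
  refseq <- function(s, e) substr(ref, s + 1, e)  # 0-based half-open
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "ref.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(structure(ref, names = "chr1")), fa)

  recs <- rbind(
    sam_rec("m1", 0L, "chr1", 501L, "200M", refseq(500, 700)),
    sam_rec("m2", 0L, "chr1", 451L, "250M", refseq(450, 700)),
    sam_rec("dd", 0L, "chr1", 501L, "50M20D130M", refseq(500, 680)),
    sam_rec("ii", 0L, "chr1", 521L, paste0("30M5I145M"),
            paste0(refseq(520, 550), "AAAAA", refseq(550, 695))))
  bam <- write_test_bam(recs, targets)
  cols <- pileup_bases(bam, region_spec("chr1", 540, 600), ref = fa,
                       cfg = filter_config())
  expect_equal(nrow(cols), 60L)
  expect_equal(cols$ref_base,
               strsplit(refseq(540, 600), "")[[1]])
  # every column's majority base equals the reference base
  bases <- c("A", "C", "G", "T", "N")
  maj <- bases[apply(as.matrix(cols[, bases]), 1, which.max)]
  expect_equal(maj, cols$ref_base)
  # deletion lane covers exactly the 20 deleted bases of read "dd"
  expect_equal(cols$pos[cols$DEL > 0], 550:569)
  # insertion anchors at the column left of the inserted bases (ref 549)
  expect_equal(cols$pos[cols$INS > 0], 549)
  # column totals never exceed the local read depth
  expect_true(all(rowSums(cols[, c(bases, "DEL")]) <= 4))
})

test_that("a 50/50 SNV column splits between the two alleles", {
  targets <- c(chr1 = 4000L)
  ref <- rand_dna(4000)
  base_at <- substr(ref, 2001, 2001)
  alt <- setdiff(c("A", "C", "G", "T"), base_at)[1]
  set.seed(33)
  recs <- do.call(rbind, lapply(1:30, function(i) {
    s <- sample(1650:1950, 1)  # every read spans the SNV at 0-based 2000
    seqi <- substr(ref, s + 1, s + 400)
    if (i %% 2 == 0) substr(seqi, 2001 - s, 2001 - s) <- alt
    sam_rec(sprintf("sv%02d", i), 0L, "chr1", s + 1L, "400M", seqi)
  }))
  bam <- write_test_bam(recs, targets)
  expect_warning(
    cols <- pileup_bases(bam, region_spec("chr1", 1950, 2250)),
    "200 bp")
  col <- cols[cols$pos == 2000, ]
  expect_equal(col[[alt]], 15)
  expect_equal(col[[base_at]], 15)
})

test_that("pileup refuses oversized regions and tolerates missing FASTA contigs", {
  targets <- c(chr1 = 5000L)
  recs <- sam_rec("a", 0L, "chr1", 101L, "200M", rand_dna(200))
  bam <- write_test_bam(recs, targets)
  expect_error(pileup_bases(bam, "chr1:1-2000"), "cap")
  expect_length(pileup_bases(bam, region_spec("chr1", 4000, 4100))$pos, 100L)
})

test_that("isoform chains follow the spliced CIGAR exactly", {
  targets <- c(chr1 = 10000L)
  recs <- rbind(
    sam_rec("iso1", 0L, "chr1", 1001L, "100M200N50M", rand_dna(150)),
    sam_rec("iso2", 0L, "chr1", 1001L, "100M200N50M", rand_dna(150)),
    sam_rec("flat", 16L, "chr1", 2001L, "300M", rand_dna(300)))
  bam <- write_test_bam(recs, targets)
  ch <- extract_isoforms(bam, "chr1:1-10000")
  e1 <- ch[ch$read_name == "iso1", ]
  expect_equal(e1$start, c(1000, 1300))
  expect_equal(e1$end, c(1100, 1350))
  # identical chains group identically
  e2 <- ch[ch$read_name == "iso2", c("start", "end")]
  rownames(e2) <- rownames(e1) <- NULL
  expect_identical(e1[, c("start", "end")], e2)
  # unspliced read: one exon spanning the alignment
  fl <- ch[ch$read_name == "flat", ]
  expect_equal(nrow(fl), 1L)
  expect_equal(c(fl$start, fl$end), c(2000, 2300))
  expect_equal(fl$strand, "-")
  # exon-union re-spanning reproduces each read's aligned span
  spans <- tapply(ch$end, ch$read_name, max) - tapply(ch$start, ch$read_name, min)
  expect_equal(as.numeric(spans[c("iso1", "flat")]), c(350, 300))
})
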