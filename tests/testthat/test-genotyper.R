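test_that("genotype thresholds are strict inequalities at 0.3 and 0.8", {
  cfg <- genotype_config()
  expect_equal(assign_genotype(30, 70, cfg)$genotype, "0/0")   # af 0.30
  expect_equal(assign_genotype(31, 69, cfg)$genotype, "0/1")   # af 0.31
  expect_equal(assign_genotype(80, 20, cfg)$genotype, "0/1")   # af 0.80
  expect_equal(assign_genotype(81, 19, cfg)$genotype, "1/1")   # af 0.81
  expect_equal(assign_genotype(9, 1, cfg)$genotype, "1/1")
  expect_equal(assign_genotype(5, 5, cfg)$genotype, "0/1")
  r <- assign_genotype(0, 0, cfg)
  expect_equal(r$genotype, "./.")
  expect_true(is.na(r$af))
})

test_that("assign_genotype is monotone in support and in thresholds", {
  cfg <- genotype_config()
  rank <- c("0/0" = 0, "0/1" = 1, "1/1" = 2)
  for (n_ref in c(1, 5, 20)) {
    prev <- -1
    for (n_sup in 0:40) {
      g <- rank[[assign_genotype(n_sup, n_ref, cfg)$genotype]]
      expect_gte(g, prev)
      prev <- g
    }
  }
  # raising the thresholds never increases 1/1 calls
  strict <- genotype_config(het_af = 0.4, hom_af = 0.9)
  n11 <- function(cfg) sum(vapply(0:20, function(s) {
    assign_genotype(s, 20 - s, cfg)$genotype == "1/1"
  }, logical(1)))
  expect_lte(n11(strict), n11(cfg))
})

test_that("evaluation windows pad the interval by the disparity tolerance", {
  cfg <- genotype_config()
  q <- svlook:::.sv_query("d1", "chr1", 10000, 12000, "DEL", 2000)
  w <- evaluation_window(q, cfg)
  expect_length(w, 1L)
  expect_equal(c(w[[1]]$start, w[[1]]$end), c(9000, 13000))

  qi <- svlook:::.sv_query("i1", "chr2", 500, 501, "INS", 100)
  w <- evaluation_window(qi, cfg)
  expect_equal(c(w[[1]]$start, w[[1]]$end), c(0, 1500))  # clipped at 0

  qt <- svlook:::.sv_query("t1", "chr1", 5000, 5001, "TRA",
                           mate_chrom = "chr9", mate_pos = 7000)
  w <- evaluation_window(qt, cfg)
  expect_length(w, 2L)
  expect_equal(w[[2]]$chrom, "chr9")
})

test_that("coverage and disparity exclusions shape the informative set", {
  cfg <- genotype_config()
  q <- svlook:::.sv_query("d1", "chr1", 10000, 12000, "DEL", 2000)

  # spans only 40% of the DEL interval -> excluded entirely
  shallow <- make_group(list(
    make_segment("chr1", 9000, 10800, 0, 1800, read_name = "shallow")),
    read_name = "shallow")
  # full-coverage read with a matching DEL split signature -> support
  supp <- make_group(list(
    make_segment("chr1", 8000, 10000, 0, 2000, read_name = "supp"),
    make_segment("chr1", 12000, 14000, 2000, 4000, read_name = "supp")),
    read_name = "supp")
  # DEL signature 1200 bp away from the query start -> reference
  far <- make_group(list(
    make_segment("chr1", 7200, 11200, 0, 4000, read_name = "far"),
    make_segment("chr1", 13200, 15200, 4000, 6000, read_name = "far")),
    read_name = "far")
  # clean spanning read -> reference
  refr <- make_group(list(
    make_segment("chr1", 9000, 13000, 0, 4000, read_name = "refr")),
    read_name = "refr")

  groups <- list(shallow = shallow, supp = supp, far = far, refr = refr)
  structures <- classify_reads(groups, 50)
  part <- collect_informative_reads(groups, structures, q, cfg)
  expect_setequal(part$support, "supp")
  expect_setequal(part$reference, c("far", "refr"))
})

test_that("support requires read/query SV length agreement", {
  cfg <- genotype_config()
  q <- svlook:::.sv_query("d1", "chr1", 10000, 10400, "DEL", 400)
  # breakpoints within tolerance but a 9 kb deletion against a 400 bp query
  nested <- make_group(list(
    make_segment("chr1", 6000, 10000, 0, 4000, read_name = "nested"),
    make_segment("chr1", 19000, 21000, 4000, 6000, read_name = "nested")),
    read_name = "nested")
  groups <- list(nested = nested)
  structures <- classify_reads(groups, 50)
  part <- collect_informative_reads(groups, structures, q, cfg)
  expect_length(part$support, 0L)
})

test_that("simulated het loci partition reads close to the simulator truth", {
  sim <- small_locus("DEL", "0/1", seed = 5, len = 400)
  q <- read_sv_queries(sim$vcf)[1, ]
  res <- genotype_sv(sim$bam, q)
  expect_equal(res$genotype, "0/1")
  sup <- attr(res, "support")
  # simulator read names carry the haplotype: h1 = reference, h2 = variant
  expect_true(all(grepl("_h2_", sup)))
  expect_true(mean(grepl("_h1_", attr(res, "reference"))) > 0.4)
})

test_that("force-calling a VCF preserves records and fills GT/DV/DR/AF", {
  dir <- withr::local_tempdir()
  sim <- small_locus("INS", "1/1", seed = 6, len = 250, dir = dir)
  out <- file.path(dir, "out.vcf")
  res <- genotype_vcf(sim$bam, sim$vcf, out)
  expect_equal(nrow(res), 1L)
  expect_equal(res$genotype, "1/1")

  lines <- readLines(out)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 1L)
  fields <- strsplit(body, "\t")[[1]]
  expect_equal(fields[9], "GT:DV:DR:AF")
  gt <- strsplit(fields[10], ":")[[1]]
  expect_equal(gt[1], "1/1")
  expect_gt(as.integer(gt[2]), 0)
  expect_gt(as.numeric(gt[4]), 0.8)
  expect_true(any(grepl("^##FORMAT=<ID=DV", lines)))
  # round trip: the annotated VCF is still parseable
  expect_equal(nrow(read_sv_queries(out)), 1L)
})

test_that("BND records are genotyped through the translocation path", {
  dir <- withr::local_tempdir()
  sim <- small_locus("TRA", "1/1", seed = 7, dir = dir)
  truth <- sim$truth
  bnd <- file.path(dir, "bnd.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"x\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    paste(truth$chrom, truth$pos + 1, "bnd1", "N",
          sprintf("N[%s:%d[", truth$chrom2, truth$pos2 + 1), ".", "PASS",
          "SVTYPE=BND", sep = "\t")), bnd)
  out <- file.path(dir, "bnd_out.vcf")
  res <- genotype_vcf(sim$bam, bnd, out)
  expect_equal(res$sv_type, "TRA")
  expect_equal(res$genotype, "1/1")
})

test_that("unparseable SVTYPE passes through as ./. with a warning", {
  dir <- withr::local_tempdir()
  sim <- small_locus("DEL", "0/1", seed = 8, dir = dir)
  vcf <- file.path(dir, "mixed.vcf")
  truth <- sim$truth
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"x\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"x\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"x\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    paste(truth$chrom, truth$pos + 1, "good", "N", "<DEL>", ".", "PASS",
          sprintf("SVTYPE=DEL;END=%d;SVLEN=-%d", truth$pos + truth$length,
                  truth$length), sep = "\t"),
    paste(truth$chrom, "100", "odd", "N", "<CPX>", ".", "PASS",
          "SVTYPE=CPX", sep = "\t")), vcf)
  out <- file.path(dir, "mixed_out.vcf")
  expect_warning(res <- genotype_vcf(sim$bam, vcf, out), "unparseable")
  expect_equal(nrow(res), 2L)
  expect_equal(res$genotype[res$id == "odd"], "./.")
  expect_equal(res$genotype[res$id == "good"], "0/1")
  body <- readLines(out)
  expect_length(body[!startsWith(body, "#")], 2L)
})
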