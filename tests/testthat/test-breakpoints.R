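test_that("split breakpoints join the reference coordinates at adjacencies", {
  g <- make_group(list(
    make_segment("chr1", 10000, 11000, 0, 1000),
    make_segment("chr1", 16000, 17000, 1000, 2000)))
  bp <- split_breakpoints(g, 50)
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$orient, "++")
  expect_equal(bp$pos_b - bp$pos_a, 5000)
  expect_equal(bp$source, "split")

  tra <- make_group(list(
    make_segment("chr1", 10000, 11000, 0, 1000),
    make_segment("chr5", 500, 1500, 1000, 2000)))
  bp <- split_breakpoints(tra, 50)
  expect_equal(bp$type, "TRA")
  expect_setequal(c(bp$chrom_a, bp$chrom_b), c("chr1", "chr5"))

  single <- make_group(list(make_segment("chr1", 0, 100, 0, 100)))
  expect_error(split_breakpoints(single), ">= 2 segments")
})

test_that("simple reads classify as REF and large split deletions by length", {
  ref <- make_group(list(make_segment("chr1", 1000, 1100, 0, 100,
                                      cigar = "100M")))
  st <- classify_read_structure(ref, 50)
  expect_equal(st$sv_type, "REF")
  expect_equal(st$sv_length, 0)
  expect_equal(nrow(st$events), 0L)

  # split-read deletion with an 85 kb gap, no query gap
  del <- make_group(list(
    make_segment("chr1", 100000, 110000, 0, 10000),
    make_segment("chr1", 195000, 205000, 10000, 20000)))
  st <- classify_read_structure(del, 50)
  expect_equal(st$sv_type, "DEL")
  expect_equal(st$sv_length, 85000)
})

test_that("classification matches the rule-table oracle on all 2-segment configurations", {
  L <- 50
  gaps <- c(-2L * L, -L, 0L, L, 2L * L)
  n_cases <- 0L
  for (s1 in c("+", "-")) for (s2 in c("+", "-")) {
    for (rgap in gaps) for (qgap in gaps) {
      g <- pair_group(s1, s2, rgap, qgap)
      st <- classify_read_structure(g, L)
      j <- pair_junctions(g)
      want <- oracle_pair_type("chr1", "chr1", s1, s2, rgap, qgap,
                               j[1], j[2], L)
      expect_equal(st$sv_type, want$type,
                   info = sprintf("%s%s rgap=%d qgap=%d", s1, s2, rgap, qgap))
      if (want$type %in% c("DEL", "INS", "DUP", "INV")) {
        expect_equal(st$sv_length, want$len,
                     info = sprintf("%s%s rgap=%d qgap=%d", s1, s2, rgap, qgap))
      }
      n_cases <- n_cases + 1L
    }
    # inter-chromosomal adjacency is TRA at any gap
    g <- pair_group(s1, s2, 0L, 0L, chrom2 = "chr9")
    expect_equal(classify_read_structure(g, L)$sv_type, "TRA")
  }
  expect_equal(n_cases, 100L)
})

test_that("classification is invariant under reversing the read", {
  L <- 50
  gaps <- c(-2L * L, -L, 0L, L, 2L * L)
  for (s1 in c("+", "-")) for (s2 in c("+", "-")) {
    for (rgap in gaps) for (qgap in gaps) {
      if (qgap < 0) next  # overlapping query intervals are an ingest artifact
      g <- pair_group(s1, s2, rgap, qgap)
      st <- classify_read_structure(g, L)
      str <- classify_read_structure(reverse_group(g), L)
      expect_equal(str$sv_type, st$sv_type)
      expect_equal(str$sv_length, st$sv_length)
    }
  }
})

test_that("typed event lengths always reach the minimum SV length", {
  set.seed(11)
  for (i in 1:200) {
    g <- pair_group(sample(c("+", "-"), 1), sample(c("+", "-"), 1),
                    sample(-300:300, 1), sample(0:300, 1))
    st <- classify_read_structure(g, 50)
    if (st$sv_type %in% c("DEL", "INS", "DUP", "INV")) {
      expect_gte(st$sv_length, 50)
    }
  }
})

test_that("multi-event reads are labelled by their largest event", {
  g <- make_group(list(
    make_segment("chr1", 1000, 2060, 0, 1000, cigar = "500M60D500M"),
    make_segment("chr1", 7060, 8060, 1000, 2000)))
  st <- classify_read_structure(g, 50)
  # cigar DEL of 60 and split DEL of 5000: label follows the larger
  expect_equal(st$sv_type, "DEL")
  expect_equal(st$sv_length, 5000)
  expect_equal(nrow(st$events), 2L)
  expect_setequal(st$events$source, c("cigar", "split"))
})

test_that("breakpoint clustering is single-linkage within tolerance, per type", {
  mk_st <- function(name, type, pos_a, pos_b, len) {
    structure(list(read_name = name, sv_type = type, sv_length = len,
                   events = data.frame(
                     type = type, chrom_a = "chr1", pos_a = pos_a,
                     chrom_b = "chr1", pos_b = pos_b, orient = "++",
                     source = "split", length = len,
                     stringsAsFactors = FALSE),
                   has_clip = FALSE), class = "read_structure")
  }
  sts <- list(mk_st("a", "DEL", 1000, 2000, 1000),
              mk_st("b", "DEL", 1010, 2010, 1000),
              mk_st("c", "DEL", 1990, 2990, 1000))
  cl <- cluster_breakpoints(sts, tol = 1000)
  expect_equal(nrow(cl), 1L)       # chained linkage merges all three
  expect_equal(cl$support, 3L)
  expect_equal(cl$pos_a, 1010)     # median consensus

  mixed <- list(mk_st("a", "DEL", 1000, 2000, 1000),
                mk_st("b", "INS", 1000, 1000, 120))
  cl <- cluster_breakpoints(mixed, tol = 1000)
  expect_equal(nrow(cl), 2L)       # types never merge

  expect_equal(nrow(cluster_breakpoints(list())), 0L)

  # conservation: breakpoints in = sum over clusters; support <= reads
  set.seed(12)
  sts <- lapply(1:40, function(i) {
    mk_st(sprintf("r%02d", i), sample(c("DEL", "INS"), 1),
          p <- sample(1:50000, 1), p + 500, 500)
  })
  cl <- cluster_breakpoints(sts, tol = 1000)
  expect_equal(sum(cl$n_bp), 40L)
  expect_true(all(cl$support <= 40L))
})
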