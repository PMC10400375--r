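test_that("trimming isolates the guide at zero stagger with both anchors", {
  lib <- make_library(3, seed = 101)
  g1 <- lib$entries$sequence[1]
  ctx <- make_context("CACCG", "GTTTT", 0, 0, 20L)
  tr <- trim_reads(paste0("CACCG", g1, "GTTTT"), ctx)
  expect_true(tr$trimmed)
  expect_equal(tr$candidate, g1)
  expect_equal(tr$stagger, 0L)
  expect_equal(tr$anchor5_mm, 0L)
})

test_that("trimming matches the exhaustive offset-scan oracle under stagger and anchor errors", {
  lib <- make_library(5, seed = 111)
  ctx <- make_context("CACCGAGGTC", "GTTTTAGAGC", 0, 7, 20L)
  set.seed(112)
  for (rep in 1:50) {
    g <- sample(lib$entries$sequence, 1)
    stag <- sample(0:7, 1)
    anchor <- ctx$anchor5
    n_err <- sample(0:3, 1)             # up to 3 anchor substitutions
    if (n_err > 0) {
      pos <- sample(nchar(anchor), n_err)
      for (p in pos)
        substr(anchor, p, p) <- sample(setdiff(BASES, substr(anchor, p, p)), 1)
    }
    read <- paste0(rand_seq(stag), anchor, g, ctx$anchor3, rand_seq(10))
    tr <- trim_reads(read, ctx, max_anchor_mm = 2)
    oracle <- oracle_trim(read, ctx$anchor5, -1, 8, max_mm = 2)
    if (is.null(oracle)) {
      expect_false(tr$trimmed)
    } else {
      expect_true(tr$trimmed)
      expect_equal(tr$stagger, oracle$offset)
      expect_equal(tr$anchor5_mm, oracle$mm)
      if (oracle$offset == stag) expect_equal(tr$candidate, g)
    }
  }
})

test_that("a single anchor substitution at stagger 3 still trims", {
  lib <- make_library(2, seed = 121)
  g <- lib$entries$sequence[1]
  ctx <- make_context("CACCGTTAGC", "GTTTTAGAGC", 0, 7, 20L)
  a5 <- ctx$anchor5
  substr(a5, 4, 4) <- if (substr(a5, 4, 4) == "A") "C" else "A"
  read <- paste0("ACT", a5, g, ctx$anchor3)
  tr <- trim_reads(read, ctx)
  expect_true(tr$trimmed)
  expect_equal(tr$stagger, 3L)
  expect_equal(tr$anchor5_mm, 1L)
  expect_equal(tr$candidate, g)
})

test_that("random reads are untrimmed, never an error", {
  ctx <- make_context("CACCGAGGTC", "GTTTTAGAGC", 0, 7, 20L)
  set.seed(131)
  tr <- trim_reads(vapply(rep(60, 40), rand_seq, ""), ctx)
  expect_true(all(!tr$trimmed))
  expect_true(all(is.na(tr$candidate)))
})

test_that("N in the anchor window counts as a mismatch; N in the candidate is kept", {
  lib <- make_library(2, seed = 141)
  g <- lib$entries$sequence[1]
  ctx <- make_context("CACCGA", "GTTTTA", 0, 0, 20L)
  r_anchor_n <- paste0("NNNCGA", g, "GTTTTA")   # 3 Ns in anchor > max 2
  expect_false(trim_reads(r_anchor_n, ctx)$trimmed)
  r_anchor_1n <- paste0("NACCGA", g, "GTTTTA")
  tr <- trim_reads(r_anchor_1n, ctx)
  expect_true(tr$trimmed)
  expect_equal(tr$anchor5_mm, 1L)
  gn <- g; substr(gn, 5, 5) <- "N"
  tr2 <- trim_reads(paste0("CACCGA", gn, "GTTTTA"), ctx)
  expect_true(tr2$trimmed)
  expect_equal(tr2$candidate, gn)               # matcher decides about N
})

test_that("offset-shift equivariance: a prepended prefix only moves the stagger", {
  lib <- make_library(4, seed = 151)
  ctx <- make_context("GACGAAACACCG", "GTTTTAGAGCTA", 0, 7, 20L)
  set.seed(152)
  for (k in 0:7) {
    g <- sample(lib$entries$sequence, 1)
    base <- paste0(ctx$anchor5, g, ctx$anchor3)
    prefix <- rand_seq(k)
    # guard against the random prefix creating a second, earlier anchor match
    if (!is.null(oracle_trim(paste0(prefix, base), ctx$anchor5, 0, 8, 2)) &&
        oracle_trim(paste0(prefix, base), ctx$anchor5, 0, 8, 2)$offset != k) next
    tr0 <- trim_reads(base, ctx)
    trk <- trim_reads(paste0(prefix, base), ctx)
    expect_equal(trk$candidate, tr0$candidate)
    expect_equal(trk$stagger, tr0$stagger + k)
  }
})

test_that("without an anchor3 match the candidate is capped at the longest guide", {
  lib <- guidecounter:::new_guide_library(c("a", "b"),
                                          c(strrep("AC", 9), strrep("GT", 10)))
  ctx <- make_context("CACCGA", "", 0, 0, c(18L, 20L))
  read <- paste0("CACCGA", strrep("GT", 10), "CCCCCC")
  tr <- trim_reads(read, ctx)
  expect_equal(tr$candidate, strrep("GT", 10))       # max(guide_lengths) bases
  short <- paste0("CACCGA", strrep("A", 12))         # fewer than min remain
  expect_false(trim_reads(short, ctx)$trimmed)
  edge <- paste0("CACCGA", strrep("A", 19))          # read ends inside guide
  expect_equal(trim_reads(edge, ctx)$candidate, strrep("A", 19))
})

test_that("trim_fastq tallies unique candidates and conserves read counts", {
  lib <- make_library(2, seed = 161)
  g <- lib$entries$sequence
  ctx <- make_context("CACCGA", "GTTTTA", 0, 0, 20L)
  set.seed(162)
  reads <- c(rep(paste0("CACCGA", g[1], "GTTTTA"), 7),
             rep(paste0("CACCGA", g[2], "GTTTTA"), 2),
             rand_seq(40))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq_plain(sample(reads), fq)
  tr <- trim_fastq(fq, ctx)
  expect_equal(sort(unclass(tr$unique), decreasing = TRUE),
               setNames(c(7L, 2L), g), ignore_attr = TRUE)
  expect_equal(unname(unclass(tr$unique)[g]), c(7L, 2L))
  expect_equal(tr$stats, list(total = 10L, trimmed = 9L, untrimmed = 1L))

  # empty stream
  empty <- withr::local_tempfile(fileext = ".fastq")
  file.create(empty)
  tr0 <- trim_fastq(empty, ctx)
  expect_length(tr0$unique, 0)
  expect_equal(tr0$stats, list(total = 0L, trimmed = 0L, untrimmed = 0L))
})

test_that("error-free simulated reads all trim and reproduce the planted multiset", {
  lib <- make_library(10, seed = 171)
  spec <- sim_spec(lib, n_reads = 1000, seed = 172)
  fq <- withr::local_tempfile(fileext = ".fastq.gz")
  truth <- simulate_single(spec, fq)
  ctx <- make_context(spec$adapter5, substr(spec$scaffold3, 1, 20), 0, 7, 20L)
  tr <- trim_fastq(fq, ctx)
  expect_equal(tr$stats$trimmed, 1000L)
  got <- unclass(tr$unique)[lib$entries$sequence]
  got[is.na(got)] <- 0L
  expect_equal(unname(got), unname(truth$counts))
})
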