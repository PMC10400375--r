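test_that("exact, one-mismatch and ambiguous assignments match the brute-force oracle", {
  lib <- make_library(30, seed = 201)
  idx <- build_match_index(lib, max_mm = 1)
  g1 <- lib$entries$sequence[1]
  expect_equal(match_sequence(g1, idx),
               list(status = "unique", guide_id = "g001", mismatches = 0L,
                    duplicate = FALSE))
  set.seed(202)
  # randomized candidates: exact, 1-mm, 2-mm, random, wrong length
  cands <- c(sample(lib$entries$sequence, 10),
             unlist(lapply(sample(lib$entries$sequence, 10), function(s)
               sample(neighbours1(s), 1))),
             vapply(rep(20, 10), rand_seq, ""),
             vapply(rep(19, 3), rand_seq, ""))
  for (cand in cands) {
    got <- match_sequence(cand, idx)
    want <- brute_match(cand, lib, max_mm = 1)
    expect_equal(got$status, want$status, info = cand)
    if (want$status == "unique") {
      expect_equal(got$guide_id, want$guide_id, info = cand)
      expect_equal(got$mismatches, want$mismatches, info = cand)
    }
  }
})

test_that("a candidate equidistant from two guides is ambiguous", {
  # two guides differing at exactly two positions; the midpoint read is 1 mm
  # from both
  a <- "ACGTACGTACGTACGTACGT"
  b <- a; substr(b, 1, 1) <- "T"; substr(b, 20, 20) <- "C"
  lib <- guidecounter:::new_guide_library(c("gA", "gB"), c(a, b))
  idx <- build_match_index(lib, max_mm = 1)
  mid <- a; substr(mid, 1, 1) <- "T"
  got <- match_sequence(mid, idx)
  expect_equal(got$status, "ambiguous")
  expect_equal(got$candidates, c("gA", "gB"))
  expect_equal(brute_match(mid, lib, 1)$status, "ambiguous")
})

test_that("a guide and its reverse complement are kept apart", {
  set.seed(211)
  g <- rand_seq(20)
  lib <- guidecounter:::new_guide_library(c("fwd", "rc"), c(g, r_revcomp(g)))
  idx <- build_match_index(lib, max_mm = 1)
  expect_equal(match_sequence(g, idx)$guide_id, "fwd")
  expect_equal(match_sequence(r_revcomp(g), idx)$guide_id, "rc")
})

test_that("duplicate library sequences count under the canonical first id", {
  s <- "ACGTACGTACGTACGTACGT"
  t <- "TTTTCCCCGGGGAAAATTTT"
  lib <- guidecounter:::new_guide_library(c("g1", "g2", "g3"), c(s, t, s))
  idx <- build_match_index(lib, max_mm = 1)
  got <- match_sequence(s, idx)
  expect_equal(got$guide_id, "g1")
  expect_true(got$duplicate)
  u <- setNames(c(4L, 3L), c(s, t))
  ct <- count_single_end(u, idx, list(total = 7, trimmed = 7, untrimmed = 0), lib)
  expect_equal(unname(ct$counts), c(4L, 3L, 0L))
})

test_that("pigeonhole search is complete for every 1-mismatch neighbour", {
  lib <- make_library(15, len = c(19, 20), seed = 221)
  idx <- build_match_index(lib, max_mm = 1)
  for (i in seq_len(nrow(lib$entries))) {
    s <- lib$entries$sequence[i]
    for (nb in neighbours1(s)) {
      got <- match_sequence(nb, idx)
      want <- brute_match(nb, lib, 1)
      expect_equal(got$status, want$status, info = nb)
      if (want$status == "unique")
        expect_equal(got$guide_id, want$guide_id, info = nb)
    }
  }
})

test_that("the placeholder is indexed under its reserved id and collisions error", {
  lib <- make_library(5, seed = 231)
  set.seed(232)
  ph <- rand_seq(20)
  idx <- build_match_index(lib, placeholder = ph, max_mm = 1)
  expect_equal(match_sequence(ph, idx)$guide_id, "3Cs_placeholder")
  lib_bad <- guidecounter:::new_guide_library(
    c("3Cs_placeholder", "x"), c(rand_seq(20), rand_seq(20)))
  expect_error(build_match_index(lib_bad, placeholder = ph),
               class = "gc_reserved_id")
})

test_that("count_single_end expands multiplicities and conserves totals", {
  lib <- make_library(4, seed = 241)
  g <- lib$entries$sequence
  idx <- build_match_index(lib, max_mm = 0)
  set.seed(242)
  u <- setNames(c(7L, 2L, 1L), c(g[1], g[2], rand_seq(20)))
  ct <- count_single_end(u, idx, list(total = 12, trimmed = 10, untrimmed = 2), lib)
  expect_equal(unname(ct$counts), c(7L, 2L, 0L, 0L))
  expect_equal(ct$totals$unaligned, 1L)
  expect_equal(sum(ct$counts) + ct$placeholder_count + ct$totals$ambiguous +
                 ct$totals$unaligned, ct$totals$trimmed)
  expect_error(
    count_single_end(u, idx, list(total = 12, trimmed = 9, untrimmed = 3), lib),
    class = "gc_inconsistent_totals")
  # empty table
  ct0 <- count_single_end(integer(0), idx,
                          list(total = 0, trimmed = 0, untrimmed = 0), lib)
  expect_equal(sum(ct0$counts), 0L)
  expect_equal(ct0$totals$total_reads, 0)
})

test_that("unique-first counting equals the naive per-read pipeline bit for bit", {
  lib <- make_library(25, seed = 251)
  spec <- sim_spec(lib, n_reads = 800, substitution_rate = 0.02,
                   junk_fraction = 0.05, seed = 252)
  truth <- simulate_single(spec)
  ctx <- make_context(spec$adapter5, substr(spec$scaffold3, 1, 20), 0, 7, 20L)
  tr <- trim_reads(truth$reads, ctx)
  cands <- tr$candidate[tr$trimmed]
  stats <- list(total = length(truth$reads), trimmed = length(cands),
                untrimmed = sum(!tr$trimmed))
  u <- guidecounter:::new_unique_table(
    guidecounter:::merge_counts(integer(), table(cands)))
  for (mm in 0:1) {
    idx <- build_match_index(lib, max_mm = mm)
    ct <- count_single_end(u, idx, stats, lib)
    want <- naive_count(cands, lib, max_mm = mm)
    expect_identical(ct$counts, want$counts)
    expect_equal(ct$totals$ambiguous, want$ambiguous)
    expect_equal(ct$totals$unaligned, want$unaligned)
  }
})

test_that("raising max_mm never loses assignments and never gains unaligned", {
  lib <- make_library(20, seed = 261)
  spec <- sim_spec(lib, n_reads = 600, substitution_rate = 0.03, seed = 262)
  truth <- simulate_single(spec)
  ctx <- make_context(spec$adapter5, substr(spec$scaffold3, 1, 20), 0, 7, 20L)
  tr <- trim_fastq_from_reads(truth$reads, ctx)
  res <- lapply(0:2, function(mm) {
    idx <- build_match_index(lib, max_mm = mm)
    count_single_end(tr$unique, idx, tr$stats, lib)$totals
  })
  for (i in 2:3) {
    expect_gte(res[[i]]$assigned + res[[i]]$ambiguous,
               res[[i - 1]]$assigned + res[[i - 1]]$ambiguous)
    expect_lte(res[[i]]$unaligned, res[[i - 1]]$unaligned)
  }
})

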