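# Shared scaffolding for paired tests: two mate contexts with distinct
# cassettes, R2 read on the opposite strand.
paired_fixture <- function(lib, pairs, n, seed, ...) {
  spec <- sim_spec(lib, n_reads = n, seed = seed, ...)
  r1 <- tempfile(fileext = "_R1.fastq")
  r2 <- tempfile(fileext = "_R2.fastq")
  truth <- simulate_paired(spec, pairs, r1, r2)
  ctx1 <- make_context(spec$adapter5, substr(spec$scaffold3, 1, 20), 0, 7,
                       lib$lengths)
  ctx2 <- make_context(guidecounter:::SIM_ADAPTER5_R2,
                       substr(guidecounter:::SIM_SCAFFOLD3_R2, 1, 20), 0, 7,
                       lib$lengths, orientation = "reverse")
  list(truth = truth, r1 = r1, r2 = r2, ctx1 = ctx1, ctx2 = ctx2)
}

sorted_pairs <- function(df) {
  df <- df[order(df$guide_id_1, df$guide_id_2), c("guide_id_1", "guide_id_2", "count")]
  rownames(df) <- NULL
  df
}

test_that("synchronized pair tallying counts unique combinations once", {
  lib <- make_library(6, seed = 301)
  pairs <- data.frame(guide_id_1 = c("g001", "g002"),
                      guide_id_2 = c("g003", "g004"), weight = c(3, 1))
  fx <- paired_fixture(lib, pairs, n = 60, seed = 302)
  on.exit(unlink(c(fx$r1, fx$r2)))
  tly <- tally_unique_pairs(fx$r1, fx$r2, fx$ctx1, fx$ctx2)
  expect_equal(tly$total_pairs, 60L)
  expect_equal(sum(tly$pairs$count), 60L)
  # error-free reads: exactly the two planted sequence combinations
  expect_equal(nrow(tly$pairs), 2)
  expect_equal(tly$stats1$trimmed, 60L)
  expect_equal(tly$stats2$trimmed, 60L)
})

test_that("mate-count mismatch and id mismatch raise named errors", {
  lib <- make_library(4, seed = 311)
  set.seed(312)
  reads <- vapply(sample(lib$entries$sequence, 10, replace = TRUE),
                  build_read, "", USE.NAMES = FALSE)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq_plain(reads, f1)
  write_fastq_plain(reads[1:9], f2)
  ctx <- make_context("CACCGA", "GTTTTAG", 0, 0, 20L)
  expect_error(tally_unique_pairs(f1, f2, ctx, ctx),
               class = "gc_mate_count_mismatch")
  # same length but different ids
  writeLines(as.vector(rbind(paste0("@x", 1:10), reads, "+",
                             strrep("I", nchar(reads)))), f2)
  expect_error(tally_unique_pairs(f1, f2, ctx, ctx, check_ids = TRUE),
               class = "gc_mate_id_mismatch")
  expect_silent(tally_unique_pairs(f1, f2, ctx, ctx))  # id check off by default
})

test_that("pair resolution categories partition all pairs and counts match truth", {
  lib <- make_library(10, seed = 321)
  pairs <- data.frame(guide_id_1 = c("g001", "g002", "g003"),
                      guide_id_2 = c("g004", "g005", "g006"),
                      weight = c(5, 3, 2))
  fx <- paired_fixture(lib, pairs, n = 500, seed = 322)
  on.exit(unlink(c(fx$r1, fx$r2)))
  tly <- tally_unique_pairs(fx$r1, fx$r2, fx$ctx1, fx$ctx2)
  idx <- build_match_index(lib, max_mm = 1)
  ct1 <- count_single_end(tly$unique1, idx, tly$stats1, lib)
  ct2 <- count_single_end(tly$unique2, idx, tly$stats2, lib)
  combo <- count_paired_end(tly, ct1, ct2)
  expect_identical(sorted_pairs(combo$combos), sorted_pairs(fx$truth$pair_counts))
  t <- combo$totals
  expect_equal(t$both_assigned + t$partial + t$neither + t$ambiguous_involved,
               t$total_pairs)
  expect_equal(sum(combo$combos$count), t$both_assigned)
  # marginals are the row/column sums of the combo matrix
  m1 <- tapply(combo$combos$count, combo$combos$guide_id_1, sum)
  expect_equal(unname(combo$marginal1[names(m1)]), as.vector(m1))
  expect_equal(sum(combo$marginal1), t$both_assigned)
  expect_equal(sum(combo$marginal2), t$both_assigned)
})

test_that("an untrimmed mate yields a partial pair, not a combo", {
  lib <- make_library(4, seed = 331)
  g <- lib$entries$sequence
  ctx <- make_context("CACCGA", "GTTTTAG", 0, 0, 20L)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  set.seed(332)
  write_fastq_plain(rep(paste0("CACCGA", g[1], "GTTTTAG"), 4), f1)
  write_fastq_plain(vapply(rep(33, 4), rand_seq, ""), f2)  # never trims
  tly <- tally_unique_pairs(f1, f2, ctx, ctx)
  expect_equal(tly$pairs$seq2, "<untrimmed>")
  idx <- build_match_index(lib, max_mm = 1)
  ct1 <- count_single_end(tly$unique1, idx, tly$stats1, lib)
  ct2 <- count_single_end(tly$unique2, idx, tly$stats2, lib)
  combo <- count_paired_end(tly, ct1, ct2)
  expect_equal(combo$totals$partial, 4L)
  expect_equal(nrow(combo$combos), 0)
})

test_that("pairwise resolution equals resolving every pair individually", {
  lib <- make_library(12, seed = 341)
  pairs <- data.frame(guide_id_1 = rep(c("g001", "g002"), 3),
                      guide_id_2 = c("g003", "g004", "g005", "g006", "g007", "g008"),
                      weight = c(6, 5, 4, 3, 2, 1))
  fx <- paired_fixture(lib, pairs, n = 400, seed = 342,
                       substitution_rate = 0.02)
  on.exit(unlink(c(fx$r1, fx$r2)))
  tly <- tally_unique_pairs(fx$r1, fx$r2, fx$ctx1, fx$ctx2)
  idx <- build_match_index(lib, max_mm = 1)
  ct1 <- count_single_end(tly$unique1, idx, tly$stats1, lib)
  ct2 <- count_single_end(tly$unique2, idx, tly$stats2, lib)
  combo <- count_paired_end(tly, ct1, ct2)

  # oracle: trim and brute-force-match each read pair on its own
  r1 <- read_fastq(fx$r1)$sequence
  r2 <- read_fastq(fx$r2)$sequence
  t1 <- trim_reads(r1, fx$ctx1)
  t2 <- trim_reads(r2, fx$ctx2)
  tab <- new.env(parent = emptyenv())
  totals <- c(both = 0L, partial = 0L, neither = 0L, amb = 0L)
  for (i in seq_along(r1)) {
    a1 <- if (t1$trimmed[i]) brute_match(t1$candidate[i], lib, 1) else list(status = "untrimmed")
    a2 <- if (t2$trimmed[i]) brute_match(t2$candidate[i], lib, 1) else list(status = "untrimmed")
    if (a1$status == "ambiguous" || a2$status == "ambiguous") {
      totals["amb"] <- totals["amb"] + 1L
    } else if (a1$status == "unique" && a2$status == "unique") {
      key <- paste(a1$guide_id, a2$guide_id)
      tab[[key]] <- (tab[[key]] %||% 0L) + 1L
      totals["both"] <- totals["both"] + 1L
    } else if (a1$status == "unique" || a2$status == "unique") {
      totals["partial"] <- totals["partial"] + 1L
    } else totals["neither"] <- totals["neither"] + 1L
  }
  got <- setNames(combo$combos$count,
                  paste(combo$combos$guide_id_1, combo$combos$guide_id_2))
  want <- unlist(as.list(tab))
  expect_equal(got[order(names(got))], want[order(names(want))])
  expect_equal(combo$totals$both_assigned, unname(totals["both"]))
  expect_equal(combo$totals$partial, unname(totals["partial"]))
  expect_equal(combo$totals$neither, unname(totals["neither"]))
  expect_equal(combo$totals$ambiguous_involved, unname(totals["amb"]))
})

test_that("collapse_orientation merges reciprocal pairs", {
  lib <- make_library(4, seed = 351)
  pairs <- data.frame(guide_id_1 = c("g001", "g002"),
                      guide_id_2 = c("g002", "g001"), weight = c(1, 1))
  fx <- paired_fixture(lib, pairs, n = 40, seed = 352)
  on.exit(unlink(c(fx$r1, fx$r2)))
  tly <- tally_unique_pairs(fx$r1, fx$r2, fx$ctx1, fx$ctx2)
  idx <- build_match_index(lib, max_mm = 1)
  ct1 <- count_single_end(tly$unique1, idx, tly$stats1, lib)
  ct2 <- count_single_end(tly$unique2, idx, tly$stats2, lib)
  keep <- count_paired_end(tly, ct1, ct2)
  fold <- count_paired_end(tly, ct1, ct2, collapse_orientation = TRUE)
  expect_equal(nrow(keep$combos), 2)
  expect_equal(nrow(fold$combos), 1)
  expect_equal(fold$combos$count, sum(keep$combos$count))
})

test_that("zero pairs give an empty, conserving combo table", {
  lib <- make_library(3, seed = 361)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  file.create(f1); file.create(f2)
  ctx <- make_context("CACCGA", "GTTTTAG", 0, 0, 20L)
  tly <- tally_unique_pairs(f1, f2, ctx, ctx)
  idx <- build_match_index(lib, max_mm = 1)
  ct1 <- count_single_end(tly$unique1, idx, tly$stats1, lib)
  ct2 <- count_single_end(tly$unique2, idx, tly$stats2, lib)
  combo <- count_paired_end(tly, ct1, ct2)
  expect_equal(combo$totals$total_pairs, 0L)
  expect_equal(nrow(combo$combos), 0)
  expect_equal(sum(combo$marginal1), 0L)
})
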