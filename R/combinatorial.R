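UNTRIMMED_TOKEN <- "<untrimmed>"
PAIR_SEP <- "\x1f"   # cannot occur in a nucleotide string or the token

#' Tally unique candidate pairs from synchronized paired-end files
#'
#' Runs the single-end trimming machinery over both mates in one
#' synchronized pass.  Each read pair contributes exactly one candidate pair
#' (an untrimmed mate is represented by the token `<untrimmed>`); per-mate
#' unique-sequence tables are tallied simultaneously so the single-end
#' counting engine can be reused for the per-mate assignment maps.
#'
#' @param r1_path,r2_path mate FASTQ(.gz) paths; must hold the same number
#'   of records in matching order.
#' @param context1,context2 per-mate [cassette_context][detect_context]
#'   objects (R2 typically has its own orientation and anchors).
#' @param max_anchor_mm,slack trimming parameters, see [trim_reads()].
#' @param check_ids cross-check mate read ids position by position (the
#'   leading token before any `/1`, `/2` or space suffix).
#' @param chunk_size records per chunk.
#' @return list with `pairs` (data.frame `seq1`, `seq2`, `count`), `unique1`,
#'   `unique2` (per-mate unique-sequence tables over trimmed candidates),
#'   `stats1`, `stats2` (per-mate trim stats) and `total_pairs`.
#' @export
tally_unique_pairs <- function(r1_path, r2_path, context1, context2,
                               max_anchor_mm = 2L, slack = 1L,
                               check_ids = FALSE, chunk_size = 100000L) {
  h1 <- fastq_open(r1_path)
  h2 <- fastq_open(r2_path)
  on.exit({ fastq_close(h1); fastq_close(h2) })
  pair_acc <- integer()
  acc1 <- integer()
  acc2 <- integer()
  total <- 0L
  trimmed1 <- 0L
  trimmed2 <- 0L
  repeat {
    c1 <- fastq_next(h1, n = chunk_size)
    c2 <- fastq_next(h2, n = chunk_size)
    if (is.null(c1) && is.null(c2)) break
    n1 <- if (is.null(c1)) 0L else nrow(c1)
    n2 <- if (is.null(c2)) 0L else nrow(c2)
    if (n1 != n2)
      stop_gc("gc_mate_count_mismatch",
              "R1 and R2 have different record counts (at read %d)",
              total + max(n1, n2))
    if (check_ids) {
      id1 <- sub("[/ ].*$", "", c1$read_id)
      id2 <- sub("[/ ].*$", "", c2$read_id)
      bad <- which(id1 != id2)
      if (length(bad))
        stop_gc("gc_mate_id_mismatch",
                "mate read ids differ at position %d: '%s' vs '%s'",
                total + bad[1L], id1[bad[1L]], id2[bad[1L]])
    }
    total <- total + n1
    t1 <- trim_reads(c1$sequence, context1, max_anchor_mm, slack)
    t2 <- trim_reads(c2$sequence, context2, max_anchor_mm, slack)
    s1 <- ifelse(t1$trimmed, t1$candidate, UNTRIMMED_TOKEN)
    s2 <- ifelse(t2$trimmed, t2$candidate, UNTRIMMED_TOKEN)
    trimmed1 <- trimmed1 + sum(t1$trimmed)
    trimmed2 <- trimmed2 + sum(t2$trimmed)
    pair_acc <- merge_counts(pair_acc, table(paste(s1, s2, sep = PAIR_SEP)))
    if (any(t1$trimmed)) acc1 <- merge_counts(acc1, table(t1$candidate[t1$trimmed]))
    if (any(t2$trimmed)) acc2 <- merge_counts(acc2, table(t2$candidate[t2$trimmed]))
  }
  if (length(pair_acc) == 0L)
    pair_acc <- stats::setNames(integer(), character())
  pair_acc <- pair_acc[order(names(pair_acc), method = "radix")]
  halves <- strsplit(names(pair_acc), PAIR_SEP, fixed = TRUE)
  pairs <- data.frame(
    seq1 = vapply(halves, `[`, "", 1L),
    seq2 = vapply(halves, `[`, "", 2L),
    count = as.integer(unname(pair_acc)),
    stringsAsFactors = FALSE)
  list(pairs = pairs,
       unique1 = new_unique_table(acc1), unique2 = new_unique_table(acc2),
       stats1 = list(total = total, trimmed = trimmed1,
                     untrimmed = total - trimmed1),
       stats2 = list(total = total, trimmed = trimmed2,
                     untrimmed = total - trimmed2),
       total_pairs = total)
}

#' Resolve unique candidate pairs into a guide-pair count table
#'
#' Each unique candidate pair is resolved once through the per-mate
#' assignment maps: both mates uniquely assigned increments the ordered
#' guide pair `(R1 guide, R2 guide)`; a pair with any ambiguous mate is
#' excluded (`ambiguous_involved` -- a wrong pair is worse than a lost pair
#' for recombination analysis); exactly one unique mate is `partial`; and
#' pairs with neither mate unique and none ambiguous are `neither`.
#' Combinations are not symmetrized -- `(g1, g2)` and `(g2, g1)` are
#' different constructs -- unless `collapse_orientation` is set.
#'
#' @param pair_tally result of [tally_unique_pairs()].
#' @param counts1,counts2 per-mate [count_table][count_single_end] objects
#'   built from `pair_tally$unique1` / `unique2` (their `assignments` maps
#'   must cover every non-token candidate).
#' @param collapse_orientation merge `(a, b)` and `(b, a)` into the
#'   lexicographically ordered pair, for libraries where cassette order is
#'   meaningless.
#' @return An object of class `combo_count_table`: list with `combos`
#'   (data.frame `guide_id_1`, `guide_id_2`, `count`), `totals`
#'   (`total_pairs`, `both_assigned`, `partial`, `neither`,
#'   `ambiguous_involved`) and `marginal1` / `marginal2` (named per-guide
#'   count vectors over both-unique pairs).
#' @export
count_paired_end <- function(pair_tally, counts1, counts2,
                             collapse_orientation = FALSE) {
  pairs <- pair_tally$pairs
  look1 <- assignment_lookup(counts1$assignments)
  look2 <- assignment_lookup(counts2$assignments)
  n <- nrow(pairs)
  st1 <- resolve_status(pairs$seq1, look1)
  st2 <- resolve_status(pairs$seq2, look2)
  any_amb <- st1$status == "ambiguous" | st2$status == "ambiguous"
  both <- st1$status == "unique" & st2$status == "unique" & !any_amb
  one <- xor(st1$status == "unique", st2$status == "unique") & !any_amb
  neither <- !both & !one & !any_amb
  combos <- data.frame(guide_id_1 = character(), guide_id_2 = character(),
                       count = integer(), stringsAsFactors = FALSE)
  if (any(both)) {
    g1 <- st1$guide_id[both]
    g2 <- st2$guide_id[both]
    if (collapse_orientation) {
      swap <- g1 > g2
      tmp <- g1[swap]; g1[swap] <- g2[swap]; g2[swap] <- tmp
    }
    key <- paste(g1, g2, sep = PAIR_SEP)
    agg <- tapply(pairs$count[both], key, sum)
    halves <- strsplit(names(agg), PAIR_SEP, fixed = TRUE)
    combos <- data.frame(
      guide_id_1 = vapply(halves, `[`, "", 1L),
      guide_id_2 = vapply(halves, `[`, "", 2L),
      count = as.integer(agg),
      stringsAsFactors = FALSE)
    ord <- order(-combos$count, combos$guide_id_1, combos$guide_id_2,
                 method = "radix")
    combos <- combos[ord, , drop = FALSE]
    rownames(combos) <- NULL
  }
  marginal <- function(g, w, library) {
    m <- integer(nrow(library$entries))
    names(m) <- library$entries$guide_id
    if (length(g)) {
      agg <- tapply(w, g, sum)
      keep <- names(agg) %in% names(m)      # placeholder id has no column
      m[names(agg)[keep]] <- as.integer(agg[keep])
    }
    m
  }
  structure(list(
    combos = combos,
    totals = list(total_pairs = sum(pairs$count),
                  both_assigned = sum(pairs$count[both]),
                  partial = sum(pairs$count[one]),
                  neither = sum(pairs$count[neither]),
                  ambiguous_involved = sum(pairs$count[any_amb])),
    marginal1 = marginal(st1$guide_id[both], pairs$count[both], counts1$library),
    marginal2 = marginal(st2$guide_id[both], pairs$count[both], counts2$library)
  ), class = "combo_count_table")
}

assignment_lookup <- function(assignments) {
  env <- new.env(parent = emptyenv(), size = max(1L, nrow(assignments)))
  for (i in seq_len(nrow(assignments)))
    env[[assignments$candidate[i]]] <-
      list(status = assignments$status[i], guide_id = assignments$guide_id[i])
  env
}

resolve_status <- function(seqs, lookup) {
  n <- length(seqs)
  status <- character(n)
  gid <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (seqs[i] == UNTRIMMED_TOKEN) {
      status[i] <- "untrimmed"
    } else {
      a <- lookup[[seqs[i]]]
      if (is.null(a))
        stop_gc("gc_missing_assignment",
                "candidate '%s' missing from the assignment map", seqs[i])
      status[i] <- a$status
      gid[i] <- a$guide_id
    }
  }
  list(status = status, guide_id = gid)
}

#' @export
print.combo_count_table <- function(x, ...) {
  t <- x$totals
  cat(sprintf(paste0(
    "combo_count_table: %d guide pairs\n",
    "  pairs: %d total, %d both-assigned, %d partial, %d neither, %d ambiguous-involved\n"),
    nrow(x$combos), t$total_pairs, t$both_assigned, t$partial, t$neither,
    t$ambiguous_involved))
  if (nrow(x$combos)) print(utils::head(x$combos, 5))
  invisible(x)
}
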