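# Default cassette constants for simulated reads: the 3' end of a human U6
# promoter (R1 cassette) and the start of the SpCas9 tracrRNA scaffold, the
# flanks a single-guide lentiviral amplicon actually presents.
SIM_ADAPTER5 <- "GTGGAAAGGACGAAACACCG"
SIM_SCAFFOLD3 <- "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGC"
SIM_ADAPTER5_R2 <- "CCTTGGAGAACCACCTTGTTG"
SIM_SCAFFOLD3_R2 <- "GTTTAAGAGCTATGCTGGAAACAGCATAGCAAG"

#' Specify a synthetic staggered-read sample
#'
#' Collects every knob of the read simulator: the guide library and per-guide
#' sampling weights, the constant cassette flanks, the stagger-length
#' distribution (default uniform over 0--7 nt, the standard staggered-primer
#' design window), a uniform per-base substitution rate, a junk-read
#' fraction, an optional template-placeholder contamination, read
#' orientation and length, and the seed all randomness flows from.
#'
#' @param library a [guide_library][read_library].
#' @param n_reads number of reads (or read pairs) to generate.
#' @param frequencies per-guide non-negative sampling weights (recycled
#'   uniform when `NULL`).
#' @param adapter5,scaffold3 constant flanks around the guide.
#' @param stagger_lengths integer set of stagger prefix lengths.
#' @param stagger_weights sampling weights over `stagger_lengths`.
#' @param substitution_rate uniform per-base substitution probability in
#'   `[0, 1)`, applied over the whole read (stagger, anchors, guide and
#'   scaffold alike).
#' @param junk_fraction fraction of reads drawn as fully random sequence.
#' @param placeholder optional placeholder sequence planted instead of a
#'   guide in `placeholder_fraction` of reads.
#' @param placeholder_fraction see `placeholder`.
#' @param orientation `"forward"`, or `"reverse"` to reverse-complement
#'   every read.
#' @param read_length output read length (reads are padded with random bases
#'   or truncated to it).
#' @param seed integer seed; identical seeds give byte-identical FASTQ.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(library, n_reads, frequencies = NULL,
                     adapter5 = SIM_ADAPTER5, scaffold3 = SIM_SCAFFOLD3,
                     stagger_lengths = 0:7, stagger_weights = NULL,
                     substitution_rate = 0, junk_fraction = 0,
                     placeholder = NULL, placeholder_fraction = 0,
                     orientation = c("forward", "reverse"),
                     read_length = 75L, seed = 1L) {
  orientation <- match.arg(orientation)
  nguides <- nrow(library$entries)
  if (is.null(frequencies)) frequencies <- rep(1, nguides)
  stopifnot(length(frequencies) == nguides, all(frequencies >= 0),
            sum(frequencies) > 0, n_reads >= 1,
            substitution_rate >= 0, substitution_rate < 1,
            junk_fraction >= 0, junk_fraction <= 1,
            placeholder_fraction >= 0, placeholder_fraction < 1,
            all(stagger_lengths >= 0))
  if (is.null(stagger_weights)) stagger_weights <- rep(1, length(stagger_lengths))
  stopifnot(length(stagger_weights) == length(stagger_lengths),
            sum(stagger_weights) > 0)
  need <- nchar(adapter5) + max(stagger_lengths) +
    max(library$lengths, if (is.null(placeholder)) 0 else nchar(placeholder))
  if (read_length < need)
    stop_gc("gc_bad_sim_spec",
            "read_length (%d) must cover adapter + max stagger + longest insert (%d)",
            read_length, need)
  structure(list(library = library, n_reads = as.integer(n_reads),
                 frequencies = frequencies, adapter5 = toupper(adapter5),
                 scaffold3 = toupper(scaffold3),
                 stagger_lengths = as.integer(stagger_lengths),
                 stagger_weights = stagger_weights,
                 substitution_rate = substitution_rate,
                 junk_fraction = junk_fraction,
                 placeholder = placeholder,
                 placeholder_fraction = placeholder_fraction,
                 orientation = orientation,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

random_bases <- function(total_len) {
  if (total_len <= 0) return("")
  paste(sample(DNA_BASES, total_len, replace = TRUE), collapse = "")
}

random_seq_vec <- function(lens) {
  vapply(lens, random_bases, "")
}

apply_substitutions <- function(reads, rate) {
  if (rate <= 0) return(reads)
  lens <- nchar(reads)
  offsets <- c(0L, cumsum(lens))
  total <- offsets[length(offsets)]
  hit <- which(stats::runif(total) < rate)
  if (length(hit) == 0L) return(reads)
  read_idx <- findInterval(hit - 1L, offsets[-length(offsets)],
                           rightmost.closed = FALSE)
  pos <- hit - offsets[read_idx]
  for (k in seq_along(hit)) {
    i <- read_idx[k]
    p <- pos[k]
    old <- substr(reads[i], p, p)
    new <- sample(setdiff(DNA_BASES, old), 1L)
    substr(reads[i], p, p) <- new
  }
  reads
}

build_reads <- function(inserts, spec) {
  n <- length(inserts)
  stag_len <- sample(spec$stagger_lengths, n, replace = TRUE,
                     prob = spec$stagger_weights)
  body <- paste0(random_seq_vec(stag_len), spec$adapter5, inserts,
                 spec$scaffold3)
  pad <- pmax(0L, spec$read_length - nchar(body))
  reads <- substr(paste0(body, random_seq_vec(pad)), 1L, spec$read_length)
  apply_substitutions(reads, spec$substitution_rate)
}

# Draw the insert class (guide index, junk, placeholder) for each read.
draw_inserts <- function(spec) {
  n <- spec$n_reads
  ids <- spec$library$entries$guide_id
  w_guides <- spec$frequencies / sum(spec$frequencies)
  p_junk <- spec$junk_fraction
  p_ph <- if (is.null(spec$placeholder)) 0 else spec$placeholder_fraction
  p_guide <- 1 - p_junk - p_ph
  stopifnot(p_guide >= 0)
  class_draw <- sample(c("guide", "junk", "placeholder"), n, replace = TRUE,
                       prob = c(p_guide, p_junk, p_ph))
  guide_idx <- ifelse(class_draw == "guide",
                      sample(seq_along(ids), n, replace = TRUE,
                             prob = w_guides), NA_integer_)
  list(class = class_draw, guide_idx = guide_idx)
}

#' Simulate a single-end staggered FASTQ sample
#'
#' Builds reads as `random stagger prefix + adapter5 + insert + scaffold3`,
#' padded with random bases or truncated to the read length, applies uniform
#' substitutions, reverse-complements the whole read for reverse
#' orientation, and writes FASTQ (gzip when the path ends in `.gz`) with
#' constant quality.  The returned truth table is the exact planted
#' multiset, so error-free simulations can be checked against pipeline
#' output for equality.
#'
#' @param spec a [sim_spec()].
#' @param out FASTQ output path (`.gz` for compressed), or `NULL` to skip
#'   writing.
#' @return An object of class `sim_truth`: list with `counts` (named planted
#'   count per guide id, zeros included), `junk`, `placeholder_count`,
#'   `n_reads` and the spec.
#' @export
simulate_single <- function(spec, out = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(spec$seed)
  draw <- draw_inserts(spec)
  inserts <- character(spec$n_reads)
  is_guide <- draw$class == "guide"
  inserts[is_guide] <- spec$library$entries$sequence[draw$guide_idx[is_guide]]
  is_junk <- draw$class == "junk"
  is_ph <- draw$class == "placeholder"
  inserts[is_ph] <- spec$placeholder %||% ""
  reads <- build_reads(inserts, spec)
  # junk reads are wholly random, not cassette-shaped
  reads[is_junk] <- random_seq_vec(rep(spec$read_length, sum(is_junk)))
  if (spec$orientation == "reverse") reads <- revcomp(reads)
  ids <- sprintf("sim_%06d", seq_len(spec$n_reads))
  if (!is.null(out))
    write_fastq(ids, reads, strrep("I", nchar(reads)), out)
  counts <- integer(nrow(spec$library$entries))
  names(counts) <- spec$library$entries$guide_id
  if (any(is_guide)) {
    tab <- table(spec$library$entries$guide_id[draw$guide_idx[is_guide]])
    counts[names(tab)] <- as.integer(tab)
  }
  structure(list(counts = counts, junk = sum(is_junk),
                 placeholder_count = sum(is_ph),
                 n_reads = spec$n_reads, spec = spec, reads = reads),
            class = "sim_truth")
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a paired-end dual-guide FASTQ sample
#'
#' Draws construct pairs from `pair_weights`, emits order-synchronized R1
#' and R2 files, each mate with its own adapter, scaffold and orientation
#' (R2 defaults to reverse, as the second cassette is typically read from
#' the opposite strand).  An optional `swap_fraction` recombines R2 inserts
#' between read pairs -- emulating lentiviral template switching -- before
#' the truth table is computed, so the truth always reflects what was
#' actually planted.
#'
#' @param spec a [sim_spec()] for the R1 cassette; its library must contain
#'   every guide named in `pairs`.
#' @param pairs data.frame with columns `guide_id_1`, `guide_id_2`, `weight`.
#' @param out_r1,out_r2 mate FASTQ output paths (or `NULL` to skip writing).
#' @param adapter5_r2,scaffold3_r2,orientation_r2 R2 cassette layout.
#' @param swap_fraction fraction of pairs whose R2 insert is re-drawn by
#'   permutation among the swapped pairs.
#' @return An object of class `sim_truth_paired`: list with `pair_counts`
#'   (data.frame `guide_id_1`, `guide_id_2`, `count` of planted, post-swap
#'   pairs), `n_pairs`, `n_swapped`, and the spec.
#' @export
simulate_paired <- function(spec, pairs, out_r1 = NULL, out_r2 = NULL,
                            adapter5_r2 = SIM_ADAPTER5_R2,
                            scaffold3_r2 = SIM_SCAFFOLD3_R2,
                            orientation_r2 = "reverse",
                            swap_fraction = 0) {
  stopifnot(inherits(spec, "sim_spec"),
            all(c("guide_id_1", "guide_id_2", "weight") %in% names(pairs)),
            nrow(pairs) >= 1, all(pairs$weight >= 0), sum(pairs$weight) > 0,
            swap_fraction >= 0, swap_fraction <= 1)
  lib_ids <- spec$library$entries$guide_id
  miss <- setdiff(unique(c(pairs$guide_id_1, pairs$guide_id_2)), lib_ids)
  if (length(miss))
    stop_gc("gc_bad_sim_spec", "pair guides not in library: %s",
            paste(utils::head(miss, 5), collapse = ", "))
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(spec$seed)
  n <- spec$n_reads
  pick <- sample(nrow(pairs), n, replace = TRUE, prob = pairs$weight)
  g1 <- pairs$guide_id_1[pick]
  g2 <- pairs$guide_id_2[pick]
  n_swap <- 0L
  if (swap_fraction > 0 && n > 1) {
    swap <- which(stats::runif(n) < swap_fraction)
    if (length(swap) > 1) {
      g2[swap] <- g2[sample(swap)]
      n_swap <- length(swap)
    }
  }
  seq_of <- stats::setNames(spec$library$entries$sequence, lib_ids)
  r1 <- build_reads(seq_of[g1], spec)
  spec2 <- spec
  spec2$adapter5 <- toupper(adapter5_r2)
  spec2$scaffold3 <- toupper(scaffold3_r2)
  r2 <- build_reads(seq_of[g2], spec2)
  if (spec$orientation == "reverse") r1 <- revcomp(r1)
  if (orientation_r2 == "reverse") r2 <- revcomp(r2)
  ids <- sprintf("sim_%06d", seq_len(n))
  if (!is.null(out_r1)) write_fastq(ids, r1, strrep("I", nchar(r1)), out_r1)
  if (!is.null(out_r2)) write_fastq(ids, r2, strrep("I", nchar(r2)), out_r2)
  key <- paste(g1, g2, sep = PAIR_SEP)
  tab <- table(key)
  halves <- strsplit(names(tab), PAIR_SEP, fixed = TRUE)
  pair_counts <- data.frame(
    guide_id_1 = vapply(halves, `[`, "", 1L),
    guide_id_2 = vapply(halves, `[`, "", 2L),
    count = as.integer(tab), stringsAsFactors = FALSE)
  structure(list(pair_counts = pair_counts, n_pairs = n, n_swapped = n_swap,
                 spec = spec, r1 = r1, r2 = r2),
            class = "sim_truth_paired")
}
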