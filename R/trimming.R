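#' Trim reads against a cassette context
#'
#' Extracts the putative guide sequence from each read.  The 5' anchor is
#' searched at stagger offsets `[stagger_min - slack, stagger_max + slack]`
#' (clipped at zero); among offsets where the Hamming distance between the
#' anchor and the read window is at most `max_anchor_mm`, the
#' minimal-mismatch offset wins, ties broken by the smallest offset.  `N`
#' counts as a mismatch inside the anchor window.  The candidate runs from
#' the end of the 5' anchor to the leftmost 3' anchor match at least
#' `min(guide_lengths)` bases downstream, or to `max(guide_lengths)` bases
#' (clipped at the read end) when there is no 3' anchor match.  Matching is
#' Hamming-only: stagger offsets already absorb positional shifts, so
#' trimming stays gap-free and offsets remain well defined.
#'
#' A read is `untrimmed` (a status, not an error) when no offset qualifies or
#' fewer than `min(guide_lengths)` bases remain after the anchor.
#'
#' @param reads character vector of read sequences.  Reads are
#'   reverse-complemented first when `context$orientation` is `"reverse"`.
#' @param context a [cassette_context][detect_context].
#' @param max_anchor_mm maximum anchor mismatches (default 2).
#' @param slack extra offsets searched beyond the detected stagger window
#'   (default 1; the detection subsample may miss rare stagger lengths).
#' @return data.frame with columns `trimmed` (logical), `candidate`
#'   (character, `NA` when untrimmed), `stagger` and `anchor5_mm` (integer,
#'   `NA` when untrimmed), one row per read.
#' @export
trim_reads <- function(reads, context, max_anchor_mm = 2L, slack = 1L) {
  reads <- as.character(reads)
  if (context$orientation == "reverse") reads <- revcomp(reads)
  # when the constant flank was longer than the stored anchor, the anchor
  # sits anchor5_offset bases into every read's prefix; search there and
  # report stagger relative to the full flank
  off <- context$anchor5_offset %||% 0L
  res <- C_trim_reads(reads, context$anchor5, context$anchor3,
                      as.integer(context$stagger_min + off - slack),
                      as.integer(context$stagger_max + off + slack),
                      as.integer(max_anchor_mm),
                      as.integer(min(context$guide_lengths)),
                      as.integer(max(context$guide_lengths)))
  data.frame(trimmed = res$trimmed, candidate = res$candidate,
             stagger = res$stagger - off, anchor5_mm = res$anchor5_mm,
             stringsAsFactors = FALSE)
}

#' Trim a FASTQ file and tally unique candidate sequences
#'
#' Streams the file in chunks, trims every read with [trim_reads()], and
#' accumulates the multiset of trimmed candidates: the unique-sequence table
#' that decouples matching cost from read depth.
#'
#' @param path FASTQ(.gz) file path.
#' @param context a [cassette_context][detect_context].
#' @inheritParams trim_reads
#' @param chunk_size records per chunk.
#' @return list with `unique` (named integer vector: candidate sequence ->
#'   multiplicity) and `stats` (list `total`, `trimmed`, `untrimmed`).
#' @export
trim_fastq <- function(path, context, max_anchor_mm = 2L, slack = 1L,
                       chunk_size = 100000L) {
  h <- fastq_open(path)
  on.exit(fastq_close(h))
  acc <- integer()
  total <- 0L
  trimmed <- 0L
  repeat {
    chunk <- fastq_next(h, n = chunk_size)
    if (is.null(chunk)) break
    total <- total + nrow(chunk)
    tr <- trim_reads(chunk$sequence, context, max_anchor_mm, slack)
    cand <- tr$candidate[tr$trimmed]
    trimmed <- trimmed + length(cand)
    if (length(cand)) acc <- merge_counts(acc, table(cand))
  }
  list(unique = new_unique_table(acc),
       stats = list(total = total, trimmed = trimmed,
                    untrimmed = total - trimmed))
}

merge_counts <- function(acc, tab) {
  add <- as.integer(tab)
  names(add) <- names(tab)
  hit <- names(add) %in% names(acc)
  if (any(hit)) acc[names(add)[hit]] <- acc[names(add)[hit]] + add[hit]
  c(acc, add[!hit])
}

new_unique_table <- function(x) {
  if (length(x) == 0L) x <- stats::setNames(integer(), character())
  x <- x[order(names(x), method = "radix")]   # canonical order for determinism
  structure(x, class = "unique_seq_table")
}

#' @export
print.unique_seq_table <- function(x, ...) {
  cat(sprintf("unique_seq_table: %d unique sequences, %d reads total\n",
              length(x), sum(x)))
  invisible(x)
}
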