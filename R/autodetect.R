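#' Detect read orientation relative to the guide library
#'
#' Counts subsample reads containing any library sequence as an exact
#' substring (forward evidence) and reads containing any reverse-complemented
#' library sequence (reverse evidence), and returns the majority orientation.
#' The library is used exactly as given: a guide and its reverse complement
#' are distinct sequences, each scoring for its own orientation.
#'
#' @param reads character vector of read sequences (a subsample, typically
#'   the first 10,000 records of the file).
#' @param library a [guide_library][read_library].
#' @param min_hit_frac minimum fraction of subsample reads that must contain
#'   a guide in the winning orientation; below it detection fails with a
#'   named error (wrong library or corrupt data).
#' @return `"forward"` or `"reverse"`, with attributes `hits_forward` and
#'   `hits_reverse`.
#' @export
detect_orientation <- function(reads, library, min_hit_frac = 0.05) {
  reads <- as.character(reads)
  n <- length(reads)
  if (n < 1L) stop_gc("gc_empty_subsample", "orientation detection needs at least one read")
  seqs <- library$entries$sequence
  f <- sum(C_scan_guides(reads, seqs)$n_occ > 0L)
  r <- sum(C_scan_guides(reads, revcomp(seqs))$n_occ > 0L)
  if (max(f, r) / n < min_hit_frac)
    stop_gc("gc_orientation_failure",
            "orientation detection failed: %d/%d forward and %d/%d reverse subsample reads contain a library guide (threshold %.2f) - wrong library or corrupt data?",
            f, n, r, n, min_hit_frac)
  structure(if (f >= r) "forward" else "reverse",
            hits_forward = f, hits_reverse = r)
}

#' Detect the cassette context from a read subsample
#'
#' For every subsample read containing exactly one library guide as an exact
#' substring (reads are reverse-complemented first when `orientation` is
#' `"reverse"`; reads with two or more distinct guide hits are skipped as
#' ambiguous anchor evidence), the bases before the guide (prefix) and after
#' it (suffix) are recorded.  The 5' anchor is the longest string that is a
#' suffix of at least `anchor_consensus_frac` of all recorded prefixes,
#' grown base by base and truncated to `max_anchor_len`; the 3' anchor is
#' built analogously from suffix prefixes and may be empty.  The stagger
#' window is the range of (prefix length - anchor length) over the
#' anchor-bearing prefixes, clipped to `[0, stagger_cap]`.
#'
#' @param reads character vector of subsample read sequences.
#' @param library a [guide_library][read_library].
#' @param orientation `"forward"` or `"reverse"` (from
#'   [detect_orientation()]).
#' @param stagger_cap maximum believable stagger length (nt); a wider
#'   inferred window raises a named error (adapter heterogeneity).
#' @param anchor_consensus_frac consensus fraction for anchor growth.
#' @param min_anchor_len minimum acceptable 5' anchor length.
#' @param max_anchor_len anchor truncation length.
#' @return An object of class `cassette_context`: list with `orientation`,
#'   `anchor5`, `anchor5_offset` (bases of additional constant flank 5' of
#'   the stored anchor, non-zero only when the flank exceeds
#'   `max_anchor_len`), `anchor3`, `stagger_min`, `stagger_max`,
#'   `guide_lengths`.
#' @export
detect_context <- function(reads, library, orientation = "forward",
                           stagger_cap = 8L, anchor_consensus_frac = 0.9,
                           min_anchor_len = 6L, max_anchor_len = 20L) {
  reads <- as.character(reads)
  if (length(reads) < 1L)
    stop_gc("gc_empty_subsample", "context detection needs at least one read")
  if (orientation == "reverse") reads <- revcomp(reads)
  seqs <- library$entries$sequence
  scan <- C_scan_guides(reads, seqs)
  keep <- scan$n_occ == 1L & scan$n_distinct == 1L
  if (!any(keep))
    stop_gc("gc_no_guide_reads",
            "no subsample read contains exactly one library guide; cannot infer anchors")
  pos <- scan$pos[keep]                     # 0-based guide start
  glen <- nchar(seqs)[scan$guide[keep]]
  rd <- reads[keep]
  prefixes <- substr(rd, 1L, pos)
  suffixes <- substr(rd, pos + glen + 1L, nchar(rd))

  # the full constant flank may exceed max_anchor_len; measure it whole so
  # the stagger window stays anchored to the true random-prefix length, then
  # keep only the guide-proximal max_anchor_len bases as the search anchor
  flank <- grow_consensus(prefixes, side = "suffix",
                          frac = anchor_consensus_frac,
                          max_len = max(nchar(prefixes)))
  if (nchar(flank) < min_anchor_len)
    stop_gc("gc_anchor_too_short",
            "no constant 5' flank of length >= %d found (consensus anchor: '%s')",
            min_anchor_len, flank)
  anchor5 <- substr(flank, max(1L, nchar(flank) - max_anchor_len + 1L),
                    nchar(flank))
  anchor5_offset <- nchar(flank) - nchar(anchor5)
  anchor3 <- grow_consensus(suffixes, side = "prefix",
                            frac = anchor_consensus_frac,
                            max_len = max_anchor_len)

  plen <- nchar(prefixes)
  bearing <- plen >= nchar(flank) &
    substr(prefixes, plen - nchar(flank) + 1L, plen) == flank
  stag <- plen[bearing] - nchar(flank)
  if (max(stag) - min(stag) > stagger_cap)
    stop_gc("gc_stagger_too_wide",
            "inferred stagger window [%d, %d] is wider than the cap (%d): heterogeneous adapters?",
            min(stag), max(stag), stagger_cap)
  stag <- pmin(pmax(stag, 0L), stagger_cap)
  structure(list(orientation = orientation,
                 anchor5 = anchor5, anchor5_offset = anchor5_offset,
                 anchor3 = anchor3,
                 stagger_min = min(stag), stagger_max = max(stag),
                 guide_lengths = library$lengths),
            class = "cassette_context")
}

# Grow the longest string occurring as a suffix (or prefix) of >= frac of
# the input strings, one base at a time from the guide-proximal end.
grow_consensus <- function(strings, side = c("suffix", "prefix"), frac,
                           max_len) {
  side <- match.arg(side)
  n <- length(strings)
  lens <- nchar(strings)
  anchor <- ""
  has <- rep(TRUE, n)          # strings currently ending/starting with anchor
  repeat {
    k <- nchar(anchor) + 1L
    if (k > max_len) break
    ok <- has & lens >= k
    if (!any(ok)) break
    ch <- if (side == "suffix") substr(strings[ok], lens[ok] - k + 1L, lens[ok] - k + 1L)
          else substr(strings[ok], k, k)
    tab <- table(ch)
    best <- names(tab)[which.max(tab)]
    hit <- ok
    hit[ok] <- ch == best
    if (sum(hit) / n < frac) break
    anchor <- if (side == "suffix") paste0(best, anchor) else paste0(anchor, best)
    has <- hit
  }
  anchor
}

#' @export
print.cassette_context <- function(x, ...) {
  cat(sprintf("cassette_context: orientation %s\n  anchor5: %s\n  anchor3: %s\n  stagger window: [%d, %d]\n  guide lengths: {%s}\n",
              x$orientation, x$anchor5,
              if (nzchar(x$anchor3)) x$anchor3 else "(empty)",
              x$stagger_min, x$stagger_max,
              paste(x$guide_lengths, collapse = ",")))
  invisible(x)
}

#' Find the 3Cs template placeholder sequence from a vector map
#'
#' Covalently-closed-circular-synthesized (3Cs) gRNA libraries are built from
#' a template vector whose placeholder insert can persist in the sequenced
#' sample.  This locates the detected anchors in the vector map (both
#' strands; the origin is wrapped for circular maps), extracts the segment
#' between them, and reports it as the placeholder when its length is within
#' +/- `len_tol` of the library guide lengths and it is not itself a library
#' sequence.
#'
#' @param vector_seq vector nucleotide string from [read_vector()].
#' @param context a [cassette_context][detect_context].
#' @param library a [guide_library][read_library].
#' @param reads optional character vector of subsample read sequences used to
#'   count placeholder occurrences (`subsample_hits`).
#' @param len_tol length tolerance around the library guide lengths (nt).
#' @return `NULL` when the vector cassette carries a library guide (the
#'   sample is not template-contaminated); otherwise a `placeholder_info`
#'   list with `sequence`, `source` (`"vector"` or `"both"`) and
#'   `subsample_hits`.
#' @export
find_placeholder <- function(vector_seq, context, library, reads = NULL,
                             len_tol = 2L) {
  v <- toupper(as.character(vector_seq))
  a5 <- context$anchor5
  a3 <- context$anchor3
  gmin <- min(context$guide_lengths) - len_tol
  gmax <- max(context$guide_lengths) + len_tol
  wrap <- nchar(a5) + gmax + max(nchar(a3), 1L) - 1L
  strands <- c(v, revcomp(v))
  inserts <- character()
  for (s in strands) {
    ss <- paste0(s, substr(s, 1L, min(wrap, nchar(s))))
    hits5 <- gregexpr(a5, ss, fixed = TRUE)[[1L]]
    if (hits5[1L] == -1L) next
    hits5 <- hits5[hits5 <= nchar(s)]        # starts within the original seq
    for (q in hits5) {
      start <- q + nchar(a5)
      if (nzchar(a3)) {
        rest <- substr(ss, start, min(nchar(ss), start + gmax + nchar(a3)))
        p <- regexpr(a3, rest, fixed = TRUE)[1L]
        if (p == -1L) next
        ins <- substr(rest, 1L, p - 1L)
      } else {
        ins <- substr(ss, start, start + max(context$guide_lengths) - 1L)
      }
      if (nchar(ins) >= gmin && nchar(ins) <= gmax)
        inserts <- c(inserts, ins)
    }
  }
  inserts <- unique(inserts)
  if (length(inserts) == 0L)
    stop_gc("gc_anchors_not_found",
            "cassette anchors not found in the vector map")
  in_lib <- inserts %in% library$entries$sequence
  if (any(in_lib)) return(NULL)
  if (length(inserts) > 1L)
    stop_gc("gc_conflicting_cassettes",
            "multiple candidate cassettes with conflicting inserts found in the vector: %s",
            paste(utils::head(inserts, 3), collapse = ", "))
  hits <- 0L
  if (!is.null(reads) && length(reads)) {
    tr <- trim_reads(reads, context)
    hits <- sum(tr$candidate == inserts, na.rm = TRUE)
  }
  structure(list(sequence = inserts,
                 source = if (hits > 0L) "both" else "vector",
                 subsample_hits = hits),
            class = "placeholder_info")
}
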