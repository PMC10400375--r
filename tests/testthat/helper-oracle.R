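# Independent brute-force oracles, written against base R only and never
# calling into the package's index/trimming internals.

r_revcomp <- function(x) {
  vapply(strsplit(chartr("ACGTacgt", "TGCAtgca", x), ""),
         function(ch) paste(rev(ch), collapse = ""), "")
}

r_hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Brute-force assignment of one candidate against every library entry.
# Mirrors the documented policy: equal length only, Hamming <= max_mm,
# duplicate sequences collapse to the first-in-file id, ties -> ambiguous.
brute_match <- function(candidate, lib, max_mm, placeholder = NULL) {
  ids <- lib$entries$guide_id
  seqs <- lib$entries$sequence
  if (!is.null(placeholder)) {
    ids <- c(ids, "3Cs_placeholder")
    seqs <- c(seqs, placeholder)
  }
  canonical <- ids[match(seqs, seqs)]
  same <- nchar(seqs) == nchar(candidate)
  if (!any(same)) return(list(status = "unaligned"))
  d <- vapply(seqs[same], r_hamming, 0L, a = candidate, USE.NAMES = FALSE)
  keep <- d <= max_mm
  if (!any(keep)) return(list(status = "unaligned"))
  dmin <- min(d[keep])
  best <- unique(canonical[same][keep][d[keep] == dmin])
  if (length(best) == 1L)
    list(status = "unique", guide_id = best, mismatches = dmin)
  else list(status = "ambiguous", candidates = sort(best))
}

# Naive per-read counting pipeline: every read's candidate matched
# individually by brute force, no unique-sequence tally.
naive_count <- function(candidates, lib, max_mm, placeholder = NULL) {
  counts <- integer(nrow(lib$entries))
  names(counts) <- lib$entries$guide_id
  ambiguous <- 0L
  unaligned <- 0L
  ph <- 0L
  for (cand in candidates) {
    a <- brute_match(cand, lib, max_mm, placeholder)
    if (a$status == "unique") {
      if (identical(a$guide_id, "3Cs_placeholder")) ph <- ph + 1L
      else counts[a$guide_id] <- counts[a$guide_id] + 1L
    } else if (a$status == "ambiguous") ambiguous <- ambiguous + 1L
    else unaligned <- unaligned + 1L
  }
  list(counts = counts, ambiguous = ambiguous, unaligned = unaligned,
       placeholder = ph)
}

# Exhaustive offset scan for trimming: all anchor5 placements, minimal
# mismatches, smallest offset on ties.
oracle_trim <- function(read, anchor5, omin, omax, max_mm) {
  best <- NULL
  for (o in max(0, omin):omax) {
    if (o + nchar(anchor5) > nchar(read)) break
    w <- substr(read, o + 1, o + nchar(anchor5))
    mm <- r_hamming(w, anchor5)
    if (mm <= max_mm && (is.null(best) || mm < best$mm))
      best <- list(offset = o, mm = mm)
  }
  best
}

# All Hamming-distance-1 neighbours of a sequence over {A,C,G,T}.
neighbours1 <- function(seq) {
  out <- character(0)
  for (p in seq_len(nchar(seq))) {
    for (b in setdiff(BASES, substr(seq, p, p))) {
      s <- seq
      substr(s, p, p) <- b
      out <- c(out, s)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
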