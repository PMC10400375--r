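PLACEHOLDER_ID <- "3Cs_placeholder"

#' Build the match index for a guide library
#'
#' The index has two layers: an exact hash from full sequence to guide id,
#' and -- for `max_mm >= 1` -- a pigeonhole index in which every library
#' sequence is split into `max_mm + 1` contiguous near-equal segments, each
#' keyed by (segment ordinal, segment string, sequence length).  A candidate
#' within Hamming distance `max_mm` of a library sequence must match at least
#' one segment exactly, so looking up the candidate's own segments retrieves
#' a complete superset of its true neighbours, which are then verified by
#' Hamming distance.
#'
#' Entries sharing an identical sequence resolve to the first-in-file
#' (canonical) id.  A template placeholder, when provided, is indexed under
#' the reserved id `3Cs_placeholder`.
#'
#' @param library a [guide_library][read_library].
#' @param placeholder optional [placeholder_info][find_placeholder] (or a
#'   bare placeholder sequence string).
#' @param max_mm maximum Hamming mismatches the index must support (0, 1
#'   or 2).
#' @return an opaque `match_index` object.
#' @export
build_match_index <- function(library, placeholder = NULL, max_mm = 1L) {
  stopifnot(max_mm %in% 0:2)
  if (PLACEHOLDER_ID %in% library$entries$guide_id && !is.null(placeholder))
    stop_gc("gc_reserved_id",
            "library entry named '%s' collides with the reserved placeholder id",
            PLACEHOLDER_ID)
  ids <- library$entries$guide_id
  seqs <- library$entries$sequence
  # duplicate sequences -> canonical first-in-file id
  canonical <- ids[match(seqs, seqs)]
  dup_flag <- seqs %in% names(library$duplicate_groups)
  if (!is.null(placeholder)) {
    pseq <- if (inherits(placeholder, "placeholder_info")) placeholder$sequence
            else as.character(placeholder)
    ids <- c(ids, PLACEHOLDER_ID)
    seqs <- c(seqs, pseq)
    canonical <- c(canonical, PLACEHOLDER_ID)
    dup_flag <- c(dup_flag, FALSE)
  }
  exact <- new.env(parent = emptyenv(), size = length(seqs))
  for (i in seq_along(seqs))
    if (is.null(exact[[seqs[i]]])) exact[[seqs[i]]] <- i
  pigeon <- new.env(parent = emptyenv())
  lens <- sort(unique(nchar(seqs)))
  bounds <- lapply(lens, segment_bounds, k = max_mm + 1L)
  names(bounds) <- as.character(lens)
  if (max_mm >= 1L) {
    for (i in seq_along(seqs)) {
      b <- bounds[[as.character(nchar(seqs[i]))]]
      for (j in seq_len(nrow(b))) {
        key <- paste0(j, ":", nchar(seqs[i]), ":",
                      substr(seqs[i], b[j, 1L], b[j, 2L]))
        pigeon[[key]] <- c(pigeon[[key]], i)
      }
    }
  }
  structure(list(ids = ids, seqs = seqs, canonical = canonical,
                 dup_flag = dup_flag, exact = exact, pigeon = pigeon,
                 bounds = bounds, lengths = lens, max_mm = as.integer(max_mm),
                 has_placeholder = !is.null(placeholder)),
            class = "match_index")
}

#' @export
print.match_index <- function(x, ...) {
  cat(sprintf("match_index: %d sequences (placeholder: %s), max_mm = %d, lengths {%s}\n",
              length(x$seqs), if (x$has_placeholder) "yes" else "no",
              x$max_mm, paste(x$lengths, collapse = ",")))
  invisible(x)
}

#' Match one candidate sequence against the index
#'
#' An exact hit is `unique` with 0 mismatches (duplicated library sequences
#' resolve to the canonical id, flagged).  Otherwise the candidate's
#' pigeonhole segments nominate equal-length library sequences which are
#' verified by Hamming distance: a single guide at the minimal distance
#' `<= max_mm` is `unique`; two or more distinct guides tied at the minimal
#' distance are `ambiguous`; none is `unaligned`.  Candidates whose length
#' matches no library length are `unaligned` without search, and `N`
#' mismatches every base.
#'
#' @param candidate nucleotide string.
#' @param index a [match_index][build_match_index].
#' @param max_mm maximum mismatches for this query (defaults to, and may not
#'   exceed, the index's `max_mm`).
#' @return list with `status` (`"unique"`, `"ambiguous"`, `"unaligned"`),
#'   and when relevant `guide_id`, `mismatches`, `duplicate` (canonical-id
#'   flag) or `candidates` (the tied guide ids).
#' @export
match_sequence <- function(candidate, index, max_mm = index$max_mm) {
  stopifnot(nzchar(candidate), max_mm <= index$max_mm)
  i <- index$exact[[candidate]]
  if (!is.null(i))
    return(list(status = "unique", guide_id = index$canonical[i],
                mismatches = 0L, duplicate = index$dup_flag[i]))
  L <- nchar(candidate)
  if (max_mm == 0L || !(L %in% index$lengths))
    return(list(status = "unaligned"))
  b <- index$bounds[[as.character(L)]]
  hits <- integer()
  for (j in seq_len(nrow(b))) {
    key <- paste0(j, ":", L, ":", substr(candidate, b[j, 1L], b[j, 2L]))
    hits <- c(hits, index$pigeon[[key]])
  }
  hits <- unique(hits)
  if (length(hits) == 0L) return(list(status = "unaligned"))
  d <- C_hamming_vec(candidate, index$seqs[hits])
  keep <- !is.na(d) & d <= max_mm
  if (!any(keep)) return(list(status = "unaligned"))
  hits <- hits[keep]
  d <- d[keep]
  dmin <- min(d)
  best <- unique(index$canonical[hits[d == dmin]])
  if (length(best) == 1L)
    return(list(status = "unique", guide_id = best, mismatches = dmin,
                duplicate = any(index$dup_flag[hits[d == dmin]])))
  list(status = "ambiguous", candidates = sort(best))
}

#' Count a single-end sample from its unique-sequence table
#'
#' The heart of unique-first counting: every unique trimmed candidate is
#' matched against the library exactly once, then multiplicities are expanded
#' into per-guide counts.  Ambiguous candidates are excluded from per-guide
#' counts and reported in the totals, which keeps the conservation identity
#' `sum(counts) + placeholder + ambiguous + unaligned = trimmed` exact.
#'
#' @param unique named integer vector (candidate sequence -> multiplicity),
#'   e.g. from [trim_fastq()].
#' @param index a [match_index][build_match_index].
#' @param trim_stats list with `total`, `trimmed`, `untrimmed` (from
#'   [trim_fastq()]); `sum(unique)` must equal `trimmed`.
#' @param library the [guide_library][read_library] behind the index.
#' @return An object of class `count_table`: list with
#'   \describe{
#'     \item{counts}{named integer vector over all library guide ids (library
#'       order, zeros included; duplicated sequences count under the
#'       canonical id),}
#'     \item{totals}{`total_reads`, `trimmed`, `untrimmed`, `assigned`,
#'       `ambiguous`, `unaligned`,}
#'     \item{placeholder_count}{reads matching the template placeholder,}
#'     \item{unaligned}{unique-sequence table of unaligned candidates,}
#'     \item{assignments}{data.frame mapping every unique candidate to its
#'       assignment (`status`, `guide_id`, `mismatches`), reused by the
#'       combinatorial pipeline.}
#'   }
#' @export
count_single_end <- function(unique, index, trim_stats, library) {
  mult <- as.integer(unname(unique))
  cand <- names(unique) %||% character(0)
  if (sum(mult) != trim_stats$trimmed)
    stop_gc("gc_inconsistent_totals",
            "unique-table total (%d) does not equal trimmed read count (%d)",
            sum(mult), trim_stats$trimmed)
  n <- length(cand)
  status <- character(n)
  gid <- rep(NA_character_, n)
  mm <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    a <- match_sequence(cand[i], index)
    status[i] <- a$status
    if (a$status == "unique") {
      gid[i] <- a$guide_id
      mm[i] <- a$mismatches
    }
  }
  ids <- library$entries$guide_id
  counts <- integer(length(ids))
  names(counts) <- ids
  is_ph <- status == "unique" & gid == PLACEHOLDER_ID
  guide_hit <- status == "unique" & !is_ph
  if (any(guide_hit)) {
    agg <- tapply(mult[guide_hit], gid[guide_hit], sum)
    counts[names(agg)] <- as.integer(agg)
  }
  unaligned <- new_unique_table(
    stats::setNames(mult[status == "unaligned"], cand[status == "unaligned"]))
  structure(list(
    counts = counts,
    totals = list(total_reads = trim_stats$total,
                  trimmed = trim_stats$trimmed,
                  untrimmed = trim_stats$untrimmed,
                  assigned = sum(mult[guide_hit]),
                  ambiguous = sum(mult[status == "ambiguous"]),
                  unaligned = sum(mult[status == "unaligned"])),
    placeholder_count = sum(mult[is_ph]),
    unaligned = unaligned,
    assignments = data.frame(candidate = cand, status = status,
                             guide_id = gid, mismatches = mm,
                             stringsAsFactors = FALSE),
    library = library
  ), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  t <- x$totals
  cat(sprintf(paste0(
    "count_table: %d guides\n",
    "  reads: %d total, %d trimmed, %d untrimmed\n",
    "  assigned %d, ambiguous %d, unaligned %d, placeholder %d\n"),
    length(x$counts), t$total_reads, t$trimmed, t$untrimmed,
    t$assigned, t$ambiguous, t$unaligned, x$placeholder_count))
  invisible(x)
}

#' @export
summary.count_table <- function(object, ...) {
  print(object)
  cat("top guides:\n")
  print(utils::head(sort(object$counts, decreasing = TRUE), 5))
  invisible(object)
}
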