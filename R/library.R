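#' Read a guide RNA library
#'
#' Parses a gRNA library from CSV (columns for id and sequence, optional gene)
#' or FASTA (record headers become guide ids).  Sequences are uppercased and
#' validated against the strict DNA alphabet `{A,C,G,T}`; entries sharing an
#' identical sequence are grouped (not rejected) so that counting can assign
#' them to one canonical id.
#'
#' CSV column names are matched case-insensitively against the synonym sets
#' `{id, guide_id, name}`, `{seq, sequence}` and `{gene, gene_symbol}`.
#'
#' @param path path to the library file.
#' @param format `"csv"`, `"fasta"`, or `"auto"` (sniff: a leading `>` means
#'   FASTA).
#' @return An object of class `guide_library`: a list with
#'   \describe{
#'     \item{entries}{data.frame with columns `guide_id`, `sequence`, `gene`
#'       in file order,}
#'     \item{duplicate_groups}{named list; one character vector of guide ids
#'       per sequence shared by two or more entries,}
#'     \item{lengths}{sorted integer vector of distinct sequence lengths.}
#'   }
#' @export
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' writeLines(c("id,seq", "g1,ACGTACGTACGTACGTACGT"), tmp)
#' read_library(tmp)
read_library <- function(path, format = c("auto", "csv", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path) || dir.exists(path))
    stop_gc("gc_missing_file", "library file not found: %s", path)
  if (file.size(path) == 0)
    stop_gc("gc_empty_file", "library file is empty: %s", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (length(first) && startsWith(first, ">")) "fasta" else "csv"
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    ids <- names(set)
    ids <- sub("\\s.*$", "", ids)  # FASTA description after first whitespace
    seqs <- as.character(set)
    genes <- rep(NA_character_, length(ids))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
    nm <- tolower(names(df))
    id_col <- which(nm %in% c("id", "guide_id", "name"))[1]
    seq_col <- which(nm %in% c("seq", "sequence"))[1]
    gene_col <- which(nm %in% c("gene", "gene_symbol"))[1]
    if (is.na(id_col) || is.na(seq_col))
      stop_gc("gc_missing_columns",
              "library CSV must have an id column (id/guide_id/name) and a sequence column (seq/sequence); found: %s",
              paste(names(df), collapse = ", "))
    ids <- df[[id_col]]
    seqs <- df[[seq_col]]
    genes <- if (is.na(gene_col)) rep(NA_character_, nrow(df)) else df[[gene_col]]
  }
  new_guide_library(ids, seqs, genes)
}

new_guide_library <- function(ids, seqs, genes = NULL) {
  if (is.null(genes)) genes <- rep(NA_character_, length(ids))
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) == 0)
    stop_gc("gc_empty_library", "guide library has no entries")
  if (any(is.na(ids) | !nzchar(ids)))
    stop_gc("gc_bad_id", "guide ids must be non-empty")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_gc("gc_duplicate_id", "duplicate guide_id in library: %s",
            paste(utils::head(dup, 5), collapse = ", "))
  bad <- which(!is_dna(seqs))
  if (length(bad))
    stop_gc("gc_bad_sequence",
            "library sequences must be non-empty over {A,C,G,T}; offending id(s): %s",
            paste(utils::head(ids[bad], 5), collapse = ", "))
  lens <- nchar(seqs)
  if (any(lens < 10 | lens > 60))
    stop_gc("gc_bad_sequence",
            "library sequence lengths must be in [10, 60]; offending id(s): %s",
            paste(utils::head(ids[lens < 10 | lens > 60], 5), collapse = ", "))
  dup_seqs <- unique(seqs[duplicated(seqs)])
  duplicate_groups <- lapply(dup_seqs, function(s) ids[seqs == s])
  names(duplicate_groups) <- dup_seqs
  structure(list(
    entries = data.frame(guide_id = ids, sequence = seqs, gene = genes,
                         stringsAsFactors = FALSE),
    duplicate_groups = duplicate_groups,
    lengths = sort(unique(lens))
  ), class = "guide_library")
}

#' @export
print.guide_library <- function(x, ...) {
  cat(sprintf("guide_library: %d guides, lengths {%s}, %d duplicate group(s)\n",
              nrow(x$entries), paste(x$lengths, collapse = ","),
              length(x$duplicate_groups)))
  print(utils::head(x$entries, 5))
  if (nrow(x$entries) > 5) cat(sprintf("... and %d more\n", nrow(x$entries) - 5))
  invisible(x)
}

#' @export
length.guide_library <- function(x) nrow(x$entries)
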