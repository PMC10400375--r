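DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement over the DNA alphabet; `N` (and any other
#' letter) maps to itself, case is preserved.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAC"))
revcomp <- function(x) {
  C_revcomp(as.character(x))
}

# Hamming distance with strict length check; N mismatches everything.
hamming <- function(a, b) C_hamming(a, b)

is_dna <- function(x) {
  !is.na(x) & nzchar(x) & !grepl("[^ACGT]", x)
}

stop_gc <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "guidecounter_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Contiguous near-equal segmentation of a length-L string into k parts;
# returns a 2-column matrix of 1-based [start, end] bounds.
segment_bounds <- function(L, k) {
  sizes <- rep(L %/% k, k)
  extra <- L %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  cbind(start = c(1L, head(ends, -1L) + 1L), end = ends)
}

# Quote CSV fields per RFC 4180 only when needed; always UNIX newlines.
csv_field <- function(x) {
  x <- as.character(x)
  need <- grepl('[",\n\r]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}

write_csv_lines <- function(header, rows, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n")
  invisible(path)
}
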