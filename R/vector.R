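#' Read a vector (plasmid) map
#'
#' Accepts a single-record FASTA or GenBank flat file and returns the
#' uppercase vector sequence.  Proprietary binary SnapGene `.dna` files are
#' not parsed; passing one raises a named error pointing at the supported
#' formats.
#'
#' @param path path to a FASTA or GenBank file containing exactly one
#'   sequence.
#' @return uppercase nucleotide string, with attribute `circular` (TRUE for
#'   GenBank records declared circular, FALSE otherwise).
#' @export
read_vector <- function(path) {
  if (!file.exists(path) || dir.exists(path))
    stop_gc("gc_missing_file", "vector file not found: %s", path)
  magic <- readBin(path, "raw", n = 4L)
  # SnapGene .dna starts with a 0x09 block tag followed by a length word
  if (length(magic) >= 1 && magic[1] == as.raw(0x09))
    stop_gc("gc_snapgene_unsupported",
            "binary SnapGene .dna maps are not supported; export the vector as GenBank or FASTA")
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L)
    stop_gc("gc_empty_file", "vector file is empty: %s", path)
  if (startsWith(first, ">")) {
    set <- Biostrings::readBStringSet(path)
    if (length(set) != 1L)
      stop_gc("gc_multi_record",
              "vector FASTA must contain exactly one record, found %d", length(set))
    seq <- toupper(as.character(set[[1L]]))
    circular <- FALSE
  } else if (grepl("^LOCUS", first)) {
    parsed <- parse_genbank(path)
    seq <- parsed$sequence
    circular <- parsed$circular
  } else {
    stop_gc("gc_bad_format",
            "vector file is neither FASTA nor GenBank flat file: %s", path)
  }
  if (!nzchar(seq))
    stop_gc("gc_empty_sequence", "vector sequence is empty: %s", path)
  structure(seq, circular = circular)
}

# Minimal GenBank flat-file parser: LOCUS line (circular flag), ORIGIN block
# up to '//' with position numbers and whitespace stripped.
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines)
  if (length(locus) != 1L)
    stop_gc("gc_multi_record",
            "vector GenBank file must contain exactly one LOCUS record, found %d",
            length(locus))
  circular <- grepl("\\bcircular\\b", lines[locus], ignore.case = TRUE)
  ori <- grep("^ORIGIN", lines)
  if (length(ori) != 1L)
    stop_gc("gc_bad_format", "GenBank file has no ORIGIN block: %s", path)
  end <- grep("^//", lines)
  end <- end[end > ori][1]
  if (is.na(end)) end <- length(lines) + 1L
  body <- lines[seq(ori + 1L, end - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  list(sequence = seq, circular = circular)
}
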