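#' Write a count table to CSV
#'
#' Single-guide tables are written with header
#' `guide_id,sequence,gene,count`, one row per library entry in library
#' order, zero counts included.  Combinatorial tables are written with header
#' `guide_id_1,guide_id_2,count`, rows sorted by descending count and then
#' lexicographically by the id pair.  Fields are quoted per RFC 4180 when
#' needed and files end in UNIX newlines.
#'
#' @param table a `count_table` or `combo_count_table`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_count_csv <- function(table, path) {
  UseMethod("write_count_csv")
}

#' @export
write_count_csv.count_table <- function(table, path) {
  e <- table$library$entries
  gene <- ifelse(is.na(e$gene), "", e$gene)
  rows <- paste(csv_field(e$guide_id), csv_field(e$sequence),
                csv_field(gene), table$counts[e$guide_id], sep = ",")
  write_csv_lines("guide_id,sequence,gene,count", rows, path)
}

#' @export
write_count_csv.combo_count_table <- function(table, path) {
  cc <- table$combos
  if (nrow(cc)) {
    ord <- order(-cc$count, cc$guide_id_1, cc$guide_id_2, method = "radix")
    cc <- cc[ord, , drop = FALSE]
    rows <- paste(csv_field(cc$guide_id_1), csv_field(cc$guide_id_2),
                  cc$count, sep = ",")
  } else rows <- character()
  write_csv_lines("guide_id_1,guide_id_2,count", rows, path)
}

#' Write the unaligned-sequence report
#'
#' Sequences that could not be assigned to any library guide, written as
#' `sequence,count` sorted by descending count (ties broken
#' lexicographically), truncated to the `top_n` most abundant.
#'
#' @param unaligned a named integer vector (unique-sequence table) of
#'   unaligned sequences.
#' @param path output file path.
#' @param top_n maximum number of rows (default 1000).
#' @return the path, invisibly.
#' @export
write_unaligned_report <- function(unaligned, path, top_n = 1000L) {
  stopifnot(top_n >= 1)
  if (length(unaligned)) {
    ord <- order(-unname(unaligned), names(unaligned), method = "radix")
    u <- unaligned[ord]
    u <- utils::head(u, top_n)
    rows <- paste(csv_field(names(u)), unname(u), sep = ",")
  } else rows <- character()
  write_csv_lines("sequence,count", rows, path)
}
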