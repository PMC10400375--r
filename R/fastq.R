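#' Open a FASTQ (or gzipped FASTQ) file for chunked reading
#'
#' Compression is detected from the gzip magic bytes, never from the file
#' extension.  Use [fastq_next()] to pull successive chunks and
#' [fastq_close()] when done; [read_fastq()] is the load-everything
#' convenience wrapper.
#'
#' @param path path to a FASTQ or gzip-compressed FASTQ file.
#' @return an opaque handle.
#' @export
fastq_open <- function(path) {
  if (!file.exists(path) || dir.exists(path))
    stop_gc("gc_missing_file", "FASTQ file not found: %s", path)
  magic <- readBin(path, "raw", n = 2L)
  gz <- length(magic) == 2 && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
  con <- if (gz) gzfile(path, open = "rt") else file(path, open = "rt")
  structure(new.env(parent = emptyenv()), class = "fastq_handle") -> h
  h$con <- con
  h$path <- path
  h$n_read <- 0L
  h
}

#' Read the next chunk of FASTQ records
#'
#' @param handle a handle from [fastq_open()].
#' @param n maximum number of records to read.
#' @return data.frame with columns `read_id`, `sequence`, `quality`
#'   (records in file order), or `NULL` at end of file.
#' @export
fastq_next <- function(handle, n = 100000L) {
  lines <- readLines(handle$con, n = 4L * n, warn = FALSE)
  if (length(lines) == 0L) return(NULL)
  if (length(lines) %% 4L != 0L)
    stop_gc("gc_truncated_fastq",
            "truncated FASTQ record in %s (line count not a multiple of 4)",
            handle$path)
  ids <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  plus <- lines[seq(3L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]
  if (any(!startsWith(ids, "@")) || any(!startsWith(plus, "+")))
    stop_gc("gc_truncated_fastq",
            "malformed FASTQ record in %s (missing @/+ markers)", handle$path)
  if (any(nchar(seqs) != nchar(qual)))
    stop_gc("gc_fastq_length_mismatch",
            "quality/sequence length mismatch in %s", handle$path)
  if (any(nchar(seqs) == 0L))
    stop_gc("gc_truncated_fastq", "empty sequence line in %s", handle$path)
  handle$n_read <- handle$n_read + length(ids)
  data.frame(read_id = sub("^@", "", ids), sequence = seqs, quality = qual,
             stringsAsFactors = FALSE)
}

#' @rdname fastq_open
#' @param handle a handle from [fastq_open()].
#' @export
fastq_close <- function(handle) {
  close(handle$con)
  invisible(NULL)
}

#' Read a whole FASTQ file into memory
#'
#' @inheritParams fastq_open
#' @param n maximum number of records to read (default all).
#' @return data.frame with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path, n = Inf) {
  h <- fastq_open(path)
  on.exit(fastq_close(h))
  out <- list()
  left <- n
  repeat {
    chunk <- fastq_next(h, n = as.integer(min(left, 100000L)))
    if (is.null(chunk)) break
    out[[length(out) + 1L]] <- chunk
    left <- left - nrow(chunk)
    if (left <= 0) break
  }
  if (length(out) == 0L)
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

write_fastq <- function(ids, seqs, quals, path) {
  gz <- grepl("\\.gz$", path)
  con <- if (gz) gzfile(path, open = "wb") else file(path, open = "wb")
  on.exit(close(con))
  block <- rbind(paste0("@", ids), seqs, "+", quals)
  writeLines(as.vector(block), con, sep = "\n")
  invisible(path)
}
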