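# Fixture builders shared across test files.  All randomness is seeded at
# the call site so fixtures are reproducible.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(len) paste(sample(BASES, len, replace = TRUE), collapse = "")

# A library of n distinct random guides of the given length(s).
make_library <- function(n, len = 20, seed = NULL, prefix = "g") {
  if (!is.null(seed)) set.seed(seed)
  seqs <- character(0)
  while (length(seqs) < n) {
    k <- n - length(seqs)
    lens <- if (length(len) == 1) rep(len, k) else sample(len, k, replace = TRUE)
    seqs <- unique(c(seqs, vapply(lens, rand_seq, "")))
  }
  seqs <- seqs[seq_len(n)]
  guidecounter:::new_guide_library(sprintf("%s%03d", prefix, seq_len(n)), seqs)
}

write_lib_csv <- function(lib, path, id_col = "id", seq_col = "seq") {
  writeLines(c(paste(id_col, seq_col, sep = ","),
               paste(lib$entries$guide_id, lib$entries$sequence, sep = ",")),
             path)
  path
}

# Plain FASTQ writer independent of the package's own writer.
write_fastq_plain <- function(seqs, path, gz = FALSE) {
  con <- if (gz) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(seqs))
    writeLines(as.vector(rbind(paste0("@r", seq_along(seqs)), seqs, "+",
                               strrep("I", nchar(seqs)))), con, sep = "\n")
  invisible(path)
}

# A hand-built cassette context (skips detection).
make_context <- function(anchor5, anchor3, stagger_min, stagger_max,
                         guide_lengths, orientation = "forward") {
  structure(list(orientation = orientation, anchor5 = anchor5,
                 anchor3 = anchor3, stagger_min = stagger_min,
                 stagger_max = stagger_max, guide_lengths = guide_lengths),
            class = "cassette_context")
}

# Cassette-shaped reads built outside the simulator, for targeted cases.
build_read <- function(guide, adapter = "CACCGA", scaffold = "GTTTTAG",
                       stagger = 0, read_len = NA) {
  r <- paste0(rand_seq(stagger), adapter, guide, scaffold)
  if (!is.na(read_len)) {
    if (nchar(r) < read_len) r <- paste0(r, rand_seq(read_len - nchar(r)))
    r <- substr(r, 1, read_len)
  }
  r
}

# In-memory twin of trim_fastq, for tests that already hold the reads.
trim_fastq_from_reads <- function(reads, ctx) {
  tr <- trim_reads(reads, ctx)
  cands <- tr$candidate[tr$trimmed]
  list(unique = guidecounter:::new_unique_table(
         guidecounter:::merge_counts(integer(), table(cands))),
       stats = list(total = length(reads), trimmed = length(cands),
                    untrimmed = length(reads) - length(cands)))
}
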