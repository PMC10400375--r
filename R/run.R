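#' Describe one sequencing sample
#'
#' @param name unique sample name (file stem for all outputs).
#' @param r1 path to the R1 FASTQ(.gz).
#' @param r2 optional path to the R2 FASTQ(.gz); its presence makes the
#'   sample paired-end.
#' @param vector optional vector map path (GenBank or FASTA) for template
#'   placeholder discovery.
#' @param expected_depth optional expected sequencing depth (reads per
#'   guide) echoed into the QC report.
#' @return a `sample_spec` list.
#' @export
sample_spec <- function(name, r1, r2 = NULL, vector = NULL,
                        expected_depth = NULL) {
  stopifnot(is.character(name), nzchar(name))
  if (!is.null(expected_depth)) stopifnot(expected_depth > 0)
  structure(list(name = name, r1 = r1, r2 = r2, vector = vector,
                 expected_depth = expected_depth),
            class = "sample_spec")
}

#' Parse a sample sheet
#'
#' CSV with header `name,r1,r2,library,vector,expected_depth`; `r2`,
#' `vector` and `expected_depth` may be empty per row (and their columns may
#' be omitted entirely).  A `library` column, when present, may override the
#' run-level library per sample.
#'
#' @param path sample sheet path.
#' @return list of [sample_spec()] objects (with an extra `library` field
#'   when the sheet carries one).
#' @export
parse_sample_sheet <- function(path) {
  if (!file.exists(path))
    stop_gc("gc_missing_file", "sample sheet not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  nm <- tolower(names(df))
  need <- c("name", "r1")
  if (!all(need %in% nm))
    stop_gc("gc_missing_columns", "sample sheet must have columns %s; found: %s",
            paste(need, collapse = ","), paste(names(df), collapse = ","))
  names(df) <- nm
  blank2null <- function(x) if (is.null(x) || is.na(x) || !nzchar(x)) NULL else x
  if (anyDuplicated(df$name))
    stop_gc("gc_duplicate_sample",
            "duplicate sample names in sheet: %s",
            paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    ed <- blank2null(df$expected_depth[i])
    s <- sample_spec(df$name[i], df$r1[i],
                     r2 = blank2null(df$r2[i]),
                     vector = blank2null(df$vector[i]),
                     expected_depth = if (is.null(ed)) NULL else as.numeric(ed))
    s$library <- blank2null(df$library[i])
    s
  })
}

#' Run the full counting pipeline over one or more samples
#'
#' For each sample: subsample the first `subsample_n` reads, detect
#' orientation and cassette context (independently per mate for paired-end
#' samples), optionally discover the template placeholder from a vector map,
#' trim the whole file, count (single-end or combinatorial), and write
#' `<name>.counts.csv`, `<name>.unaligned.csv`, `<name>.qc.json`,
#' `<name>.report.png`/`.pdf` and `<name>.run.txt` into `out_dir`.  Samples
#' are independent: a failing sample is reported in the summary and does not
#' abort the batch, and results are identical whatever the processing order
#' or thread count.
#'
#' @param samples a list of [sample_spec()] objects, a single `sample_spec`,
#'   or a sample-sheet path.
#' @param library a [guide_library][read_library] or a library file path.
#' @param out_dir output directory.
#' @param max_mm maximum Hamming mismatches for guide matching (0--2).
#' @param max_anchor_mm maximum anchor mismatches for trimming.
#' @param stagger_cap maximum believable stagger length (nt, default 8).
#' @param subsample_n detection subsample size (first n reads).
#' @param threads number of worker processes for sample-level parallelism.
#' @param collapse_orientation merge `(a,b)`/`(b,a)` guide pairs, see
#'   [count_paired_end()].
#' @param check_ids cross-check mate read ids, see [tally_unique_pairs()].
#' @param top_n_unaligned rows kept in the unaligned-sequence report.
#' @return named list of per-sample summaries: each either a list with
#'   `status = "ok"`, the `count_table` (and `combo_count_table` for
#'   paired samples), `metrics` and the output paths, or `status =
#'   "failed"` with the error `message`.  Attribute `n_failed` gives the
#'   failure count.
#' @export
run_samples <- function(samples, library, out_dir = ".", max_mm = 1L,
                        max_anchor_mm = 2L, stagger_cap = 8L,
                        subsample_n = 10000L, threads = 1L,
                        collapse_orientation = FALSE, check_ids = FALSE,
                        top_n_unaligned = 1000L) {
  if (is.character(samples)) samples <- parse_sample_sheet(samples)
  if (inherits(samples, "sample_spec")) samples <- list(samples)
  stopifnot(length(samples) >= 1, threads >= 1, stagger_cap >= 0)
  names(samples) <- vapply(samples, `[[`, "", "name")
  if (anyDuplicated(names(samples)))
    stop_gc("gc_duplicate_sample", "duplicate sample names: %s",
            paste(unique(names(samples)[duplicated(names(samples))]),
                  collapse = ", "))
  if (is.character(library)) library <- read_library(library)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  params <- list(max_mm = max_mm, max_anchor_mm = max_anchor_mm,
                 stagger_cap = stagger_cap, subsample_n = subsample_n,
                 threads = threads, collapse_orientation = collapse_orientation,
                 check_ids = check_ids, top_n_unaligned = top_n_unaligned)
  worker <- function(s) {
    tryCatch({
      lib <- if (!is.null(s$library)) read_library(s$library) else library
      res <- run_one_sample(s, lib, out_dir, params)
      c(list(status = "ok"), res)
    }, error = function(e) list(status = "failed", message = conditionMessage(e)))
  }
  results <- if (threads > 1L) {
    parallel::mclapply(samples, worker, mc.cores = threads)
  } else {
    lapply(samples, worker)
  }
  failed <- vapply(results, function(r) identical(r$status, "failed"), TRUE)
  for (nm in names(results)[failed])
    message(sprintf("sample '%s' failed: %s", nm, results[[nm]]$message))
  structure(results, n_failed = sum(failed))
}

run_one_sample <- function(s, library, out_dir, p) {
  stem <- function(ext) file.path(out_dir, paste0(s$name, ext))
  sub1 <- read_fastq(s$r1, n = p$subsample_n)
  orient1 <- detect_orientation(sub1$sequence, library)
  ctx1 <- detect_context(sub1$sequence, library, orient1,
                         stagger_cap = p$stagger_cap)
  placeholder <- NULL
  if (!is.null(s$vector)) {
    v <- read_vector(s$vector)
    placeholder <- find_placeholder(v, ctx1, library, reads = sub1$sequence)
  }
  index <- build_match_index(library, placeholder, max_mm = p$max_mm)
  paired <- !is.null(s$r2)
  if (!paired) {
    tr <- trim_fastq(s$r1, ctx1, p$max_anchor_mm)
    ct <- count_single_end(tr$unique, index, tr$stats, library)
    metrics <- compute_metrics(ct, library, s$expected_depth)
    write_count_csv(ct, stem(".counts.csv"))
    write_unaligned_report(ct$unaligned, stem(".unaligned.csv"),
                           p$top_n_unaligned)
    render_report(metrics, ct, out_dir, s$name)
    write_run_log(c(list(sample = s$name, r1 = s$r1, mode = "single-end"), p),
                  ctx1, placeholder, stem(".run.txt"))
    list(counts = ct, metrics = metrics,
         files = c(counts = stem(".counts.csv"),
                   unaligned = stem(".unaligned.csv"),
                   qc = stem(".qc.json"), log = stem(".run.txt")))
  } else {
    sub2 <- read_fastq(s$r2, n = p$subsample_n)
    orient2 <- detect_orientation(sub2$sequence, library)
    ctx2 <- detect_context(sub2$sequence, library, orient2,
                           stagger_cap = p$stagger_cap)
    tly <- tally_unique_pairs(s$r1, s$r2, ctx1, ctx2, p$max_anchor_mm,
                              check_ids = p$check_ids)
    ct1 <- count_single_end(tly$unique1, index, tly$stats1, library)
    ct2 <- count_single_end(tly$unique2, index, tly$stats2, library)
    combo <- count_paired_end(tly, ct1, ct2,
                              collapse_orientation = p$collapse_orientation)
    metrics1 <- compute_metrics(ct1, library, s$expected_depth)
    metrics2 <- compute_metrics(ct2, library, s$expected_depth)
    write_count_csv(combo, stem(".counts.csv"))
    write_count_csv(ct1, stem(".R1.counts.csv"))
    write_count_csv(ct2, stem(".R2.counts.csv"))
    both_unaligned <- merge_counts(unclass(ct1$unaligned), ct2$unaligned)
    write_unaligned_report(both_unaligned, stem(".unaligned.csv"),
                           p$top_n_unaligned)
    render_report(metrics1, ct1, out_dir, paste0(s$name, ".R1"))
    render_report(metrics2, ct2, out_dir, paste0(s$name, ".R2"))
    qc <- list(R1 = unclass(metrics1), R2 = unclass(metrics2),
               pairs = combo$totals)
    jsonlite::write_json(qc, stem(".qc.json"), auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    write_run_log(c(list(sample = s$name, r1 = s$r1, r2 = s$r2,
                         mode = "paired-end"), p),
                  list(R1 = ctx1, R2 = ctx2), placeholder, stem(".run.txt"))
    list(counts = ct1, counts_r2 = ct2, combos = combo,
         metrics = metrics1, metrics_r2 = metrics2,
         files = c(counts = stem(".counts.csv"),
                   unaligned = stem(".unaligned.csv"),
                   qc = stem(".qc.json"), log = stem(".run.txt")))
  }
}
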