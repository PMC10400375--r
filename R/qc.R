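#' Compute QC metrics for a counted sample
#'
#' Summarises trimming and alignment rates, expected versus observed
#' sequencing depth (reads per guide), library completeness (fraction of
#' guides seen at least once), the P90/P10 skew ratio of the count
#' distribution, and template-placeholder abundance.  Degenerate
#' denominators never divide by zero: rates over empty input are 0 and the
#' skew of an undefined distribution is `NA`.
#'
#' @param table a [count_table][count_single_end].
#' @param library the [guide_library][read_library] (defaults to the one
#'   embedded in the table).
#' @param expected_depth optional expected sequencing depth (reads per
#'   guide).
#' @return An object of class `qc_metrics`: list with fields `trim_rate`,
#'   `align_rate_of_trimmed`, `align_rate_of_total`, `expected_depth`,
#'   `observed_depth`, `completeness`, `skew_ratio`, `zero_guides`,
#'   `placeholder_fraction`, `duplicate_groups_flagged`.
#' @export
compute_metrics <- function(table, library = table$library,
                            expected_depth = NULL) {
  t <- table$totals
  nlib <- nrow(library$entries)
  div <- function(a, b) if (b > 0) a / b else 0
  zero_guides <- sum(table$counts == 0L)
  structure(list(
    trim_rate = div(t$trimmed, t$total_reads),
    align_rate_of_trimmed = div(t$assigned, t$trimmed),
    align_rate_of_total = div(t$assigned, t$total_reads),
    expected_depth = if (is.null(expected_depth)) NA_real_
                     else as.numeric(expected_depth),
    observed_depth = div(t$assigned, nlib),
    completeness = 1 - div(zero_guides, nlib) * (nlib > 0),
    skew_ratio = skew_ratio(table$counts),
    zero_guides = zero_guides,
    placeholder_fraction = div(table$placeholder_count, t$trimmed),
    duplicate_groups_flagged = length(library$duplicate_groups)
  ), class = "qc_metrics")
}

#' P90/P10 skew ratio of a count distribution
#'
#' Sorts the per-guide counts (zeros for unobserved guides included) and
#' returns the ratio of the nearest-rank 90th to the 10th percentile:
#' element `ceil(0.9 N)` over element `ceil(0.1 N)` of the sorted vector
#' (1-based).  The ratio is the established screen-QC evenness measure; a
#' perfectly uniform sample gives 1.  Undefined (`NA`) when the vector is
#' empty or P10 is zero (at least 10% of guides unobserved).
#'
#' @param counts numeric vector of per-guide counts including zeros.
#' @return the ratio (>= 1 for sorted quantiles), or `NA_real_` when
#'   undefined.
#' @export
#' @examples
#' skew_ratio(1:100)  # P10 = 10, P90 = 90 -> 9
skew_ratio <- function(counts) {
  n <- length(counts)
  if (n == 0L) return(NA_real_)
  s <- sort(counts)
  p10 <- s[ceiling(0.10 * n)]
  p90 <- s[ceiling(0.90 * n)]
  if (p10 == 0) return(NA_real_)
  unname(p90 / p10)
}

#' @export
print.qc_metrics <- function(x, ...) {
  cat("qc_metrics:\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-26s %s\n", k,
                if (is.na(v)) "undefined" else format(v, digits = 4)))
  }
  invisible(x)
}

#' Render the QC report for a sample
#'
#' Writes the four-panel QC figure in both PNG and PDF: (1) trimming and
#' alignment rates; (2) expected vs observed depth; (3) per-guide read-count
#' histogram on log-scaled counts, with the placeholder abundance marked
#' when present; (4) sorted cumulative count curve annotated with
#' completeness.  Also writes `<name>.qc.json` with every metric field
#' (undefined values serialised as `null`).
#'
#' @param metrics a [qc_metrics][compute_metrics].
#' @param table the [count_table][count_single_end] behind the metrics.
#' @param out_dir output directory (created if missing).
#' @param name sample name used as the file stem.
#' @return named character vector of the files written, invisibly.
#' @export
render_report <- function(metrics, table, out_dir, name) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  png_path <- file.path(out_dir, paste0(name, ".report.png"))
  pdf_path <- file.path(out_dir, paste0(name, ".report.pdf"))
  json_path <- file.path(out_dir, paste0(name, ".qc.json"))

  draw <- function() {
    op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 3, 1))
    on.exit(graphics::par(op))
    rates <- c(trimmed = metrics$trim_rate,
               `aligned/trimmed` = metrics$align_rate_of_trimmed,
               `aligned/total` = metrics$align_rate_of_total)
    graphics::barplot(rates, ylim = c(0, 1), col = "steelblue",
                      main = name, ylab = "rate", las = 1, cex.names = 0.8)
    depth <- c(expected = metrics$expected_depth,
               observed = metrics$observed_depth)
    graphics::barplot(ifelse(is.na(depth), 0, depth), col = "darkseagreen",
                      names.arg = names(depth), las = 1,
                      main = "sequencing depth", ylab = "reads / guide")
    if (is.na(depth["expected"]))
      graphics::mtext("expected depth not provided", side = 3, cex = 0.6)
    lc <- log10(table$counts + 1)
    if (length(lc) && any(lc > 0)) {
      graphics::hist(lc, breaks = 30, col = "grey70", main = "count distribution",
                     xlab = "log10(count + 1)", las = 1)
      if (table$placeholder_count > 0)
        graphics::abline(v = log10(table$placeholder_count + 1), col = "red", lwd = 2)
    } else {
      graphics::plot.new()
      graphics::title(main = "count distribution (no counts)")
    }
    s <- sort(table$counts)
    cum <- if (sum(s) > 0) cumsum(as.numeric(s)) / sum(s) else rep(0, length(s))
    graphics::plot(seq_along(s), cum, type = "l", lwd = 2, col = "steelblue",
                   xlab = "guides (sorted by count)", ylab = "cumulative count fraction",
                   main = "cumulative counts", las = 1, ylim = c(0, 1))
    graphics::legend("topleft", bty = "n", cex = 0.9, legend = sprintf(
      "completeness %.1f%%  zero guides %d",
      100 * metrics$completeness, metrics$zero_guides))
  }
  grDevices::png(png_path, width = 1400, height = 1000, res = 150)
  draw()
  grDevices::dev.off()
  grDevices::pdf(pdf_path, width = 9, height = 7)
  draw()
  grDevices::dev.off()

  m <- unclass(metrics)
  jsonlite::write_json(m, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(png = png_path, pdf = pdf_path, json = json_path))
}

#' Read back a QC metrics JSON file
#'
#' @param path path to a `.qc.json` written by [render_report()].
#' @return a `qc_metrics` object (`null` fields become `NA`).
#' @export
read_qc_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- lapply(m, function(v) if (is.null(v)) NA_real_ else v)
  structure(m, class = "qc_metrics")
}

#' Write the run-parameter log
#'
#' Plain-text `key: value` lines covering every resolved pipeline parameter,
#' the detected cassette context, the placeholder sequence when found, and
#' package version / timing information.
#'
#' @param params named list of resolved parameters (defaults included).
#' @param context optional [cassette_context][detect_context] (or a list of
#'   them for paired samples, named by mate).
#' @param placeholder optional [placeholder_info][find_placeholder].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_run_log <- function(params, context = NULL, placeholder = NULL, path) {
  lines <- c(sprintf("guidecounter_version: %s",
                     as.character(utils::packageVersion("guidecounter"))),
             sprintf("finished: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")))
  for (k in names(params)) {
    v <- params[[k]]
    lines <- c(lines, sprintf("%s: %s", k,
                              if (is.null(v) || length(v) == 0) "NA"
                              else paste(v, collapse = ",")))
  }
  fmt_ctx <- function(ctx, prefix = "") {
    c(sprintf("%sorientation: %s", prefix, ctx$orientation),
      sprintf("%sanchor5: %s", prefix, ctx$anchor5),
      sprintf("%sanchor3: %s", prefix, ctx$anchor3),
      sprintf("%sstagger_window: [%d, %d]", prefix, ctx$stagger_min,
              ctx$stagger_max))
  }
  if (inherits(context, "cassette_context")) {
    lines <- c(lines, fmt_ctx(context))
  } else if (is.list(context)) {
    for (nm in names(context))
      lines <- c(lines, fmt_ctx(context[[nm]], paste0(nm, "_")))
  }
  if (!is.null(placeholder))
    lines <- c(lines,
               sprintf("placeholder_sequence: %s", placeholder$sequence),
               sprintf("placeholder_source: %s", placeholder$source))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
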