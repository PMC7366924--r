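#' Percent of reads assigned to the alternate reference
#'
#' For each sample, the percentage of unambiguously mapped reads assigned to
#' the alternate (Bactrian camel) reference out of all unambiguously mapped
#' reads: `100 * alt / (primary + alt)`.
#'
#' @param counts Data frame with columns `sample_id`, `reads_ref_primary`,
#'   `reads_ref_alt`.
#' @return The input as a tibble with an added `percent_alt` column.
#' @examples
#' percent_alt_reference(tibble::tibble(
#'   sample_id = "a", reads_ref_primary = 980, reads_ref_alt = 20))
#' @export
percent_alt_reference <- function(counts) {
  counts <- tibble::as_tibble(counts)
  req <- c("sample_id", "reads_ref_primary", "reads_ref_alt")
  if (!all(req %in% names(counts))) {
    rlang::abort(paste0("`counts` needs columns: ", paste(req, collapse = ", ")))
  }
  if (any(counts$reads_ref_primary < 0 | counts$reads_ref_alt < 0)) {
    rlang::abort("read counts must be non-negative")
  }
  total <- counts$reads_ref_primary + counts$reads_ref_alt
  if (any(total == 0)) {
    rlang::abort(paste0(
      "zero total mapped reads for sample(s): ",
      paste(counts$sample_id[total == 0], collapse = ", ")))
  }
  dplyr::mutate(counts, percent_alt = 100 * .data$reads_ref_alt /
                  (.data$reads_ref_primary + .data$reads_ref_alt))
}

#' Tukey far-out threshold
#'
#' The far-out outlier rule: third quartile plus three times the
#' interquartile range, with quartiles by linear interpolation on order
#' statistics (the common default of scientific stacks, R quantile type 7).
#'
#' @param values Numeric vector of at least 4 values.
#' @return Single numeric threshold.
#' @examples
#' far_out_threshold(c(1, 2, 3, 4, 100))  # Q1 = 2, Q3 = 4 -> 10
#' @export
far_out_threshold <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4) {
    rlang::abort("at least 4 values are required for the far-out rule")
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] + 3 * (q[2] - q[1])
}

#' Screen for interspecific hybrids
#'
#' Flags samples whose alternate-reference read percentage is a far-out
#' value: strictly greater than Q3 + 3 x IQR of all samples' percentages.
#' The screen is run on the raw read-assignment table, before any genotype
#' QC.
#'
#' @param counts Data frame as for [percent_alt_reference()].
#' @return An object of class `hybrid_screen`: a list with `report` (tibble
#'   with `sample_id`, `percent_alt`, `flagged`), `flagged` (character ids),
#'   `threshold`, `q1`, `q3`. `tidy()` returns the per-sample report,
#'   `glance()` the threshold summary.
#' @examples
#' tab <- simulate_read_assignments(hybrid_sim_spec(
#'   n_ind = 30, mean_reads = 1e4, baseline_frac = 0.01,
#'   hybrid_ids = "ind007", hybrid_frac = 0.2, seed = 3))
#' flag_hybrids(tab)$flagged
#' @export
flag_hybrids <- function(counts) {
  pct <- percent_alt_reference(counts)
  q <- stats::quantile(pct$percent_alt, c(0.25, 0.75), names = FALSE, type = 7)
  thr <- far_out_threshold(pct$percent_alt)
  report <- dplyr::mutate(
    pct[, c("sample_id", "reads_ref_primary", "reads_ref_alt", "percent_alt")],
    flagged = .data$percent_alt > thr
  )
  structure(
    list(report = report,
         flagged = report$sample_id[report$flagged],
         threshold = thr, q1 = q[1], q3 = q[2]),
    class = "hybrid_screen"
  )
}

#' @export
print.hybrid_screen <- function(x, ...) {
  cat(sprintf(
    "<hybrid_screen> %d samples, threshold %.4g%% (Q1 %.4g, Q3 %.4g): %d flagged\n",
    nrow(x$report), x$threshold, x$q1, x$q3, length(x$flagged)))
  if (length(x$flagged)) cat("  flagged:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.hybrid_screen <- function(x, ...) x$report

#' @importFrom generics glance
#' @export
glance.hybrid_screen <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$report), n_flagged = length(x$flagged),
                 threshold = x$threshold, q1 = x$q1, q3 = x$q3)
}

#' @export
autoplot.hybrid_screen <- function(object, ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$sample_id, y = .data$percent_alt,
                               fill = .data$flagged)) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "% reads on alternate reference",
                  fill = "far-out") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6))
}
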