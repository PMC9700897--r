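#' Plot a phosphate calibration curve
#'
#' Calibration points with the fitted least-squares line.
#'
#' @param object A `calibration_curve` from [fit_calibration()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.calibration_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$pi_nmol, y = .data$absorbance)) +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$slope,
      colour = "steelblue"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Inorganic phosphate (nmol)", y = "Absorbance (750 nm)",
      title = sprintf("Calibration fit (R² = %.4f)", object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot pathway enrichment results
#'
#' Top pathways by adjusted significance.
#'
#' @param object An `enrichment_result` from [pathway_enrichment()].
#' @param n Number of pathways to show (default 20).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, n = 20, ...) {
  top <- utils::head(object, n)
  top$pathway <- factor(top$pathway, levels = rev(top$pathway))
  ggplot2::ggplot(top, ggplot2::aes(
    x = -log10(.data$q_value), y = .data$pathway
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = expression(-log[10] ~ "q-value"), y = NULL,
      title = "Pathway over-representation (hypergeometric, BH-adjusted)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-sample specific activities
#'
#' @param object An `activity_result` from [specific_activity()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.activity_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$sample_id, -.data$specific_activity),
    y = .data$specific_activity
  )) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(
      x = NULL, y = "Specific activity (pmol Pi / mg Hb / min)",
      title = "Pyrimidine 5'-nucleotidase specific activity"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the prioritization cascade
#'
#' Survivor counts per pipeline stage of a [run_prioritization()] report.
#'
#' @param object A `candidate_report`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.candidate_report <- function(object, ...) {
  counts <- stage_counts(object)
  counts$stage <- factor(counts$stage, levels = counts$stage)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = NULL, y = "Variants surviving (log scale)",
      title = "Variant-prioritization cascade"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
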