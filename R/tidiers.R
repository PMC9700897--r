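#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a calibration curve fit
#'
#' @param x A `calibration_curve` from [fit_calibration()].
#' @param ... Passed on.
#' @return Tibble with one row per coefficient (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`).
#' @export
tidy.calibration_curve <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit)$coefficients)
  tibble(
    term = c("intercept", "slope_per_nmol"),
    estimate = unname(s[, 1]),
    std.error = unname(s[, 2]),
    statistic = unname(s[, 3]),
    p.value = unname(s[, 4])
  )
}

#' One-row summary of a calibration curve fit
#'
#' @param x A `calibration_curve`.
#' @param ... Ignored.
#' @return Tibble with `slope`, `intercept`, `r_squared`, `n_points`.
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept,
    r_squared = x$r_squared, n_points = nrow(x$points)
  )
}
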