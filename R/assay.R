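#' Default assay volume bookkeeping
#'
#' The nucleotidase reaction mixes hemolysate and substrate solution; an
#' aliquot is quenched in iron-TCA stop solution and a fixed volume of the
#' extract is loaded on the phosphate-detection plate. These volumes define
#' the conversion from nanomoles detected in a well back to nanomoles
#' released in the full reaction.
#'
#' @param hemolysate_uL Hemolysate volume in the reaction (default 150).
#' @param substrate_uL Substrate solution volume (default 150).
#' @param aliquot_uL Reaction aliquot quenched in stop solution (default 120).
#' @param stop_uL Stop-solution volume (default 1200).
#' @param plate_load_uL Extract volume loaded per detection well (default 120).
#' @return Named list of volumes (microlitres).
#' @export
assay_volumes <- function(hemolysate_uL = 150, substrate_uL = 150,
                          aliquot_uL = 120, stop_uL = 1200,
                          plate_load_uL = 120) {
  list(
    hemolysate_uL = hemolysate_uL, substrate_uL = substrate_uL,
    aliquot_uL = aliquot_uL, stop_uL = stop_uL, plate_load_uL = plate_load_uL
  )
}

# nmol in a detection well -> nmol in the full reaction mixture.
well_to_reaction_factor <- function(volumes) {
  extract_uL <- volumes$aliquot_uL + volumes$stop_uL
  reaction_uL <- volumes$hemolysate_uL + volumes$substrate_uL
  (extract_uL / volumes$plate_load_uL) * (reaction_uL / volumes$aliquot_uL)
}

#' Fit a phosphate calibration curve
#'
#' Ordinary least-squares line through known inorganic-phosphate amounts
#' (nmol) versus blank-subtracted absorbance at 750 nm.
#'
#' @param points Data frame with columns `pi_nmol` and `absorbance` (at
#'   least two distinct `pi_nmol` values).
#' @return A `calibration_curve` object with `slope` (absorbance per
#'   nmol), `intercept`, `r_squared`, the input `points`, and the
#'   underlying `lm` fit. A non-positive slope is fatal.
#' @examples
#' fit_calibration(data.frame(pi_nmol = c(0, 10), absorbance = c(0, 0.5)))
#' @export
fit_calibration <- function(points) {
  points <- as_tibble(points)
  if (nrow(points) < 2 || length(unique(points$pi_nmol)) < 2) {
    abort("calibration needs at least 2 points with distinct pi_nmol")
  }
  fit <- stats::lm(absorbance ~ pi_nmol, data = points)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    abort(sprintf("calibration slope must be positive (got %.4g)", slope))
  }
  structure(
    list(
      slope = slope,
      intercept = unname(stats::coef(fit)[1]),
      r_squared = suppressWarnings(summary(fit)$r.squared),
      points = points,
      fit = fit
    ),
    class = "calibration_curve"
  )
}

#' @export
#' @method print calibration_curve
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve: absorbance = %.5g + %.5g * nmol Pi, R^2 = %.4f, %d points>\n",
    x$intercept, x$slope, x$r_squared, nrow(x$points)
  ))
  invisible(x)
}

#' Inorganic phosphate from a well absorbance
#'
#' Inverts the calibration fit after blank subtraction; negative amounts
#' floor at zero.
#'
#' @param a750 Absorbance(s) at 750 nm.
#' @param blank Blank absorbance (reagents with water in place of extract).
#' @param curve A [fit_calibration()] curve.
#' @return Phosphate amount(s) in nmol.
#' @export
pi_from_absorbance <- function(a750, blank, curve) {
  pmax(((a750 - blank) - curve$intercept) / curve$slope, 0)
}

#' Hemoglobin concentration by Beer-Lambert at 512 nm
#'
#' Converts absorbance to molar concentration with the hemoglobin molar
#' extinction coefficient at 512 nm (26,936.8 per cm per M), then to mass
#' concentration. The default molar mass is the tetramer (64,458 g/mol);
#' it is a visible parameter because the mass basis of the coefficient is
#' a unit-chain choice that should be auditable.
#'
#' @param a512 Absorbance(s) at 512 nm (non-negative).
#' @param path_cm Optical path length in cm (default 1; must be positive).
#' @param epsilon Molar extinction coefficient, per cm per M.
#' @param molar_mass_g_per_mol Hemoglobin molar mass (default 64458).
#' @return Concentration(s) in mg/mL.
#' @export
hb_mg_per_ml <- function(a512, path_cm = 1, epsilon = 26936.8,
                         molar_mass_g_per_mol = 64458) {
  if (path_cm <= 0) abort("path_cm must be positive")
  if (any(a512 < 0)) abort("absorbance must be non-negative")
  mol_per_L <- a512 / (epsilon * path_cm)
  mol_per_L * molar_mass_g_per_mol  # g/L == mg/mL
}

#' Specific nucleotidase activity from a plate layout
#'
#' Computes, per sample, the phosphate released during incubation
#' (reaction minus paired zero-time control, both inverted through the
#' calibration curve and scaled by the volume bookkeeping), normalized by
#' the hemoglobin mass in the reaction and the incubation time:
#' pmol phosphate per mg hemoglobin per minute. Negative
#' baseline-subtracted activities clip to zero with a warning (measurement
#' noise near zero activity). When AMP-substrate control wells are
#' present, the nonspecific fraction (AMP activity / UMP activity) is
#' reported, with a warning above `nonspecific_warn`.
#'
#' @param plate Tibble with columns `well`, `sample_id`, `role` (one of
#'   `reaction`, `zero_time`, `blank`, `calibration`, `amp_control`,
#'   `amp_zero`), `absorbance_750`, `dilution_factor` (hemolysate
#'   dilution), and `pi_nmol` for calibration wells.
#' @param curve Optional [fit_calibration()] curve; if `NULL`, fitted from
#'   the plate's calibration wells (blank-subtracted).
#' @param hb Named numeric: hemoglobin concentration of each sample's
#'   *undiluted* hemolysate, mg/mL.
#' @param incubation_minutes Incubation time (default 120).
#' @param volumes Volume bookkeeping from [assay_volumes()].
#' @param nonspecific_warn Warning bound for the nonspecific fraction
#'   (default 0.15).
#' @return An `activity_result` tibble: `sample_id`, `pi_released_pmol`,
#'   `hb_mg`, `specific_activity`, `nonspecific_fraction`.
#' @export
specific_activity <- function(plate, curve = NULL, hb,
                              incubation_minutes = 120,
                              volumes = assay_volumes(),
                              nonspecific_warn = 0.15) {
  plate <- as_tibble(plate)
  blank_wells <- plate[plate$role == "blank", , drop = FALSE]
  blank <- if (nrow(blank_wells) > 0) mean(blank_wells$absorbance_750) else 0

  if (is.null(curve)) {
    cal <- plate[plate$role == "calibration", , drop = FALSE]
    if (nrow(cal) < 2) abort("no curve supplied and fewer than 2 calibration wells")
    curve <- fit_calibration(tibble(
      pi_nmol = cal$pi_nmol, absorbance = cal$absorbance_750 - blank
    ))
  }

  rxn <- plate[plate$role == "reaction", , drop = FALSE]
  zero <- plate[plate$role == "zero_time", , drop = FALSE]
  missing_zero <- setdiff(unique(rxn$sample_id), unique(zero$sample_id))
  if (length(missing_zero) > 0) {
    abort(sprintf(
      "no zero-time control for sample(s): %s",
      paste(missing_zero, collapse = ", ")
    ))
  }
  scale <- well_to_reaction_factor(volumes)

  released_nmol <- function(rxn_rows, zero_rows) {
    r <- mean(pi_from_absorbance(rxn_rows$absorbance_750, blank, curve))
    z <- mean(pi_from_absorbance(zero_rows$absorbance_750, blank, curve))
    (r - z) * scale
  }

  samples <- unique(rxn$sample_id)
  n_clipped <- 0L
  res <- purrr::map_dfr(samples, function(s) {
    rel <- released_nmol(
      rxn[rxn$sample_id == s, ], zero[zero$sample_id == s, ]
    )
    df <- rxn$dilution_factor[rxn$sample_id == s][1]
    if (is.na(df)) df <- 1
    if (is.na(match(s, names(hb)))) {
      abort(sprintf("no hemoglobin value for sample '%s'", s))
    }
    hb_mg <- hb[[s]] * (volumes$hemolysate_uL / 1000) / df
    act <- rel * 1000 / hb_mg / incubation_minutes  # nmol -> pmol
    if (act < 0) {
      n_clipped <<- n_clipped + 1L
      act <- 0
      rel <- 0
    }
    amp <- plate[plate$role == "amp_control" & plate$sample_id == s, , drop = FALSE]
    nonspec <- NA_real_
    if (nrow(amp) > 0) {
      amp_zero <- plate[plate$role == "amp_zero" & plate$sample_id == s, , drop = FALSE]
      if (nrow(amp_zero) == 0) amp_zero <- zero[zero$sample_id == s, , drop = FALSE]
      amp_rel <- released_nmol(amp, amp_zero)
      nonspec <- if (rel > 0) max(amp_rel, 0) / rel else NA_real_
    }
    tibble(
      sample_id = s, pi_released_pmol = rel * 1000, hb_mg = hb_mg,
      specific_activity = act, nonspecific_fraction = nonspec
    )
  })
  if (n_clipped > 0) {
    warn(sprintf(
      "%d sample(s) with negative baseline-subtracted activity clipped to 0",
      n_clipped
    ))
  }
  high <- !is.na(res$nonspecific_fraction) &
    res$nonspecific_fraction > nonspecific_warn
  if (any(high)) {
    warn(sprintf(
      "nonspecific (AMP) fraction above %.0f%% for: %s",
      100 * nonspecific_warn, paste(res$sample_id[high], collapse = ", ")
    ))
  }
  class(res) <- c("activity_result", class(res))
  res
}

#' Fold change of a patient activity relative to a control mean
#'
#' @param patient_activity Patient value(s).
#' @param control_mean_activity Positive control-group mean.
#' @return `patient_activity / control_mean_activity`.
#' @export
fold_change <- function(patient_activity, control_mean_activity) {
  if (control_mean_activity <= 0) abort("control mean activity must be positive")
  patient_activity / control_mean_activity
}

#' Purine/pyrimidine nucleotide ratio
#'
#' @param purine_signal Purine absorbance signal(s).
#' @param pyrimidine_signal Positive pyrimidine signal(s).
#' @return Elementwise ratio.
#' @export
purine_pyrimidine_ratio <- function(purine_signal, pyrimidine_signal) {
  if (any(pyrimidine_signal <= 0)) abort("pyrimidine signal must be positive")
  purine_signal / pyrimidine_signal
}

#' Fold difference between control and patient ratio means
#'
#' @param control_mean Control-group mean ratio.
#' @param patient_mean Positive patient-group mean ratio.
#' @return `control_mean / patient_mean`.
#' @examples
#' ratio_fold(3.17, 1.26)  # ~2.5
#' @export
ratio_fold <- function(control_mean, patient_mean) {
  if (any(patient_mean <= 0)) abort("patient mean must be positive")
  control_mean / patient_mean
}

#' Eosin-5-maleimide binding as percent of reference
#'
#' Flow-cytometry mean fluorescence intensity expressed as a percentage of
#' the laboratory reference, rounded half-up to an integer for reporting.
#' A reference given as a range (two values) uses its midpoint.
#'
#' @param patient_mfi Patient MFI.
#' @param reference_mfi Reference MFI: a single positive value or a
#'   length-2 range.
#' @return Integer percent of reference.
#' @examples
#' ema_percent(5.73, 5.1)                 # 112
#' ema_percent(114.05, c(98.31, 110.23))  # 109
#' @export
ema_percent <- function(patient_mfi, reference_mfi) {
  ref <- if (length(reference_mfi) == 2) mean(reference_mfi) else reference_mfi[1]
  if (ref <= 0) abort("reference MFI must be positive")
  as.integer(round_half_up(100 * patient_mfi / ref, 0))
}

#' Dual-luciferase normalization
#'
#' Firefly luciferase expression normalized to the Renilla co-transfection
#' control; optionally expressed relative to a designated control well.
#'
#' @param firefly Firefly luminescence value(s).
#' @param renilla Positive Renilla luminescence value(s).
#' @param control Optional index or name of the control well; when given,
#'   normalized values are divided by the control's normalized value (the
#'   control maps to 1).
#' @return Normalized (and optionally relative) expression values.
#' @examples
#' normalize_dlr(2000, 1000)                       # 2
#' normalize_dlr(c(a = 100, b = 300), c(100, 100), control = "a")
#' @export
normalize_dlr <- function(firefly, renilla, control = NULL) {
  if (any(renilla <= 0)) abort("Renilla values must be positive")
  norm <- firefly / renilla
  if (!is.null(control)) {
    ctrl <- norm[control]
    if (length(ctrl) != 1 || is.na(ctrl)) abort("control well not found")
    norm <- norm / as.numeric(ctrl)
  }
  norm
}
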