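#' Calibration model mapping MS2 intensity to mRNA molecule counts
#'
#' @param qq_slope,qq_intercept Parameters of the linear fit to the
#'   quantile-quantile pairing of MS2 intensities against smFISH molecule
#'   counts; `molecules = qq_slope * intensity + qq_intercept`.
#' @param unit_intensity Intensity of a single mRNA molecule (a.u.),
#'   per fluorophore; optional, recorded for provenance.
#' @param detection_floor_molecules Counts below this are flagged as below
#'   the detection limit (default 3 molecules).
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(qq_slope, qq_intercept,
                              unit_intensity = NA_real_,
                              detection_floor_molecules = 3) {
  if (!is.na(unit_intensity) && unit_intensity <= 0)
    stop("unit_intensity must be > 0")
  if (qq_slope <= 0) stop("qq_slope must be > 0")
  structure(list(qq_slope = qq_slope, qq_intercept = qq_intercept,
                 unit_intensity = unit_intensity,
                 detection_floor_molecules = detection_floor_molecules),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> molecules = %.4g * I + %.4g (floor %g)\n",
              x$qq_slope, x$qq_intercept, x$detection_floor_molecules))
  invisible(x)
}

#' Single-molecule intensity from smFISH spot intensities
#'
#' The median intensity of all detected particles above `min_threshold` is
#' used as a proxy for the intensity of a single mRNA molecule; the
#' threshold removes nonspecific particles.
#'
#' @param intensities Numeric vector of spot intensities.
#' @param min_threshold Intensities at or below this are discarded first.
#' @return The unit intensity (a.u. per molecule).
#' @export
estimate_unit_intensity <- function(intensities, min_threshold = 0) {
  kept <- intensities[is.finite(intensities) & intensities > min_threshold]
  if (!length(kept)) stop("no spots above threshold")
  stats::median(kept)
}

#' Molecules at an active transcription site
#'
#' Total ATS intensity divided by the single-molecule intensity.
#'
#' @param ats_total_intensity Total spot intensity (a.u.).
#' @param unit_intensity Single-molecule intensity (a.u.), > 0.
#' @param round_to Optional number of digits to round the count to
#'   (default `NULL`, unrounded).
#' @return Molecule count (real-valued unless rounded).
#' @export
ats_molecule_count <- function(ats_total_intensity, unit_intensity,
                               round_to = NULL) {
  if (unit_intensity <= 0) stop("unit_intensity must be > 0")
  n <- ats_total_intensity / unit_intensity
  if (!is.null(round_to)) n <- round(n, round_to)
  n
}

#' Quantile-quantile calibration of MS2 intensities against smFISH counts
#'
#' Sorts both samples, matches quantiles on a common probability grid of
#' `min(n1, n2)` equally spaced probabilities (linear interpolation between
#' order statistics), and fits an ordinary least-squares line
#' `molecules ~ intensity`. Samples from multiple genes should be pooled
#' before calling (the relationship is gene-independent, so a single
#' combined fit is used).
#'
#' @param ms2_intensity MS2 focus intensities (a.u.), nonempty.
#' @param smfish_molecules smFISH ATS molecule counts, nonempty.
#' @param unit_intensity,detection_floor_molecules Passed through to the
#'   returned model.
#' @return A `calibration_model` with the quantile pairs attached as
#'   attribute `qq_points`.
#' @export
qq_calibrate <- function(ms2_intensity, smfish_molecules,
                         unit_intensity = NA_real_,
                         detection_floor_molecules = 3) {
  if (!length(ms2_intensity) || !length(smfish_molecules))
    stop("both samples must be nonempty")
  if (stats::sd(ms2_intensity) == 0 || stats::sd(smfish_molecules) == 0)
    stop("degenerate (constant) sample")
  m <- min(length(ms2_intensity), length(smfish_molecules))
  probs <- (seq_len(m) - 0.5) / m
  qx <- stats::quantile(ms2_intensity, probs, type = 7, names = FALSE)
  qy <- stats::quantile(smfish_molecules, probs, type = 7, names = FALSE)
  fit <- stats::lm(qy ~ qx)
  model <- calibration_model(qq_slope = unname(stats::coef(fit)[2]),
                             qq_intercept = unname(stats::coef(fit)[1]),
                             unit_intensity = unit_intensity,
                             detection_floor_molecules = detection_floor_molecules)
  attr(model, "qq_points") <- data.frame(ms2 = qx, molecules = qy)
  model
}

#' Convert a trace to absolute molecule counts
#'
#' Applies the calibration line; counts are floored at zero after intercept
#' subtraction, and frames below the detection floor are flagged.
#'
#' @param trace A `fluor_trace` in arbitrary units.
#' @param model A `calibration_model`.
#' @param clip_negative Floor calibrated values at 0 (default TRUE).
#' @return The calibrated trace (channel suffixed `"_mol"`), with a logical
#'   attribute `below_detection` per frame.
#' @export
apply_calibration <- function(trace, model, clip_negative = TRUE) {
  mol <- model$qq_slope * trace$intensity + model$qq_intercept
  if (clip_negative) mol <- pmax(mol, 0)
  below <- trace$present & mol < model$detection_floor_molecules
  trace$intensity <- mol
  trace$channel <- paste0(trace$channel, "_mol")
  attr(trace, "below_detection") <- below
  trace
}

#' Invert a calibration (molecules back to arbitrary units)
#'
#' @param trace A calibrated trace.
#' @param model The `calibration_model` used to calibrate it.
#' @return The trace mapped back through the calibration line.
#' @export
invert_calibration <- function(trace, model) {
  trace$intensity <- (trace$intensity - model$qq_intercept) / model$qq_slope
  trace$channel <- sub("_mol$", "", trace$channel)
  trace
}
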