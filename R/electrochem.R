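## Voltammetric calibration analysis.
##
## Cyclic-voltammetry peak currents are linear in analyte concentration
## at fixed scan rate (diffusion-controlled response), so a serial
## dilution of a stock solution yields a calibration line from which a
## saturated sample's concentration -- the solubility -- is read off.

#' Peak current from the diffusion-controlled voltammetric response
#'
#' Standard peak-current law at 25 C:
#' i_p = 2.69e5 n^(3/2) A C sqrt(D v).
#' The square-root dependence on diffusion coefficient and scan rate is
#' the standard form; only the linearity in concentration matters for
#' the solubility pipeline.
#'
#' @param n electrons per redox event (positive integer).
#' @param A electrode area, cm^2.
#' @param C analyte concentration, mol/cm^3.
#' @param D diffusion coefficient, cm^2/s.
#' @param v scan rate, V/s.
#' @return Peak current in amperes.
#' @examples
#' randles_sevcik_current(n = 1, A = 1, C = 1e-6, D = 1e-5, v = 0.1)
#' @export
randles_sevcik_current <- function(n, A, C, D, v) {
  vals <- c(n = n, A = A, C = C, D = D, v = v)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all voltammetry parameters must be finite and > 0", call. = FALSE)
  }
  if (n != round(n)) stop("`n` must be a positive integer", call. = FALSE)
  2.69e5 * n^1.5 * A * C * sqrt(D * v)
}

#' Concentrations along a sequential-addition dilution series
#'
#' Starting from `initial_volume` mL of stock at `initial_concentration`,
#' `n_additions` aliquots of `addition_volume` mL of blank electrolyte
#' are added sequentially; after the i-th addition the concentration is
#' C0 V0 / (V0 + i Va).
#'
#' @param initial_volume stock volume V0, mL (> 0).
#' @param addition_volume per-step addition Va, mL (>= 0).
#' @param n_additions number of additions (>= 0).
#' @param initial_concentration stock concentration C0, mol/L.
#' @return Numeric vector of length `n_additions + 1`, starting at C0.
#' @examples
#' dilution_series(2.0, 0.5, 6, 1)  # the 2.0 mL + six 0.5 mL schedule
#' @export
dilution_series <- function(initial_volume, addition_volume, n_additions,
                            initial_concentration = 1) {
  if (initial_volume <= 0) stop("initial_volume must be > 0", call. = FALSE)
  if (addition_volume < 0) stop("addition_volume must be >= 0", call. = FALSE)
  if (n_additions < 0 || n_additions != round(n_additions)) {
    stop("n_additions must be a non-negative integer", call. = FALSE)
  }
  i <- 0:n_additions
  initial_concentration * initial_volume /
    (initial_volume + i * addition_volume)
}

#' Fit a voltammetric calibration line
#'
#' Ordinary least squares of peak current on concentration.  Curves are
#' accepted only if r^2 exceeds `r2_min` (strict inequality); rejected
#' fits are returned as a `calibration_rejection` carrying the computed
#' r^2 so the caller can report it.
#'
#' @param concentration concentrations, mol/L (>= 3 points, >= 2 distinct).
#' @param current peak currents (same length; any consistent current unit).
#' @param r2_min acceptance threshold on r^2 (default 0.97, strict `>`).
#' @param through_origin force a zero intercept (default `FALSE`: a
#'   baseline current offset exists in practice).
#' @return On acceptance, a `calibration_curve` with `slope`,
#'   `intercept`, `r_squared` and the source `points`; otherwise a
#'   `calibration_rejection` with the same fields.  Both answer
#'   [is_accepted()].
#' @export
fit_calibration <- function(concentration, current, r2_min = 0.97,
                            through_origin = FALSE) {
  if (length(concentration) != length(current)) {
    stop("concentration and current must have equal length", call. = FALSE)
  }
  if (length(concentration) < 3L) {
    stop("need at least 3 calibration points", call. = FALSE)
  }
  if (length(unique(concentration)) < 2L) {
    stop("degenerate design: all concentrations equal", call. = FALSE)
  }
  fit <- if (through_origin) {
    stats::lm(current ~ 0 + concentration)
  } else {
    stats::lm(current ~ concentration)
  }
  slope <- unname(stats::coef(fit)[["concentration"]])
  intercept <- if (through_origin) 0 else unname(stats::coef(fit)[[1L]])
  fitted <- intercept + slope * concentration
  ## r^2 about the mean in both cases, so through-origin fits are
  ## reported on the same scale
  rsq <- 1 - sum((current - fitted)^2) /
    sum((current - mean(current))^2)
  out <- list(slope = slope, intercept = intercept, r_squared = rsq,
              r2_min = r2_min, through_origin = through_origin,
              points = data.frame(concentration = concentration,
                                  current = current))
  cls <- if (rsq > r2_min) "calibration_curve" else "calibration_rejection"
  structure(out, class = cls)
}

#' Did a calibration fit pass the r^2 filter?
#' @param x result of [fit_calibration()].
#' @return `TRUE` for an accepted `calibration_curve`.
#' @export
is_accepted <- function(x) inherits(x, "calibration_curve")

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration curve: i = %.6g * C + %.6g  (r^2 = %.4f, accepted; %d points)\n",
              x$slope, x$intercept, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' @export
print.calibration_rejection <- function(x, ...) {
  cat(sprintf("calibration REJECTED: r^2 = %.4f <= %.2f  (%d points)\n",
              x$r_squared, x$r2_min, nrow(x$points)))
  invisible(x)
}

#' Saturation solubility from a measured peak current
#'
#' Inverts an accepted calibration line: S = dilution_factor *
#' (i - intercept) / slope.  The measured aliquot is usually diluted
#' before the scan, hence the dilution factor (>= 1).
#'
#' @param curve an accepted `calibration_curve`.
#' @param measured_current peak current of the (diluted) saturated sample.
#' @param dilution_factor aliquot dilution factor (>= 1).
#' @return Solubility in mol/L.  Warns if the measured current lies
#'   outside the calibrated current range; errors if the implied
#'   concentration is not positive.
#' @export
solubility_from_cv <- function(curve, measured_current, dilution_factor = 1) {
  if (!is_accepted(curve)) {
    stop("calibration curve was rejected (r^2 = ",
         signif(curve$r_squared, 4), "); cannot quantify", call. = FALSE)
  }
  if (dilution_factor < 1) stop("dilution_factor must be >= 1", call. = FALSE)
  rng <- range(curve$points$current)
  span <- diff(rng)
  if (measured_current < rng[1] - 0.05 * span ||
      measured_current > rng[2] + 0.05 * span) {
    warning("measured current ", signif(measured_current, 4),
            " lies outside the calibrated range [",
            signif(rng[1], 4), ", ", signif(rng[2], 4), "]", call. = FALSE)
  }
  conc <- (measured_current - curve$intercept) / curve$slope
  if (conc <= 0) {
    stop("measured current is at or below the calibration intercept; ",
         "implied concentration is not positive", call. = FALSE)
  }
  dilution_factor * conc
}
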