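# Linear calibration: fit, inverse prediction, detection limits, stability.

#' Fit a linear calibration curve
#'
#' Ordinary least-squares fit of instrument response (absorbance or peak
#' area) on analyte concentration, the standard Beer-Lambert style
#' calibration used to quantify dissolution and PAMPA samples.
#'
#' @param standards data frame with numeric columns `concentration`
#'   (mass concentration, ug/ml, all > 0) and `response` (instrument
#'   response, dimensionless). One row per standard replicate.
#'
#' @return An object of class `calibration_curve`: a list with `slope`,
#'   `intercept`, their standard errors `slope_sd` and `intercept_sd`,
#'   `r_squared`, `conc_range` (min/max of the standards, ug/ml) and
#'   `n_points`.
#'
#' @details The regression is unweighted; the calibration design must
#'   contain at least 3 points spanning at least 2 distinct
#'   concentrations. When the residuals are exactly zero (points on an
#'   exact line) the coefficient standard errors are zero and
#'   `r_squared` is 1.
#'
#' @examples
#' std <- data.frame(concentration = c(0.375, 0.75, 1.5, 3, 6),
#'                   response = 0.045 * c(0.375, 0.75, 1.5, 3, 6) + 0.009)
#' fit_calibration(std)
#' @export
fit_calibration <- function(standards) {
  if (!is.data.frame(standards) ||
      !all(c("concentration", "response") %in% names(standards))) {
    stop("`standards` must be a data frame with columns `concentration` and `response`")
  }
  conc <- as.numeric(standards$concentration)
  resp <- as.numeric(standards$response)
  if (any(!is.finite(conc)) || any(!is.finite(resp))) {
    stop("calibration standards must be finite")
  }
  if (any(conc <= 0)) stop("standard concentrations must be positive")
  if (length(conc) < 3 || length(unique(conc)) < 2) {
    stop("insufficient calibration design: need >= 3 standards at >= 2 distinct concentrations")
  }
  fit <- stats::lm(resp ~ conc)
  # exact-line standards are legitimate; silence lm's perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  out <- list(
    slope = unname(co["conc", "Estimate"]),
    intercept = unname(co["(Intercept)", "Estimate"]),
    slope_sd = unname(co["conc", "Std. Error"]),
    intercept_sd = unname(co["(Intercept)", "Std. Error"]),
    r_squared = sm$r.squared,
    conc_range = c(min(conc), max(conc)),
    n_points = length(conc)
  )
  if (out$slope == 0) stop("degenerate calibration: zero slope")
  class(out) <- "calibration_curve"
  out
}

#' Construct a calibration curve from known coefficients
#'
#' Builds a `calibration_curve` directly from published coefficients,
#' e.g. when only the fitted equation of an assay is available rather
#' than the raw standards.
#'
#' @param slope response per (ug/ml); must be nonzero.
#' @param intercept response at zero concentration.
#' @param slope_sd,intercept_sd standard errors of the coefficients
#'   (same units); default `NA`.
#' @param conc_range numeric length-2 validity range in ug/ml.
#' @param r_squared coefficient of determination, if known.
#' @param n_points number of standards behind the fit, if known.
#' @return A `calibration_curve` object.
#' @examples
#' calibration_curve(slope = 0.045, intercept = 0.009,
#'                   intercept_sd = 0.003, conc_range = c(0.375, 6))
#' @export
calibration_curve <- function(slope, intercept, slope_sd = NA_real_,
                              intercept_sd = NA_real_,
                              conc_range = c(-Inf, Inf),
                              r_squared = NA_real_, n_points = NA_integer_) {
  if (!is.finite(slope) || slope == 0) stop("slope must be finite and nonzero")
  if (!is.finite(intercept)) stop("intercept must be finite")
  if (length(conc_range) != 2 || conc_range[1] >= conc_range[2]) {
    stop("conc_range must be (min, max) with min < max")
  }
  structure(list(slope = slope, intercept = intercept,
                 slope_sd = slope_sd, intercept_sd = intercept_sd,
                 r_squared = r_squared, conc_range = as.numeric(conc_range),
                 n_points = n_points),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve: response = %.6g * conc + %.6g\n",
              x$slope, x$intercept))
  if (is.finite(x$r_squared)) cat(sprintf("  r^2 = %.4f\n", x$r_squared))
  if (all(is.finite(x$conc_range))) {
    cat(sprintf("  valid range: %.4g - %.4g ug/ml (n = %s)\n",
                x$conc_range[1], x$conc_range[2], x$n_points))
  }
  invisible(x)
}

#' Inverse prediction: response to concentration
#'
#' Interpolates instrument responses on a fitted calibration curve,
#' returning `(response - intercept) / slope`. Values that fall outside
#' the curve's concentration range are still returned but flagged as
#' extrapolated (attribute `extrapolated`) with a warning, since early
#' dissolution samples routinely sit below the lowest standard.
#'
#' @param curve a `calibration_curve`.
#' @param response numeric vector of instrument responses; must be finite.
#' @return Numeric vector of concentrations (ug/ml) with a logical
#'   attribute `extrapolated` marking out-of-range predictions.
#' @examples
#' cc <- calibration_curve(0.045, 0.009, conc_range = c(0.375, 6))
#' invert_calibration(cc, 0.0684)  # ~1.32 ug/ml
#' @export
invert_calibration <- function(curve, response) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(!is.finite(response))) stop("response must be finite")
  conc <- (response - curve$intercept) / curve$slope
  extra <- conc < curve$conc_range[1] | conc > curve$conc_range[2]
  if (any(extra)) {
    warning(sprintf("%d prediction(s) outside the calibration range %.4g-%.4g ug/ml (extrapolated)",
                    sum(extra), curve$conc_range[1], curve$conc_range[2]))
  }
  attr(conc, "extrapolated") <- extra
  conc
}

#' Limits of detection and quantitation
#'
#' LoD and LoQ from the calibration coefficients using the ICH
#' sigma-of-blank convention with the intercept standard error as the
#' blank noise estimate: LoD = 3.3 * sd(intercept) / slope and
#' LoQ = 10 * sd(intercept) / slope.
#'
#' @param curve a `calibration_curve` with a finite `intercept_sd`.
#' @return List with `lod` and `loq` in ug/ml.
#' @examples
#' cc <- calibration_curve(0.045, 0.009, intercept_sd = 0.003)
#' detection_limits(cc)
#' @export
detection_limits <- function(curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(curve$intercept_sd)) stop("intercept_sd is required for detection limits")
  if (curve$slope == 0) stop("slope must be nonzero")
  list(lod = 3.3 * curve$intercept_sd / abs(curve$slope),
       loq = 10 * curve$intercept_sd / abs(curve$slope))
}

#' Screen analyte stability over time
#'
#' Flags whether an analyte solution is stable over a monitoring period
#' by the maximum relative drift of its instrument response from the
#' initial reading. Used to pick an assay concentration that survives
#' long PAMPA incubations.
#'
#' @param time_h numeric vector of time points in hours (>= 2 points).
#' @param response instrument responses at those times; `response[1]`
#'   (at the earliest time) must be positive.
#' @param max_rel_drift allowed relative drift as a fraction; default
#'   0.05 (5%).
#' @return List with `stable` (logical) and `observed_max_drift`
#'   (fraction).
#' @examples
#' check_stability(c(0, 24, 48), c(1.0, 0.99, 0.98))
#' @export
check_stability <- function(time_h, response, max_rel_drift = 0.05) {
  if (length(time_h) != length(response)) stop("time_h and response must have equal length")
  if (length(response) < 2) stop("need at least 2 time points")
  ord <- order(time_h)
  response <- response[ord]
  if (!is.finite(response[1]) || response[1] <= 0) {
    stop("initial response must be positive")
  }
  drift <- max(abs(response - response[1]) / response[1])
  list(stable = drift <= max_rel_drift, observed_max_drift = drift)
}
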