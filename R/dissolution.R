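# Dissolution profiles: % released, withdrawal correction, f1/f2 fit factors.

#' Percent released from a measured concentration
#'
#' Expresses a dissolved-drug concentration as a percentage of the
#' theoretical maximum concentration the dosage form can reach in the
#' vessel (dose / medium volume).
#'
#' @param concentration measured concentration, ug/ml (>= 0).
#' @param theoretical_max theoretical maximum concentration, ug/ml (> 0).
#' @return Percent released, unrounded. Vectorized over `concentration`.
#' @examples
#' percent_released_conc(1.32, 1.5)  # 88
#' @export
percent_released_conc <- function(concentration, theoretical_max) {
  if (!is.numeric(theoretical_max) || length(theoretical_max) != 1 ||
      !is.finite(theoretical_max) || theoretical_max <= 0) {
    stop("theoretical_max must be a single positive number")
  }
  if (any(concentration < 0, na.rm = TRUE)) stop("concentration must be >= 0")
  100 * concentration / theoretical_max
}

#' Percent released from an HPLC peak-area ratio
#'
#' Release percentage from the area of a dissolution sample relative to
#' the average area of a reference-standard injection:
#' `sample_area * Ws * Wu / (standard_average_area * 20 * 1.5)`,
#' where 20 is the dilution factor of the standard preparation and 1.5
#' the theoretical assay result of one tablet (mg of drug).
#'
#' @param sample_area peak area of the dissolution sample (>= 0).
#' @param standard_average_area mean peak area of the standard (> 0).
#' @param Ws weight of drug working standard, mg (> 0); 30 mg in the
#'   standard preparation this formula assumes.
#' @param Wu assay percentage of the working standard (> 0), e.g. 100.
#' @return Percent of the active ingredient released; linear in
#'   `sample_area`.
#' @examples
#' percent_released_hplc(1000, 1000, Ws = 30, Wu = 100)  # 100
#' @export
percent_released_hplc <- function(sample_area, standard_average_area,
                                  Ws = 30, Wu = 100) {
  if (standard_average_area <= 0) stop("standard_average_area must be positive")
  if (Ws <= 0 || Wu <= 0) stop("Ws and Wu must be positive")
  if (any(sample_area < 0)) stop("sample_area must be >= 0")
  sample_area * Ws * Wu / (standard_average_area * 20 * 1.5)
}

#' Sampling scheme of a dissolution apparatus
#'
#' @param vessel_volume medium volume in the vessel, ml.
#' @param sample_volume volume withdrawn per sampling, ml; must be
#'   positive and smaller than `vessel_volume`.
#' @param replace_with_medium whether withdrawn volume is replaced with
#'   fresh medium (the usual pharmacopoeial practice).
#' @return A `sampling_scheme` list.
#' @export
sampling_scheme <- function(vessel_volume = 1000, sample_volume = 3,
                            replace_with_medium = TRUE) {
  if (sample_volume <= 0 || sample_volume >= vessel_volume) {
    stop("require 0 < sample_volume < vessel_volume")
  }
  structure(list(vessel_volume = vessel_volume, sample_volume = sample_volume,
                 replace_with_medium = replace_with_medium),
            class = "sampling_scheme")
}

#' Correct measured concentrations for sampling withdrawal
#'
#' When each withdrawn aliquot is replaced with fresh medium, the
#' measured concentration at later time points underestimates the
#' cumulative amount dissolved. The standard cumulative-sampling
#' correction adds back the diluted fraction:
#' `c'_k = c_k + (Vs / V) * sum_{j < k} c_j`.
#'
#' @param conc measured concentrations (ug/ml) in time order.
#' @param scheme a [sampling_scheme()]. When `replace_with_medium` is
#'   `FALSE` the input is returned unchanged.
#' @return Corrected concentrations, never smaller than the input.
#' @examples
#' correct_cumulative(rep(1.5, 4), sampling_scheme(1000, 3))
#' @export
correct_cumulative <- function(conc, scheme) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  if (!scheme$replace_with_medium || length(conc) <= 1) return(conc)
  ratio <- scheme$sample_volume / scheme$vessel_volume
  conc + ratio * c(0, cumsum(conc)[-length(conc)])
}

#' Difference fit factor f1
#'
#' `f1 = 100 * sum(|R_t - T_t|) / sum(R_t)`, the pointwise relative
#' difference between a reference (`R`) and a test (`T`) dissolution
#' profile. Zero for identical profiles; note the asymmetry: the
#' reference profile supplies the denominator.
#'
#' @param reference,test percent-released values at matched time
#'   points; equal length, `sum(reference) > 0`.
#' @return f1 (dimensionless, >= 0).
#' @examples
#' fit_factor_f1(c(88, 100), c(60, 67))
#' @export
fit_factor_f1 <- function(reference, test) {
  if (length(reference) != length(test)) stop("profiles must have equal length")
  if (length(reference) < 1) stop("need at least one time point")
  if (sum(reference) <= 0) stop("reference profile must have positive sum")
  100 * sum(abs(reference - test)) / sum(reference)
}

#' Similarity fit factor f2
#'
#' `f2 = 50 * log10(100 * (1 + MSD)^(-1/2))` with
#' `MSD = mean((R_t - T_t)^2)`. Equals 100 for identical profiles and
#' decreases as the profiles diverge; the conventional similarity
#' cutoff f2 >= 50 corresponds to a mean squared difference of 99
#' (about 10 percentage points RMS).
#'
#' @inheritParams fit_factor_f1
#' @return f2 (dimensionless, <= 100). Symmetric in its arguments.
#' @examples
#' fit_factor_f2(c(88, 100), c(60, 67))
#' @export
fit_factor_f2 <- function(reference, test) {
  if (length(reference) != length(test)) stop("profiles must have equal length")
  if (length(reference) < 1) stop("need at least one time point")
  msd <- mean((reference - test)^2)
  50 * log10(100 * (1 + msd)^(-0.5))
}

#' Compute both fit factors for a profile pair
#'
#' @inheritParams fit_factor_f1
#' @param times optional time points (minutes) of the profile values,
#'   recorded in the result.
#' @param truncate_at_85 if `TRUE`, restrict the comparison to time
#'   points up to and including the first at which the reference
#'   profile exceeds 85% released (a common guidance rule for highly
#'   soluble drugs). Default `FALSE`: all points are used.
#' @return A `fit_factors` object: list with `f1`, `f2`, `n_points`,
#'   `point_times`.
#' @examples
#' fit_factors(c(63, 86, 95, 98), c(53, 78, 90, 95), times = c(15, 30, 45, 60))
#' @export
fit_factors <- function(reference, test, times = NULL, truncate_at_85 = FALSE) {
  if (length(reference) != length(test)) stop("profiles must have equal length")
  if (!is.null(times) && length(times) != length(reference)) {
    stop("times must match the profiles in length")
  }
  keep <- seq_along(reference)
  if (truncate_at_85) {
    first85 <- which(reference >= 85)[1]
    if (!is.na(first85)) keep <- seq_len(first85)
  }
  r <- reference[keep]; t_ <- test[keep]
  structure(list(f1 = fit_factor_f1(r, t_),
                 f2 = fit_factor_f2(r, t_),
                 n_points = length(r),
                 point_times = if (is.null(times)) NULL else times[keep]),
            class = "fit_factors")
}

#' @export
print.fit_factors <- function(x, ...) {
  cat(sprintf("Fit factors over %d point(s): f1 = %.2f, f2 = %.2f\n",
              x$n_points, x$f1, x$f2))
  invisible(x)
}

#' Similarity verdict from fit factors
#'
#' Applies the conventional dual criterion: profiles are declared
#' similar when f1 <= `f1_max` and f2 >= `f2_min`. The regulatory
#' defaults are 15 and 50; both are configurable because published
#' studies do not always apply them consistently.
#'
#' @param factors a [fit_factors()] object, or any list with elements
#'   `f1` and `f2`.
#' @param f1_max maximum f1 for similarity (default 15).
#' @param f2_min minimum f2 for similarity (default 50).
#' @return List with `verdict` (`"similar"` or `"not_similar"`), the
#'   raw `f1` and `f2`, and the thresholds used.
#' @examples
#' similarity_verdict(list(f1 = 0.88, f2 = 85.67))
#' @export
similarity_verdict <- function(factors, f1_max = 15, f2_min = 50) {
  f1 <- factors$f1; f2 <- factors$f2
  if (is.null(f1) || is.null(f2)) stop("factors must contain f1 and f2")
  list(verdict = if (f1 <= f1_max && f2 >= f2_min) "similar" else "not_similar",
       f1 = f1, f2 = f2, f1_max = f1_max, f2_min = f2_min)
}

#' Average release rate to plateau
#'
#' The dose-normalized release rate up to the plateau: with `t*` the
#' first time at which the profile reaches `plateau_fraction` of its
#' maximum and `v*` the percent released there, the rate is
#' `dose * (v*/100) / t*` in ug/min.
#'
#' @param times time points in minutes, strictly increasing, > 0.
#' @param values percent released at those times.
#' @param dose label-claim dose in ug (1500 for a 1.5 mg tablet).
#' @param plateau_fraction fraction of the profile maximum taken as the
#'   plateau; default 0.95.
#' @return Release rate in ug/min.
#' @examples
#' release_rate(c(25, 50), c(80, 100), dose = 1500)  # 30 ug/min
#' @export
release_rate <- function(times, values, dose = 1500, plateau_fraction = 0.95) {
  if (length(times) != length(values) || length(times) < 1) {
    stop("times and values must be nonempty and of equal length")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(times <= 0)) stop("times must be positive")
  if (dose <= 0) stop("dose must be positive")
  thresh <- plateau_fraction * max(values)
  idx <- which(values >= thresh)[1]
  if (is.na(idx)) stop("profile not at plateau")
  dose * (values[idx] / 100) / times[idx]
}

#' Aggregate replicate dissolution profiles
#'
#' Collapses per-replicate percent-released values into a mean profile
#' with dispersion per formulation, detection mode and time point.
#'
#' @param profiles data frame with columns `formulation_id`,
#'   `detection_mode`, `replicate_id`, `time_min`, `pct_released`.
#' @return Data frame with one row per (formulation_id, detection_mode,
#'   time_min): `mean_pct`, `sd_pct`, `rsd_pct`, `n`.
#' @export
aggregate_profiles <- function(profiles) {
  need <- c("formulation_id", "detection_mode", "time_min", "pct_released")
  if (!all(need %in% names(profiles))) {
    stop("profiles must contain columns: ", paste(need, collapse = ", "))
  }
  key <- interaction(profiles$formulation_id, profiles$detection_mode,
                     profiles$time_min, drop = TRUE)
  rows <- lapply(split(profiles, key), function(d) {
    s <- summarize_group(d$pct_released)
    data.frame(formulation_id = d$formulation_id[1],
               detection_mode = d$detection_mode[1],
               time_min = d$time_min[1],
               mean_pct = s$mean, sd_pct = s$sd, rsd_pct = s$rsd_pct,
               n = s$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$formulation_id, out$detection_mode, out$time_min), ]
  rownames(out) <- NULL
  out
}
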