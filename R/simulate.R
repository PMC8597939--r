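# Synthetic-data generator: dissolution time courses with an insoluble
# drug-excipient aggregate pool, and PAMPA plates from the closed-form
# two-compartment permeation model, with multiplicative measurement noise.

#' Formulation parameters for the release simulator
#'
#' Ground-truth kinetics of one tablet formulation. Total release
#' follows first-order kinetics toward the dose (or Weibull when a
#' shape is given); a fraction of the released drug is bound in
#' insoluble drug-excipient aggregates that redissolve slowly. Direct
#' UV measures only the free dissolved drug, while HPLC (whose organic
#' mobile phase dissolves the aggregates) measures free + aggregated.
#'
#' @param formulation_id label for the formulation.
#' @param dose drug dose per tablet, ug; default 1500 (a 1.5 mg tablet).
#' @param vessel_volume dissolution medium volume, ml; default 1000.
#' @param k_release first-order release rate constant, 1/min.
#' @param weibull_shape optional Weibull shape; `NULL` (default) gives
#'   pure first-order release.
#' @param aggregate_fraction fraction in [0, 1) of released drug that
#'   enters the insoluble aggregate pool.
#' @param aggregate_redissolve_rate first-order rate (1/min) at which
#'   aggregates release free drug; default 0.003.
#' @return A `formulation_params` list.
#' @export
formulation_params <- function(formulation_id = "F", dose = 1500,
                               vessel_volume = 1000, k_release,
                               weibull_shape = NULL,
                               aggregate_fraction = 0,
                               aggregate_redissolve_rate = 0.003) {
  if (dose <= 0) stop("dose must be positive")
  if (vessel_volume <= 0) stop("vessel_volume must be positive")
  if (k_release <= 0) stop("k_release must be positive")
  if (aggregate_fraction < 0 || aggregate_fraction >= 1) {
    stop("aggregate_fraction must be in [0, 1)")
  }
  if (!is.null(weibull_shape) && weibull_shape <= 0) {
    stop("weibull_shape must be positive")
  }
  if (aggregate_redissolve_rate < 0) stop("aggregate_redissolve_rate must be >= 0")
  structure(list(formulation_id = formulation_id, dose = dose,
                 vessel_volume = vessel_volume, k_release = k_release,
                 weibull_shape = weibull_shape,
                 aggregate_fraction = aggregate_fraction,
                 aggregate_redissolve_rate = aggregate_redissolve_rate),
            class = "formulation_params")
}

#' Preset: brand-name-like formulation
#'
#' Fast first-order release (95% of the dose by 45 min) with no
#' aggregate formation.
#' @return A [formulation_params()] object with `formulation_id = "B"`.
#' @export
brand_formulation <- function() {
  formulation_params(formulation_id = "B", k_release = log(20) / 45,
                     aggregate_fraction = 0)
}

#' Preset: generic-like formulation
#'
#' Moderately slower first-order release (95% of the dose by 60 min)
#' with 30% of released drug bound in insoluble aggregates that
#' redissolve at 0.003/min. Total (HPLC-visible) release stays close
#' to the brand preset while the free (UV-visible) profile is strongly
#' suppressed -- the signature of drug-excipient aggregation.
#' @return A [formulation_params()] object with `formulation_id = "A"`.
#' @export
generic_formulation <- function() {
  formulation_params(formulation_id = "A", k_release = log(20) / 60,
                     aggregate_fraction = 0.3,
                     aggregate_redissolve_rate = 0.003)
}

#' Simulation configuration
#'
#' Shared settings for the synthetic-data generators: one global seed
#' (each generator derives an independent substream from it), the
#' measurement-noise level, replication, sampling times and the PAMPA
#' ground truth.
#'
#' @param seed integer global seed.
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal measurement noise on instrument responses; default 0.05.
#' @param n_replicates replicates per condition (dissolution vessels or
#'   PAMPA wells); default 4.
#' @param sample_times dissolution sampling times, minutes; default
#'   15-150 min.
#' @param true_pe ground-truth effective permeability, cm/s; default
#'   40e-6.
#' @param pe_well_cv well-to-well lognormal CV of the true Pe around
#'   its median; default 0.15.
#' @param geometry a [pampa_geometry()].
#' @param donor_conc donor concentration for plate samples, ug/ml;
#'   default 15 (the highest concentration at which the drug is stable
#'   under assay conditions).
#' @param calib_slope absorbance per (ug/ml) used to turn the donor
#'   concentration into an initial absorbance; default 0.045.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, noise_cv = 0.05, n_replicates = 4L,
                       sample_times = c(15, 30, 45, 60, 90, 120, 150),
                       true_pe = 40e-6, pe_well_cv = 0.15,
                       geometry = pampa_geometry(), donor_conc = 15,
                       calib_slope = 0.045) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (length(sample_times) < 1 || any(diff(sample_times) <= 0)) {
    stop("sample_times must be nonempty and strictly increasing")
  }
  if (true_pe <= 0) stop("true_pe must be positive")
  if (pe_well_cv < 0) stop("pe_well_cv must be >= 0")
  structure(list(seed = as.integer(seed), noise_cv = noise_cv,
                 n_replicates = as.integer(n_replicates),
                 sample_times = sample_times, true_pe = true_pe,
                 pe_well_cv = pe_well_cv, geometry = geometry,
                 donor_conc = donor_conc, calib_slope = calib_slope),
            class = "sim_config")
}

# Deterministic substream seed derived from the global seed and a
# stream label, kept below 2^31.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 69069 + h * 2971) %% 2147483629)
}

# sdlog of a lognormal with a given coefficient of variation.
lognormal_sdlog <- function(cv) sqrt(log(1 + cv^2))

# Fraction of the dose released (free + aggregated) at time t (min).
release_fraction <- function(params, t) {
  k <- params$k_release; b <- params$weibull_shape
  if (is.null(b)) 1 - exp(-k * t) else 1 - exp(-(k * t)^b)
}

# Instantaneous release density dF/dt at time t.
release_density <- function(params, t) {
  k <- params$k_release; b <- params$weibull_shape
  if (is.null(b)) k * exp(-k * t)
  else b * k * (k * t)^(b - 1) * exp(-(k * t)^b)
}

# Fraction of the dose held in the aggregate pool at time t:
# A(t) = fa * int_0^t dF/ds * exp(-ka (t - s)) ds.
aggregate_pool_fraction <- function(params, t) {
  fa <- params$aggregate_fraction
  if (fa == 0) return(rep(0, length(t)))
  ka <- params$aggregate_redissolve_rate
  vapply(t, function(tt) {
    if (tt <= 0) return(0)
    fa * stats::integrate(function(s) release_density(params, s) * exp(-ka * (tt - s)),
                          lower = 0, upper = tt,
                          rel.tol = 1e-10, abs.tol = 1e-12)$value
  }, numeric(1))
}

#' Noiseless release curves (free and total)
#'
#' The deterministic skeleton of the dissolution simulator: percent of
#' the dose released at each time, split into the total pool (what
#' HPLC sees) and the free dissolved pool (what direct UV sees).
#'
#' @param params a [formulation_params()].
#' @param times sampling times, minutes.
#' @return Data frame with `time_min`, `pct_total`, `pct_free`,
#'   `pct_aggregate`.
#' @export
release_curves <- function(params, times) {
  total <- 100 * release_fraction(params, times)
  agg <- 100 * aggregate_pool_fraction(params, times)
  data.frame(time_min = times, pct_total = total,
             pct_free = total - agg, pct_aggregate = agg)
}

#' Simulate replicate dissolution profiles
#'
#' Draws per-replicate, per-timepoint percent-released measurements for
#' one formulation under one detection mode. UV mode measures the free
#' dissolved drug only; HPLC mode measures free + aggregated drug
#' (organic modifier dissolves the aggregates). Measurement noise is
#' multiplicative lognormal (median-preserving) with CV
#' `cfg$noise_cv`. Fully reproducible from `cfg$seed`: the random
#' substream is derived from the seed, the formulation label and the
#' detection mode.
#'
#' @param params a [formulation_params()].
#' @param cfg a [sim_config()].
#' @param detection_mode `"UV"` or `"HPLC"`.
#' @return Data frame with columns `formulation_id`, `replicate_id`,
#'   `detection_mode`, `time_min`, `pct_released`.
#' @export
simulate_dissolution <- function(params, cfg, detection_mode = c("UV", "HPLC")) {
  stopifnot(inherits(params, "formulation_params"), inherits(cfg, "sim_config"))
  detection_mode <- match.arg(detection_mode)
  curves <- release_curves(params, cfg$sample_times)
  true_pct <- if (detection_mode == "UV") curves$pct_free else curves$pct_total
  sdlog <- lognormal_sdlog(cfg$noise_cv)
  nt <- length(cfg$sample_times)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$seed, paste0("diss/", params$formulation_id, "/", detection_mode)))
  rows <- lapply(seq_len(cfg$n_replicates), function(r) {
    noise <- if (sdlog > 0) exp(stats::rnorm(nt, 0, sdlog)) else rep(1, nt)
    data.frame(formulation_id = params$formulation_id,
               replicate_id = sprintf("r%d", r),
               detection_mode = detection_mode,
               time_min = cfg$sample_times,
               pct_released = true_pct * noise,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Closed-form percent transport of the two-compartment model
#'
#' Forward model inverted by [permeability()]:
#' `%T = (100 * Vd / (Vd + Vr)) * (1 - exp(-Pe * S * t * (Vd + Vr) / (Vd * Vr)))`.
#' Mass is conserved (no membrane retention term).
#'
#' @param pe effective permeability, cm/s (>= 0).
#' @param geom a [pampa_geometry()].
#' @param t incubation time, seconds (>= 0).
#' @return Percent transport. Vectorized over `pe` and `t`.
#' @examples
#' closed_form_percentT(41.26e-6, t = 7200)  # ~29.2
#' @export
closed_form_percentT <- function(pe, geom = pampa_geometry(), t) {
  stopifnot(inherits(geom, "pampa_geometry"))
  if (any(pe < 0)) stop("pe must be >= 0")
  if (any(t < 0)) stop("t must be >= 0")
  vd <- geom$Vd; vr <- geom$Vr
  (100 * vd / (vd + vr)) * (1 - exp(-pe * geom$S * t * (vd + vr) / (vd * vr)))
}

#' ODE oracle for percent transport
#'
#' Independent check of [closed_form_percentT()]: fixed-step
#' fourth-order Runge-Kutta integration of the two-compartment mass
#' balance `dMd/dt = -Pe * S * (Cd - Ca)`, `dMr/dt = +Pe * S * (Cd - Ca)`
#' with `Cd = Md/Vd`, `Ca = Mr/Vr`, `Md(0) = 1`, `Mr(0) = 0`, reporting
#' `%T = 100 * Mr(t) / Md(0)` (equivalently `100 * Vr * Ca / (Vd * Cd0)`).
#'
#' @param pe effective permeability, cm/s.
#' @param geom a [pampa_geometry()].
#' @param t incubation time, seconds.
#' @param n_steps number of RK4 steps (>= 100); default 10000.
#' @return List with `pctT` and `mass_error` (max deviation of
#'   `Md + Mr` from 1 over the trajectory).
#' @export
ode_oracle_percentT <- function(pe, geom = pampa_geometry(), t, n_steps = 1e4) {
  stopifnot(inherits(geom, "pampa_geometry"))
  if (n_steps < 100) stop("n_steps must be >= 100")
  if (t < 0) stop("t must be >= 0")
  vd <- geom$Vd; vr <- geom$Vr; s <- geom$S
  deriv <- function(m) {
    flux <- pe * s * (m[1] / vd - m[2] / vr)
    c(-flux, +flux)
  }
  h <- t / n_steps
  m <- c(1, 0)
  mass_error <- 0
  if (t > 0) {
    for (i in seq_len(n_steps)) {
      k1 <- deriv(m)
      k2 <- deriv(m + h / 2 * k1)
      k3 <- deriv(m + h / 2 * k2)
      k4 <- deriv(m + h * k3)
      m <- m + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      mass_error <- max(mass_error, abs(sum(m) - 1))
    }
  }
  list(pctT = 100 * m[2], mass_error = mass_error)
}

#' Simulate a group of PAMPA wells
#'
#' For each of `cfg$n_replicates` wells: draws the well's true Pe from
#' a lognormal with median `true_pe` and CV `cfg$pe_well_cv`, computes
#' %T from the closed-form two-compartment model, converts the donor
#' concentration to an initial absorbance via the calibration slope,
#' inverts the %T definition to get the acceptor absorbance
#' (`Ar = Ad0 * %T * Vd / (100 * Vr)`), and applies independent
#' multiplicative lognormal noise (CV `cfg$noise_cv`) to both
#' absorbances. The random substream is derived from `cfg$seed`, the
#' sample label and the incubation time.
#'
#' @param sample_label formulation / dissolution-time tag for the wells.
#' @param cfg a [sim_config()].
#' @param t incubation time, seconds (> 0).
#' @param true_pe ground-truth Pe for this sample, cm/s; defaults to
#'   `cfg$true_pe`.
#' @return Data frame with columns `well_id`, `sample_label`, `t_s`,
#'   `Ad0`, `Ar`, ready for [pe_timecourse()].
#' @export
simulate_pampa_plate <- function(sample_label, cfg, t, true_pe = cfg$true_pe) {
  stopifnot(inherits(cfg, "sim_config"))
  if (t <= 0) stop("t must be positive (seconds)")
  if (true_pe <= 0) stop("true_pe must be positive")
  geom <- cfg$geometry
  n <- cfg$n_replicates
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$seed, paste0("plate/", sample_label, "/", format(t))))
  sdlog_pe <- lognormal_sdlog(cfg$pe_well_cv)
  pe_wells <- if (sdlog_pe > 0) {
    stats::rlnorm(n, meanlog = log(true_pe), sdlog = sdlog_pe)
  } else rep(true_pe, n)
  pctT <- closed_form_percentT(pe_wells, geom, t)
  ad0 <- cfg$donor_conc * cfg$calib_slope
  ar <- ad0 * pctT * geom$Vd / (100 * geom$Vr)
  sdlog_n <- lognormal_sdlog(cfg$noise_cv)
  noise <- function(x) if (sdlog_n > 0) x * exp(stats::rnorm(length(x), 0, sdlog_n)) else x
  data.frame(well_id = sprintf("%s-t%g-w%d", sample_label, t, seq_len(n)),
             sample_label = sample_label, t_s = t,
             Ad0 = noise(rep(ad0, n)), Ar = noise(ar),
             stringsAsFactors = FALSE)
}

# Save/restore the global RNG state so the simulators consume their own
# derived substreams without disturbing the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
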