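# PAMPA: percent transport, effective permeability, replicate aggregation,
# reference-compound QC.

#' PAMPA sandwich geometry
#'
#' Donor volume, receptor volume and membrane area of a 96-well PAMPA
#' plate. Defaults are the MultiScreen 96-well format: 0.18 cm^3 in
#' each compartment and 0.266 cm^2 of membrane.
#'
#' @param Vd donor volume, cm^3.
#' @param Vr receptor volume, cm^3.
#' @param S membrane area, cm^2.
#' @return A `pampa_geometry` list.
#' @export
pampa_geometry <- function(Vd = 0.18, Vr = 0.18, S = 0.266) {
  if (any(c(Vd, Vr, S) <= 0)) stop("Vd, Vr and S must all be positive")
  structure(list(Vd = Vd, Vr = Vr, S = S), class = "pampa_geometry")
}

#' Percent transport across the membrane
#'
#' `%T = 100 * (Vr * Ar) / (Ad0 * Vd)`: the volume-corrected ratio of
#' acceptor absorbance after incubation to the initial donor
#' absorbance. Because absorbance enters as a ratio, no calibration
#' curve is needed; with equal volumes this is simply `100 * Ar / Ad0`.
#'
#' @param Ar acceptor absorbance after incubation (>= 0).
#' @param Ad0 initial donor absorbance (> 0).
#' @param geom a [pampa_geometry()].
#' @return Percent transport. Vectorized over `Ar` and `Ad0`.
#' @examples
#' percent_transport(0.292, 1.0)  # 29.2
#' @export
percent_transport <- function(Ar, Ad0, geom = pampa_geometry()) {
  stopifnot(inherits(geom, "pampa_geometry"))
  if (any(Ad0 <= 0)) stop("Ad0 must be positive")
  if (any(Ar < 0)) stop("Ar must be >= 0")
  100 * (geom$Vr * Ar) / (Ad0 * geom$Vd)
}

#' Effective permeability from percent transport
#'
#' Closed-form two-compartment passive-diffusion solution:
#' `Pe = Vd*Vr / ((Vd+Vr) * S * t) * ln(100*Vd / (100*Vd - %T*(Vd+Vr)))`
#' in cm/s, with `t` the incubation time in seconds. %T must lie below
#' the equilibrium ceiling `100 * Vd / (Vd + Vr)` (50% for equal
#' volumes), where Pe diverges; wells at or beyond it carry no finite
#' permeability information.
#'
#' @param pctT percent transport, `0 <= pctT <` ceiling.
#' @param geom a [pampa_geometry()].
#' @param t incubation time in seconds (> 0).
#' @return Effective permeability Pe in cm/s. Vectorized over `pctT`.
#' @examples
#' permeability(29.23, t = 7200)  # ~41.3e-6 cm/s
#' @export
permeability <- function(pctT, geom = pampa_geometry(), t) {
  stopifnot(inherits(geom, "pampa_geometry"))
  if (any(t <= 0)) stop("incubation time t must be positive (seconds)")
  if (any(pctT < 0)) stop("pctT must be >= 0")
  ceiling_pct <- 100 * geom$Vd / (geom$Vd + geom$Vr)
  if (any(pctT >= ceiling_pct)) {
    stop(sprintf("at/beyond equilibrium: Pe undefined (pctT >= %.4g)", ceiling_pct))
  }
  vd <- geom$Vd; vr <- geom$Vr
  (vd * vr) / ((vd + vr) * geom$S * t) *
    log(100 * vd / (100 * vd - pctT * (vd + vr)))
}

#' Equilibrium ceiling of percent transport
#'
#' The asymptotic %T at full equilibration, `100 * Vd / (Vd + Vr)`.
#' @param geom a [pampa_geometry()].
#' @return Percent transport ceiling.
#' @export
transport_ceiling <- function(geom = pampa_geometry()) {
  100 * geom$Vd / (geom$Vd + geom$Vr)
}

#' Replicate-aggregated permeability per sample and incubation time
#'
#' Computes per-well Pe and aggregates wells by (sample_label, t_s):
#' mean, sample SD and RSD% per group. Wells whose %T is at or beyond
#' the equilibrium ceiling have no defined Pe; they are excluded and
#' counted in `n_excluded` rather than clamped.
#'
#' @param wells data frame with columns `sample_label`, `t_s`
#'   (incubation time, seconds), `Ad0`, `Ar`; optionally `well_id`.
#' @param geom a [pampa_geometry()].
#' @return Data frame with one row per group: `sample_label`, `t_s`,
#'   `pe_mean`, `pe_sd`, `rsd_pct` (all cm/s based), `n_wells`,
#'   `n_excluded`, `valid` (FALSE when every well in the group was
#'   excluded).
#' @export
pe_timecourse <- function(wells, geom = pampa_geometry()) {
  need <- c("sample_label", "t_s", "Ad0", "Ar")
  if (!all(need %in% names(wells))) {
    stop("wells must contain columns: ", paste(need, collapse = ", "))
  }
  if (nrow(wells) < 1) stop("need at least one well")
  ceiling_pct <- transport_ceiling(geom)
  key <- interaction(wells$sample_label, wells$t_s, drop = TRUE)
  rows <- lapply(split(wells, key), function(d) {
    pctT <- percent_transport(d$Ar, d$Ad0, geom)
    ok <- pctT < ceiling_pct
    pe <- if (any(ok)) permeability(pctT[ok], geom, d$t_s[ok]) else numeric(0)
    s <- if (length(pe)) summarize_group(pe) else
      list(mean = NA_real_, sd = NA_real_, rsd_pct = NA_real_, n = 0L)
    data.frame(sample_label = d$sample_label[1], t_s = d$t_s[1],
               pe_mean = s$mean, pe_sd = s$sd, rsd_pct = s$rsd_pct,
               n_wells = s$n, n_excluded = sum(!ok),
               valid = length(pe) > 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_label, out$t_s), ]
  rownames(out) <- NULL
  out
}

#' Per-well permeability values
#'
#' Helper returning the individual-well Pe values (cm/s) for one group
#' of wells, excluding wells at/beyond the equilibrium ceiling. Useful
#' for feeding group comparisons.
#'
#' @inheritParams pe_timecourse
#' @return Numeric vector of per-well Pe (possibly shorter than
#'   `nrow(wells)` when wells are excluded).
#' @export
pe_per_well <- function(wells, geom = pampa_geometry()) {
  pctT <- percent_transport(wells$Ar, wells$Ad0, geom)
  ok <- pctT < transport_ceiling(geom)
  if (!any(ok)) return(numeric(0))
  permeability(pctT[ok], geom, wells$t_s[ok])
}

#' Validate the assay against reference-permeability compounds
#'
#' Regresses experimentally determined Pe on literature Pe for a panel
#' of quality-control compounds (e.g. atenolol, carbamazepine,
#' coumarin, norfloxacin, ranitidine) and checks the correlation
#' against a QC threshold.
#'
#' @param experimental data frame with columns `compound`, `pe`.
#' @param reference data frame with columns `compound`, `pe`
#'   (literature values, same units).
#' @param qc_r2_min minimum r-squared to pass QC; default 0.95.
#' @return List with `r_squared`, `slope`, `intercept`, `n_compounds`
#'   and `pass`.
#' @export
validate_reference_panel <- function(experimental, reference, qc_r2_min = 0.95) {
  for (nm in list(experimental, reference)) {
    if (!all(c("compound", "pe") %in% names(nm))) {
      stop("panels must have columns `compound` and `pe`")
    }
  }
  m <- merge(experimental, reference, by = "compound",
             suffixes = c("_exp", "_ref"))
  if (nrow(m) < 3) stop("need at least 3 matched compounds")
  fit <- stats::lm(pe_exp ~ pe_ref, data = m)
  r2 <- suppressWarnings(summary(fit))$r.squared
  list(r_squared = r2,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n_compounds = nrow(m),
       pass = r2 > qc_r2_min)
}
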