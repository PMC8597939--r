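---
title: "Combining dissolution and PAMPA data to flag bioequivalence risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining dissolution and PAMPA data to flag bioequivalence risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invitroBE)
```

## The problem

Two tablets with the same active ingredient and the same label claim can
still behave differently in vivo. A standard paddle dissolution test with
HPLC quantification may call their release profiles "similar" while the in
vivo bioequivalence (BE) study fails. One mechanism behind such failures is
the formation of insoluble drug–excipient aggregates: drug that has left the
tablet but is bound in non-covalent complexes is not free in solution and
cannot permeate the gastrointestinal barrier. HPLC with an organic mobile
phase dissolves those aggregates during analysis and therefore over-reports
the bioavailable fraction; direct UV spectrophotometry of the centrifuged
medium measures only the free dissolved drug.

`invitroBE` implements the analysis side of a combined workflow that pairs a
dissolution test (quantified by both UV and HPLC) with a PAMPA permeability
assay, so that the two signatures of this failure mode can be detected from
bench data alone:

1. the dissolution similarity verdict *disagrees* between detection modes, and
2. the effective permeability Pe of medium drawn early in dissolution is
   *significantly lower* for one formulation.

## Models and statistics

### Calibration

Quantification is by an unweighted ordinary-least-squares line of instrument
response on concentration, inverted as `(response − intercept)/slope`.
Inverse predictions outside the standards' range are returned but flagged as
extrapolated, because early dissolution samples legitimately sit below the
lowest standard. Detection limits use the ICH sigma-of-blank convention with
the intercept standard error as the blank noise: LoD = 3.3·σ/S,
LoQ = 10·σ/S. The regression is unweighted because calibration data of this
kind rarely justify a variance model, and the only uncertainty typically
reported with such assays is on the coefficients themselves.

### Percent released and withdrawal correction

UV-route release is `100·c/c_max` with `c_max` the theoretical maximum
concentration (dose over vessel volume, 1.5 µg/ml for a 1.5 mg tablet in
1000 ml). The HPLC route uses the area-ratio assay formula
`area_sample·Ws·Wu/(area_std·20·1.5)` with `Ws` the standard weight in mg and
`Wu` its assay percentage. When each withdrawn aliquot is replaced with fresh
medium, later samples are diluted by the history of withdrawals; the standard
cumulative correction `c'_k = c_k + (Vs/V)·Σ_{j<k} c_j` is available but off
by default, mirroring common practice where the 0.3% per-sample dilution of a
3 ml draw from a 1000 ml vessel is ignored. It is switched on for
simulator-generated data where the ground truth is known.

### Profile similarity

Two mean profiles R (reference) and T (test) at n shared time points are
compared by the fit factors

- f1 = 100·Σ|R_t − T_t| / ΣR_t (difference factor; 0 for identical profiles,
  asymmetric: the reference supplies the denominator), and
- f2 = 50·log10(100·[1 + (1/n)·Σ(R_t − T_t)²]^(−1/2)) (similarity factor; 100
  for identical profiles, 50 exactly at a mean squared difference of 99,
  i.e. ≈10 percentage points RMS).

The log in f2 must be base 10 — only then does the identical-profile case
give exactly 100, which the similarity convention requires. The verdict uses
the conventional dual thresholds f1 ≤ 15 and f2 ≥ 50; both are configurable
rather than hard-coded because published studies do not apply them uniformly.
An optional guidance-mode flag restricts the point set to times up to the
first at which the reference exceeds 85% released; it is off by default since
no single point-selection rule is universal. All f1/f2 inputs are carried
unrounded; rounding is a display concern.

### PAMPA permeability

A donor and an acceptor well (volumes Vd, Vr, both 0.18 cm³ by default) are
separated by a phospholipid-coated membrane of area S = 0.266 cm². Percent
transport is the volume-corrected absorbance ratio
`%T = 100·Vr·Ar/(Vd·Ad0)` — absorbance units cancel, so Pe needs no
calibration curve. Solving the two-compartment passive-diffusion mass
balance dMd/dt = −Pe·S·(Cd − Ca) gives the closed form

Pe = [Vd·Vr/((Vd+Vr)·S·t)] · ln( 100·Vd / (100·Vd − %T·(Vd+Vr)) ),

with t in seconds and the natural logarithm (the equation is the standard
solution of the two-compartment model). %T has an equilibrium ceiling
`100·Vd/(Vd+Vr)` (50% for equal volumes) at which Pe diverges; wells at or
beyond it are excluded and counted rather than clamped, because clamping
would fabricate a permeability. The model assumes no membrane retention, so
mass is conserved — the simulator makes the same assumption. Replicates are
aggregated as mean, sample SD and RSD% per (sample, incubation time), and
the assay is validated by regressing measured Pe for reference compounds on
literature values (QC passes at r² > 0.95 by default).

### Group comparison

Formulations are compared at a shared incubation time by Welch's two-sample,
two-sided t-test. Welch rather than the pooled-variance test because
replicate RSD% in this assay can differ grossly between groups (tens of
percent apart); this is an assumption of the package, as the underlying
procedure behind published p-value statements of this kind is usually
unstated. Default alpha 0.05; no multiple-testing correction is applied
across incubation times since each comparison is reported singly.

## The synthetic-data generator

The generator exists so that every pipeline stage can be tested against a
known ground truth. It emulates:

- **Release kinetics**: total released mass follows first-order kinetics
  toward the dose (Weibull optional). A fraction `aggregate_fraction` of
  released drug enters an insoluble aggregate pool that redissolves at a
  first-order rate; UV mode measures the free pool only, HPLC mode free +
  aggregated. The pool is a deliberately minimal mechanism — a formation
  fraction plus first-order redissolution, computed as the convolution
  A(t) = fa·∫ dF/ds·e^(−ka(t−s)) ds — because the real system is only known
  to form aggregates, not how fast.
- **Permeation**: per-well true Pe drawn from a lognormal (median =
  configured Pe, CV = `pe_well_cv`), %T from the closed form, absorbances
  reconstructed from a 15 µg/ml donor concentration and a 0.045
  absorbance/(µg/ml) slope, and multiplicative lognormal noise (CV
  `noise_cv`) applied to both absorbances. Noise is multiplicative because
  RSD%, not SD, is the dispersion currency of these assays.
- **Reproducibility**: one global seed; each generator call derives its own
  substream from the seed plus its labels, so dissolution and plate noise
  are independently reproducible and the caller's RNG stream is untouched.

Default study conditions: dose 1500 µg in 1000 ml; sampling at 15–150 min;
3 dissolution replicates and 4 wells per condition with 5% measurement
noise. The brand-like preset releases fast (k = ln(20)/45 per min, i.e. 95%
of the dose by 45 min, matching a ~45 min time-to-plateau) with no
aggregates. The generic-like preset releases modestly slower (k = ln(20)/60)
with 30% of released drug aggregating and a redissolution rate of
0.003/min — chosen once so that the free (UV-visible) profile trails the
total by roughly 20 percentage points at 45 min, the size of gap that
motivates this workflow, while the total (HPLC-visible) profiles of the two
presets remain similar. The generic's slowdown is kept modest for exactly
that reason: the aggregate mechanism, not raw kinetics, must carry the
UV/HPLC disagreement. Well-to-well Pe CV defaults to a modest 0.15; the
empirically observed RSD% range of tens of percent is reproduced by raising
it to 0.4.

What the generator does *not* emulate: UV band shapes or chromatograms,
temperature effects, membrane degradation at long incubations, unstirred
water layers, pH gradients, or aggregate kinetics fitted to any real
dataset. Passing tests therefore demonstrate internal consistency of the
analysis chain and recoverability of known parameters under the stated noise
model — not that the aggregate mechanism is the true mechanism in any
particular laboratory system.

## Numerical choices

- Pe inversion errors (rather than returning Inf/NaN) for %T at or beyond
  the equilibrium ceiling; the exclusion is counted per group.
- The RK4 oracle (`ode_oracle_percentT`) integrates the two-compartment
  model with fixed steps and checks mass conservation at every step; at 10⁴
  steps it agrees with the closed form to well under 10⁻⁶ %T, which is the
  package's own verification that the closed form implemented is the
  solution of the model it claims to solve.
- The aggregate convolution uses adaptive quadrature at 10⁻¹⁰ relative
  tolerance; for pure first-order kinetics it matches the analytic
  two-exponential solution to 10⁻⁸.
- Strict CSV dialect: dot decimal separator only, header required, failures
  reported with line numbers. European decimal-comma data is rejected
  rather than silently misparsed, since the alternative is a 1000-fold
  quantitative error that looks plausible downstream.
- Times are minutes in the dissolution arm and seconds in the PAMPA arm;
  plate CSVs accept hours and convert on read.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data at
the default study conditions: 7 sampling times × 3 replicates per
formulation and mode for dissolution, 4 wells per plate group, 50 random
(Pe, t) pairs for the inversion round trip, a 12-point (Pe, t) grid at 10⁴
RK4 steps for the oracle comparison, 200 simulated plate groups for
parameter recovery, and 1000 null replicates for the type-I-error check of
the Welch comparison. These sizes give stable medians and rates while
keeping the whole suite in the seconds-to-a-minute range.

## Known limitations

- The aggregate pool parameters are fixture choices, not estimates; fitting
  them to laboratory data is explicitly out of scope.
- f1/f2 are computed on mean profiles; bootstrap or model-based profile
  comparison is not implemented.
- No temperature correction is applied between incubation conditions, and
  no membrane-failure criterion beyond the equilibrium-ceiling exclusion is
  available.
- The withdrawal correction assumes instantaneous, complete mixing after
  each replacement.
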