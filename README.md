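# invitroBE

Analysis toolkit for predicting bioequivalence (BE) risk of oral
formulations from two bench assays: a paddle dissolution test quantified by
UV spectrophotometry and/or HPLC, and a PAMPA (parallel artificial membrane
permeability assay) permeability measurement. It is aimed at formulation and
analytical scientists who need to ask, before an in vivo study: *do these
two tablets release and permeate the same way?*

The package targets a specific failure mode of dissolution-only testing.
When a drug forms insoluble drug–excipient aggregates, HPLC (whose organic
mobile phase redissolves the aggregates) reports nearly identical release
for two formulations while direct UV of the centrifuged medium — which sees
only the free, permeable drug — reveals a markedly slower profile for one of
them. `invitroBE` detects that signature by computing the dissolution
similarity verdict under *both* detection modes and combining it with the
effective permeability of medium sampled during dissolution.

## What it computes

- **Calibration**: OLS response-vs-concentration lines, inverse prediction
  with extrapolation flags, ICH detection limits (LoD = 3.3·σ/S,
  LoQ = 10·σ/S with σ the intercept SE), and a stability drift screen.
- **Dissolution**: percent released from concentration
  (100·c/c<sub>max</sub>) or from HPLC area ratios; the cumulative
  withdrawal-replacement correction; the fit factors

  f1 = 100·Σ|R<sub>t</sub> − T<sub>t</sub>| / ΣR<sub>t</sub>,  f2 = 50·log₁₀(100·[1 + (1/n)·Σ(R<sub>t</sub> − T<sub>t</sub>)²]<sup>−1/2</sup>)

  with the conventional similarity verdict (f1 ≤ 15 and f2 ≥ 50,
  configurable); and average release rates to plateau.
- **PAMPA**: percent transport %T = 100·V<sub>r</sub>·A<sub>r</sub>/(V<sub>d</sub>·A<sub>d0</sub>) and the closed-form
  two-compartment effective permeability

  Pe = [V<sub>d</sub>V<sub>r</sub>/((V<sub>d</sub>+V<sub>r</sub>)·S·t)] · ln(100·V<sub>d</sub>/(100·V<sub>d</sub> − %T·(V<sub>d</sub>+V<sub>r</sub>)))  [cm/s],

  with equilibrium-ceiling exclusion, replicate aggregation (mean, SD,
  RSD%), and reference-compound QC regression.
- **Statistics**: Welch two-sample comparison of per-well Pe between
  formulations.
- **Reporting**: a combined JSON/text report that raises an overall flag
  when the UV and HPLC similarity verdicts disagree or Pe differs
  significantly — the two bench signatures of BE risk.
- **Simulation**: a seeded generator producing dissolution time courses
  (first-order/Weibull release with an insoluble-aggregate pool) and PAMPA
  plates (closed-form permeation, lognormal noise) with known ground truth.

## Worked example

Invert a UV absorbance on the assay calibration line, express it as percent
released, and compute a permeability:

```r
library(invitroBE)

curve <- calibration_curve(0.045, 0.009, intercept_sd = 0.003,
                           conc_range = c(0.375, 6))
invert_calibration(curve, 0.0684)   # 1.32 ug/ml
percent_released_conc(1.32, 1.5)    # 88 (% of the 1.5 ug/ml theoretical max)
permeability(29.23, t = 7200)       # 4.128e-05 cm/s (41.3 x 1e-6)
```

Run the full pipeline on simulated brand-like vs generic-like formulations
(the generic releases slightly slower and binds 30% of released drug in
aggregates):

```r
cfg  <- sim_config(seed = 1, n_replicates = 3L)
diss <- rbind(
  simulate_dissolution(brand_formulation(),   cfg, "UV"),
  simulate_dissolution(brand_formulation(),   cfg, "HPLC"),
  simulate_dissolution(generic_formulation(), cfg, "UV"),
  simulate_dissolution(generic_formulation(), cfg, "HPLC"))

cfgp   <- sim_config(seed = 1, n_replicates = 4L, pe_well_cv = 0.15)
plates <- rbind(
  simulate_pampa_plate("B-30min", cfgp, t = 7200, true_pe = 41.26e-6),
  simulate_pampa_plate("A-30min", cfgp, t = 7200, true_pe = 19.33e-6))

report <- run_be_report(diss, plates, study_config(reference = "B"),
                        plate_map = c("B-30min" = "B", "A-30min" = "A"))
print(report)
```

```
Bioequivalence-risk report (schema 1.0 )
Reference formulation: B

Dissolution similarity (f1 <= 15 , f2 >= 50 ):
  [HPLC] A vs B: f1 = 7.87, f2 = 53.91 over 7 points -> similar
  [UV] A vs B: f1 = 27.23, f2 = 29.57 over 7 points -> not_similar

Permeability (Pe, x 1e-6 cm/s):
  A-30min @ 2.00 h: Pe = 20.00 (RSD 24.2%, n = 4, excluded 0)
  B-30min @ 2.00 h: Pe = 41.90 (RSD 24.7%, n = 4, excluded 0)
  compare B-30min vs A-30min @ 2.00 h: p = 0.01661 -> significant

Flags: verdict_disagreement = TRUE ; pe_significant = TRUE ; OVERALL = TRUE
   formulation A: HPLC=similar, UV=not_similar
```

Reading it: by HPLC alone the two formulations would pass as similar
(f2 = 53.9 ≥ 50), but the UV profiles disagree sharply (f2 = 29.6) because
the generic's free-drug release lags — and the permeability of its 30-min
dissolution sample is half the brand's (20 vs 42 ×10⁻⁶ cm/s, p = 0.017).
Either signal alone raises the overall flag; here both fire.

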