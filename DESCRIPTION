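Package: invitroBE
Title: In Vitro Bioequivalence Prediction from Dissolution and PAMPA Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns raw dissolution-test and PAMPA (parallel artificial
    membrane permeability assay) plate readouts into release kinetics,
    f1/f2 profile-similarity verdicts and effective permeability (Pe)
    estimates for comparing two oral formulations of the same drug.
    Includes linear UV/HPLC calibration with inverse prediction and
    detection limits, cumulative-sampling withdrawal correction,
    replicate aggregation with RSD%, Welch group comparison, a combined
    bioequivalence-risk report, and a synthetic-data simulator that
    emulates first-order/Weibull release with an insoluble
    drug-excipient aggregate pool and closed-form two-compartment
    permeation with multiplicative measurement noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
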