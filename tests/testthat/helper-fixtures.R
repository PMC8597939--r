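# Shared fixture builders for the test suite.

# Standards lying exactly on a given line.
line_standards <- function(slope, intercept, conc = c(0.375, 0.75, 1.5, 3, 6)) {
  data.frame(concentration = conc, response = slope * conc + intercept)
}

# Random strictly-positive dissolution profile of length n on [5, 105].
random_profile <- function(n = 6) sort(stats::runif(n, 5, 105))

# Simulated two-formulation study (dissolution both modes + 30-min
# plates) used by the report and end-to-end tests.
simulated_study <- function(seed = 1L, noise_cv = 0.05,
                            pe_brand = 41.26e-6, pe_generic = 19.33e-6) {
  cfg_d <- sim_config(seed = seed, noise_cv = noise_cv, n_replicates = 3L)
  brand <- brand_formulation()
  generic <- generic_formulation()
  dissolution <- rbind(
    simulate_dissolution(brand, cfg_d, "UV"),
    simulate_dissolution(brand, cfg_d, "HPLC"),
    simulate_dissolution(generic, cfg_d, "UV"),
    simulate_dissolution(generic, cfg_d, "HPLC"))
  cfg_p <- sim_config(seed = seed, noise_cv = noise_cv, n_replicates = 4L,
                      pe_well_cv = 0.15)
  plates <- rbind(
    simulate_pampa_plate("B-30min", cfg_p, t = 7200, true_pe = pe_brand),
    simulate_pampa_plate("A-30min", cfg_p, t = 7200, true_pe = pe_generic))
  list(dissolution = dissolution, plates = plates,
       plate_map = c("B-30min" = "B", "A-30min" = "A"))
}
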