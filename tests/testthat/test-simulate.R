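test_that("simulators are bit-reproducible from the global seed", {
  cfg <- sim_config(seed = 123)
  p <- generic_formulation()
  expect_identical(simulate_dissolution(p, cfg, "UV"),
                   simulate_dissolution(p, cfg, "UV"))
  expect_identical(simulate_pampa_plate("S", cfg, 7200),
                   simulate_pampa_plate("S", cfg, 7200))
  # different seeds give different draws
  cfg2 <- sim_config(seed = 124)
  expect_false(identical(simulate_dissolution(p, cfg, "UV")$pct_released,
                         simulate_dissolution(p, cfg2, "UV")$pct_released))
  # simulators do not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_dissolution(p, cfg, "UV")); after <- runif(1)
  expect_identical(before, after)
})

test_that("without aggregates UV equals HPLC and follows first-order kinetics", {
  p <- formulation_params(formulation_id = "B", k_release = 0.05,
                          aggregate_fraction = 0)
  cfg <- sim_config(seed = 1, noise_cv = 0, n_replicates = 1L)
  uv <- simulate_dissolution(p, cfg, "UV")
  hplc <- simulate_dissolution(p, cfg, "HPLC")
  expect_equal(uv$pct_released, hplc$pct_released)
  expect_equal(uv$pct_released, 100 * (1 - exp(-0.05 * cfg$sample_times)),
               tolerance = 1e-12)
})

test_that("aggregate pool suppresses the UV profile and drains over time", {
  p <- formulation_params(formulation_id = "A", k_release = 0.05,
                          aggregate_fraction = 0.3,
                          aggregate_redissolve_rate = 0.01)
  times <- c(5, 15, 30, 45, 60, 120, 300, 900)
  cv <- release_curves(p, times)
  expect_true(all(cv$pct_total >= cv$pct_free))
  expect_true(all(cv$pct_total <= 100 + 1e-9))
  # noiseless profiles are non-decreasing
  expect_true(all(diff(cv$pct_total) > 0))
  expect_true(all(diff(cv$pct_free) > 0))
  # gap -> 0 as t -> Inf when aggregates redissolve
  gap <- cv$pct_total - cv$pct_free
  expect_lt(gap[length(times)], 0.1 * max(gap))
})

test_that("numeric aggregate pool matches the first-order closed form", {
  # independent oracle: A(t) = fa * k/(ka-k) * (exp(-k t) - exp(-ka t))
  p <- formulation_params(formulation_id = "A", k_release = 0.04,
                          aggregate_fraction = 0.25,
                          aggregate_redissolve_rate = 0.006)
  times <- c(10, 30, 60, 120)
  cv <- release_curves(p, times)
  closed <- 0.25 * 0.04 / (0.006 - 0.04) * (exp(-0.04 * times) - exp(-0.006 * times))
  expect_equal(cv$pct_aggregate / 100, closed, tolerance = 1e-8)
})

test_that("Weibull shape 1 reduces to first-order release", {
  t <- c(10, 30, 60)
  p1 <- formulation_params(formulation_id = "F", k_release = 0.03)
  pw <- formulation_params(formulation_id = "F", k_release = 0.03,
                           weibull_shape = 1)
  expect_equal(release_curves(pw, t)$pct_total, release_curves(p1, t)$pct_total,
               tolerance = 1e-10)
  ps <- formulation_params(formulation_id = "F", k_release = 0.03,
                           weibull_shape = 2, aggregate_fraction = 0.2)
  cs <- release_curves(ps, c(5, 20, 40, 80))
  expect_true(all(diff(cs$pct_total) > 0))
  expect_true(all(cs$pct_free <= cs$pct_total))
})

test_that("release-rate presets bracket the fast/slow plateau times", {
  times <- seq(15, 150, by = 15)
  fast <- formulation_params(formulation_id = "B", k_release = log(20) / 45)
  slow <- formulation_params(formulation_id = "A", k_release = log(20) / 105)
  rate_fast <- release_rate(times, release_curves(fast, times)$pct_total)
  rate_slow <- release_rate(times, release_curves(slow, times)$pct_total)
  # ~30 vs ~15 ug/min for a 1.5 mg dose
  expect_equal(rate_fast, 1500 * 0.95 / 45, tolerance = 1e-6)
  expect_equal(rate_slow, 1500 * 0.95 / 105, tolerance = 1e-6)
  expect_gt(rate_fast / rate_slow, 1.8)
})

test_that("closed-form %T has the right limits and the ODE oracle conserves mass", {
  expect_equal(closed_form_percentT(0, t = 7200), 0)
  expect_equal(closed_form_percentT(1e-5, t = 0), 0)
  # equilibrium ceiling at long times
  expect_equal(closed_form_percentT(1e-4, t = 1e9), 50, tolerance = 1e-6)
  expect_equal(closed_form_percentT(41.26e-6, t = 7200), 29.2, tolerance = 2e-3)

  o <- ode_oracle_percentT(4e-5, t = 7200, n_steps = 2000)
  expect_equal(o$pctT, closed_form_percentT(4e-5, t = 7200), tolerance = 1e-7)
  expect_lt(o$mass_error, 1e-12)
  expect_equal(ode_oracle_percentT(0, t = 7200, n_steps = 200)$pctT, 0)
})

test_that("noiseless plates round-trip the true permeability exactly", {
  cfg <- sim_config(seed = 4, noise_cv = 0, pe_well_cv = 0, true_pe = 40e-6)
  wells <- simulate_pampa_plate("S", cfg, 7200)
  res <- pe_timecourse(wells, cfg$geometry)
  expect_equal(res$pe_mean, 40e-6, tolerance = 1e-12)
  expect_equal(res$pe_sd, 0)
  expect_equal(res$n_excluded, 0L)
})

test_that("well-to-well spread at CV 0.4 yields RSD% in the tens of percent", {
  cfg <- sim_config(seed = 21, noise_cv = 0.05, pe_well_cv = 0.4,
                    n_replicates = 4L, true_pe = 40e-6)
  rsds <- vapply(1:50, function(i) {
    c2 <- sim_config(seed = 21 + i, noise_cv = 0.05, pe_well_cv = 0.4,
                     n_replicates = 4L, true_pe = 40e-6)
    pe_timecourse(simulate_pampa_plate("S", c2, 7200), c2$geometry)$rsd_pct
  }, numeric(1))
  expect_gt(median(rsds), 10)
  expect_lt(median(rsds), 100)
})

test_that("a twofold Pe separation is detectable at n = 4 with modest noise", {
  cfg <- sim_config(seed = 8, noise_cv = 0.05, pe_well_cv = 0.15,
                    n_replicates = 4L)
  a <- simulate_pampa_plate("hi", cfg, 7200, true_pe = 40e-6)
  b <- simulate_pampa_plate("lo", cfg, 7200, true_pe = 19e-6)
  cmp <- compare_groups(pe_per_well(a, cfg$geometry),
                        pe_per_well(b, cfg$geometry))
  expect_equal(cmp$verdict, "significant")
  expect_gt(cmp$mean_a, cmp$mean_b)
})
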