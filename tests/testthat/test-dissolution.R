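test_that("percent released from concentration is the published worked example", {
  expect_equal(percent_released_conc(1.32, 1.5), 88)
  expect_equal(percent_released_conc(0, 1.5), 0)
  expect_equal(percent_released_conc(1.5, 1.5), 100)
  # linear in concentration
  expect_equal(percent_released_conc(c(0.3, 0.6), 1.5),
               2 * percent_released_conc(c(0.15, 0.3), 1.5))
  expect_error(percent_released_conc(1, 0), "positive")
  expect_error(percent_released_conc(-1, 1.5))
})

test_that("HPLC area-ratio release formula evaluates as printed", {
  # area ratio 1, 30 mg standard at 100% assay: 30*100/(20*1.5*100) = 100%
  expect_equal(percent_released_hplc(1000, 1000, Ws = 30, Wu = 100), 100)
  expect_equal(percent_released_hplc(0, 1000), 0)
  expect_equal(percent_released_hplc(500, 1000),
               percent_released_hplc(1000, 1000) / 2)
  expect_error(percent_released_hplc(10, 0), "positive")
  expect_error(percent_released_hplc(10, 100, Ws = -1))
})

test_that("withdrawal correction adds the hand-summed dilution series", {
  sch <- sampling_scheme(vessel_volume = 1000, sample_volume = 3)
  out <- correct_cumulative(rep(1.5, 4), sch)
  # hand sums: ratio 0.003; prior totals 0, 1.5, 3, 4.5
  expect_equal(out - rep(1.5, 4), c(0, 0.0045, 0.009, 0.0135))

  off <- sampling_scheme(1000, 3, replace_with_medium = FALSE)
  expect_equal(correct_cumulative(c(1, 2, 3), off), c(1, 2, 3))
  expect_equal(correct_cumulative(2.2, sch), 2.2)

  set.seed(7)
  conc <- cumsum(runif(6))
  expect_true(all(correct_cumulative(conc, sch) >= conc))
  tiny <- sampling_scheme(1e9, 1e-6)
  expect_equal(correct_cumulative(conc, tiny), conc, tolerance = 1e-12)
})

test_that("f1 and f2 reproduce hand-computed values", {
  # 30/45-min published release values as fixed points
  expect_equal(fit_factor_f1(c(88, 100), c(60, 67)), 100 * 61 / 188)
  expect_equal(fit_factor_f2(c(88, 100), c(60, 67)),
               50 * log10(100 / sqrt(1 + 1873 / 2)))  # 25.70
  expect_equal(fit_factor_f1(50, 40), 20)
  expect_error(fit_factor_f1(c(1, 2), 1), "equal length")
  expect_error(fit_factor_f1(c(0, 0), c(1, 1)), "positive sum")
})

test_that("identical profiles give f1 = 0 and f2 = 100; offsets move both monotonically", {
  set.seed(11)
  for (i in 1:25) {
    r <- random_profile()
    expect_equal(fit_factor_f1(r, r), 0)
    expect_equal(fit_factor_f2(r, r), 100)
  }
  # f2 = 50 exactly at mean squared difference 99
  expect_equal(fit_factor_f2(10, 10 + sqrt(99)), 50)

  r <- random_profile()
  deltas <- c(1, 2, 5, 10, 20)
  f2s <- vapply(deltas, function(d) fit_factor_f2(r, r + d), numeric(1))
  f1s <- vapply(deltas, function(d) fit_factor_f1(r, r + d), numeric(1))
  expect_true(all(diff(f2s) < 0))
  expect_true(all(diff(f1s) > 0))
})

test_that("fit factors are reorder-invariant and asymmetric only in f1", {
  set.seed(13)
  r <- random_profile(8); t_ <- r + runif(8, -10, 10)
  perm <- sample(8)
  expect_equal(fit_factor_f1(r[perm], t_[perm]), fit_factor_f1(r, t_))
  expect_equal(fit_factor_f2(r[perm], t_[perm]), fit_factor_f2(r, t_))
  # swapping R and T leaves f2 unchanged but rescales f1's denominator
  expect_equal(fit_factor_f2(t_, r), fit_factor_f2(r, t_))
  expect_equal(fit_factor_f1(t_, r) * sum(t_), fit_factor_f1(r, t_) * sum(r))
})

test_that("similarity verdict applies configurable dual thresholds", {
  expect_equal(similarity_verdict(list(f1 = 0.88, f2 = 85.67))$verdict, "similar")
  expect_equal(similarity_verdict(list(f1 = 16.18, f2 = 63))$verdict, "not_similar")
  expect_equal(similarity_verdict(list(f1 = 0, f2 = 100))$verdict, "similar")
  # same pair flips under looser f1 threshold
  expect_equal(similarity_verdict(list(f1 = 16.18, f2 = 63),
                                  f1_max = 20)$verdict, "similar")
  v <- similarity_verdict(list(f1 = 3.2, f2 = 71.4))
  expect_equal(v$f1, 3.2)
  expect_equal(v$f2, 71.4)
})

test_that("fit_factors can truncate at 85% reference release", {
  r <- c(40, 70, 90, 99)
  t_ <- c(35, 60, 88, 98)
  full <- fit_factors(r, t_, times = c(15, 30, 45, 60))
  trunc <- fit_factors(r, t_, times = c(15, 30, 45, 60), truncate_at_85 = TRUE)
  expect_equal(full$n_points, 4L)
  expect_equal(trunc$n_points, 3L)
  expect_equal(trunc$point_times, c(15, 30, 45))
  expect_equal(trunc$f1, fit_factor_f1(r[1:3], t_[1:3]))
})

test_that("release rate is dose-normalized time to plateau", {
  expect_equal(release_rate(c(25, 50), c(80, 100), dose = 1500), 30)
  expect_equal(release_rate(c(50, 100), c(80, 100), dose = 1500), 15)
  # flat profile plateaus at the first time point
  expect_equal(release_rate(c(10, 20), c(100, 100), dose = 1500), 150)
  expect_error(release_rate(c(10, 5), c(50, 100)), "strictly increasing")
  expect_error(release_rate(numeric(0), numeric(0)), "nonempty")
})

test_that("replicate profiles aggregate to mean/SD/RSD per time point", {
  prof <- data.frame(formulation_id = "B", detection_mode = "UV",
                     replicate_id = rep(c("r1", "r2"), each = 2),
                     time_min = rep(c(15, 30), 2),
                     pct_released = c(60, 80, 64, 86))
  agg <- aggregate_profiles(prof)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$mean_pct, c(62, 83))
  expect_equal(agg$n, c(2L, 2L))
  expect_equal(agg$rsd_pct[1], 100 * stats::sd(c(60, 64)) / 62)
})
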