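test_that("semi-log regression recovers an exact exponential", {
  t <- seq(0, 3, by = 0.5)
  s <- od_series(t, 0.05 * exp(0.7 * t))
  fit <- fit_growth_rate(s)
  expect_equal(fit$lambda, 0.7, tolerance = 1e-12)
  expect_equal(fit$doubling_time, log(2) / 0.7)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$doubling_time * fit$lambda, log(2))

  flat <- od_series(t, rep(0.3, length(t)))
  expect_equal(fit_growth_rate(flat)$lambda, 0)

  expect_error(fit_growth_rate(s, c(1, 3)), class = "gp_insufficient_data_error")
  expect_error(od_series(t, -0.05 * exp(0.7 * t)), class = "gp_data_error")
  expect_error(od_series(c(0, 1, 1), c(1, 2, 3)), class = "gp_data_error")
})

test_that("automatic window selection finds the exponential phase", {
  t <- seq(0, 3, by = 0.25)
  s <- od_series(t, 0.05 * exp(0.7 * t))
  expect_equal(auto_window(s), c(1L, length(t)))

  # exponential then plateau: plateau points are excluded
  t2 <- seq(0, 5, by = 0.25)
  od2 <- ifelse(t2 <= 3, 0.05 * exp(0.7 * t2), 0.05 * exp(0.7 * 3))
  w <- auto_window(od_series(t2, od2))
  expect_equal(w, c(1L, sum(t2 <= 3)))
  expect_equal(fit_growth_rate(od_series(t2, od2), w)$lambda, 0.7, tolerance = 1e-12)

  # structureless series never reaches the r2 bar
  zigzag <- od_series(seq(0, 2, by = 0.25), rep(c(1, 2), length.out = 9))
  expect_error(auto_window(zigzag, r2_min = 0.99), class = "gp_selection_error")
  expect_error(auto_window(s, min_points = 3), class = "gp_domain_error")
})

test_that("shift detection finds the slowdown point and refuses monotone curves", {
  grid <- seq(0, 14, by = 0.05)
  s <- gen_diauxic_series(0.9, 0.25, 2, 0.3, grid)
  tb <- attr(s, "truth")$t_break
  t_shift <- detect_shift(s, 0.9)
  expect_lte(abs(t_shift - tb), 0.05 + 1e-9)

  mono <- gen_od_series(0.7, 0.05, seq(0, 5, by = 0.1))
  expect_error(detect_shift(mono, 0.7), class = "gp_noshift_error")
  expect_error(detect_shift(mono, 0.7, theta = 0.99), class = "gp_noshift_error")
  expect_error(detect_shift(mono, 0.7, theta = 1.2), class = "gp_domain_error")
})

test_that("diauxic lag back-extrapolation recovers generator ground truth", {
  grid <- seq(0, 14, by = 0.05)
  for (lag in c(0, 2)) {
    s <- gen_diauxic_series(0.9, 0.25, lag, 0.3, grid)
    res <- analyze_diauxie(s)
    expect_lte(abs(res$lag - lag), 0.05 + 1e-9)
    expect_equal(res$lambda2, 0.3, tolerance = 1e-6)
  }

  # instantaneous resumption at the same rate as a pure second phase: lag 0
  s2 <- gen_diauxic_series(0.9, 0.25, 0, 0.3, grid)
  t_shift <- detect_shift(s2, 0.9)
  n <- nrow(s2)
  res2 <- diauxic_lag(s2, t_shift, c(n - 40L, n))
  expect_lte(res2$lag, 0.05 + 1e-9)

  # independence of the reference window within the exact second exponential
  res_a <- diauxic_lag(s2, t_shift, c(n - 80L, n - 40L))
  res_b <- diauxic_lag(s2, t_shift, c(n - 40L, n))
  expect_equal(res_a$lag, res_b$lag, tolerance = 1e-6)

  # flat second phase: no regrowth
  s3 <- gen_diauxic_series(0.9, 0.25, 0, 0, grid)
  expect_error(diauxic_lag(s3, 3, c(n - 40L, n)), class = "gp_noregrowth_error")
  expect_error(diauxic_lag(s2, 13.9, c(1L, 10L)), class = "gp_domain_error")
})

test_that("survival percentage follows the density arithmetic and its invariances", {
  pct <- survival_percent(cfu_observation(200, 1e5, 0.1), cfu_observation(40, 2e4, 0.1))
  expect_equal(as.numeric(pct), 4.0)
  expect_equal(attr(pct, "initial_densities"), 2e8)
  expect_equal(attr(pct, "final_densities"), 8e6)

  same <- cfu_observation(c(100, 120), 1e5, 0.1)
  expect_equal(as.numeric(survival_percent(same, same)), 100)
  expect_equal(as.numeric(survival_percent(same, cfu_observation(0, 1e5, 0.1))), 0)

  # consistent rescaling of dilution and counts leaves the percent unchanged
  a <- cfu_observation(200, 1e5, 0.1)
  b <- cfu_observation(50, 1e5, 0.1)
  a2 <- cfu_observation(20, 1e6, 0.1)
  b2 <- cfu_observation(5, 1e6, 0.1)
  expect_equal(as.numeric(survival_percent(a, b)), as.numeric(survival_percent(a2, b2)))

  expect_error(survival_percent(cfu_observation(0, 1e5, 0.1), b), class = "gp_domain_error")
  expect_error(cfu_observation(-1, 1e5, 0.1), class = "gp_domain_error")
  expect_error(cfu_observation(10, 0.5, 0.1), class = "gp_domain_error")
})

test_that("colony-area fold change and swarming fraction summarise motility tables", {
  expect_equal(colony_area_foldchange(c(1, 2, 3), c(1, 2, 3)),
               list(mean_fold = 1, sd_fold = 0, folds = c(1, 1, 1)))
  fc <- colony_area_foldchange(c(1, 1), c(2, 4))
  expect_equal(fc$mean_fold, 3)
  expect_equal(fc$sd_fold, sqrt(2))
  expect_error(colony_area_foldchange(c(1, 2), c(1, 2, 3)), class = "gp_data_error")
  expect_error(colony_area_foldchange(c(1, -2), c(1, 2)), class = "gp_data_error")

  expect_equal(swarming_fraction(rep(FALSE, 24)), 0)
  expect_equal(swarming_fraction(c(rep(TRUE, 12), rep(FALSE, 12))), 0.5)
  expect_equal(swarming_fraction(c(5, 6, 7), area_threshold = 1), 1)
  expect_equal(swarming_fraction(c(0.5, 6, 7), area_threshold = 1), 2 / 3)
  expect_error(swarming_fraction(numeric(0)), class = "gp_domain_error")
  expect_error(swarming_fraction(c(1, 2)), class = "gp_domain_error")
})
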