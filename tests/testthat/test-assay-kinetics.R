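test_that("standard curve fitting recovers exact and noisy lines", {
  sc <- fit_standard_curve(c(0, 1, 2), c(100, 300, 500))
  expect_equal(sc$slope, 200)
  expect_equal(sc$intercept, 100)
  expect_equal(sc$r_squared, 1)

  # flat fluorescence: zero slope must be rejected
  expect_error(fit_standard_curve(c(0, 1, 2), c(5, 5, 5)), "slope")
  expect_error(fit_standard_curve(c(1, 1, 1), c(1, 2, 3)), "3 distinct")

  # noisy 6-point line equals the closed-form OLS oracle
  set.seed(42)
  conc <- c(0, 1, 2, 5, 10, 20)
  fl <- 30 + 150 * conc + rnorm(6, 0, 2)
  sc <- fit_standard_curve(conc, fl, r2_threshold = 0.9)
  sxx <- sum((conc - mean(conc))^2)
  sxy <- sum((conc - mean(conc)) * (fl - mean(fl)))
  expect_equal(sc$slope, sxy / sxx, tolerance = 1e-12)
})

test_that("initial-rate estimation converts units and divides by the dilution", {
  times <- seq(0, 120, 5)
  curve <- fit_standard_curve(c(0, 5, 10, 20), 100 + 200 * c(0, 5, 10, 20))
  # perfect line, slope 10 AU/min: 10/200 * 60 * 0.17617 = 0.52851
  est <- estimate_initial_rate(times, 50 + 10 * times, curve, dilution = 1)
  expect_equal(est$rate, 10 / 200 * 60 * 0.17617, tolerance = 1e-12)
  est2 <- estimate_initial_rate(times, 50 + 10 * times, curve, dilution = 0.01)
  expect_equal(est2$rate, est$rate * 100, tolerance = 1e-9)

  expect_error(estimate_initial_rate(times[1:2], c(1, 2), curve, 1), "3 readings")
  expect_error(estimate_initial_rate(c(0, 5, 5), c(1, 2, 3), curve, 1),
               "strictly increasing")
})

test_that("the initial window recovers the pre-plateau slope of saturating kinetics", {
  times <- seq(0, 120, 5)
  slope <- 8 # AU/min until saturation at t = 60
  fl <- 40 + slope * pmin(times, 60)
  curve <- fit_standard_curve(c(0, 5, 10, 20), 100 + 200 * c(0, 5, 10, 20))
  est <- estimate_initial_rate(times, fl, curve, dilution = 1,
                               r2_threshold = 0.99)
  truth <- slope / 200 * 60 * 0.17617
  expect_lt(abs(est$rate - truth) / truth, 0.05)
  expect_lt(est$window_n, length(times)) # plateau excluded
})

test_that("blank correction floors at zero and flags large blanks", {
  expect_equal(blank_correct(10, 0)$rate, 10)
  out <- blank_correct(10, 12)
  expect_equal(out$rate, 0)
  expect_true("high_blank" %in% out$qc_flags)
  expect_equal(blank_correct(70.4, 3.5)$rate, 66.9)
  expect_length(blank_correct(70.4, 3.5)$qc_flags, 0)
})

test_that("concentration averaging flags rate discrepancies", {
  out <- average_concentrations(10, 10)
  expect_equal(out$rate, 10)
  expect_false(out$independence_flag)
  out <- average_concentrations(10, 6) # 50% relative discrepancy
  expect_equal(out$rate, 8)
  expect_true(out$independence_flag)
  out <- average_concentrations(0, 0)
  expect_equal(out$rate, 0)
  expect_false(out$independence_flag)
})

test_that("noiseless plates round-trip the true rate to machine precision", {
  for (rate in 10^seq(-1, 2, by = 1)) {
    for (dil in c(0.005, 0.01, 1.0)) {
      plate <- generate_plate(rate, dilution = dil, noise_sd = 0)$kinetics
      act <- suppressMessages(compute_activity_series(plate))
      expect_lt(abs(act$rate - rate) / rate, 1e-9)
    }
  }
})

test_that("rates are invariant to affine fluorescence offsets", {
  plate <- generate_plate(5, dilution = 0.01, noise_sd = 0)$kinetics
  shifted <- plate
  shifted$fluorescence <- shifted$fluorescence + 250
  a1 <- suppressMessages(compute_activity_series(plate))
  a2 <- suppressMessages(compute_activity_series(shifted))
  expect_equal(a1$rate, a2$rate, tolerance = 1e-9)
})

test_that("slope-estimator noise matches the OLS closed form", {
  times <- seq(0, 120, 5)
  curve <- fit_standard_curve(c(0, 5, 10, 20), 100 + 200 * c(0, 5, 10, 20))
  sigma <- 20
  slope <- 10
  set.seed(7)
  rates <- replicate(300, {
    fl <- 50 + slope * times + rnorm(length(times), 0, sigma)
    estimate_initial_rate(times, fl, curve, dilution = 1)$rate
  })
  sxx <- sum((times - mean(times))^2)
  theoretical_sd <- sigma / sqrt(sxx) / 200 * 60 * 0.17617
  expect_lt(abs(sd(rates) - theoretical_sd) / theoretical_sd, 0.15)
  expect_lt(abs(mean(rates) - slope / 200 * 60 * 0.17617) / theoretical_sd, 0.2)
})
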