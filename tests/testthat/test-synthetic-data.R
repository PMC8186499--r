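test_that("activity profile follows the lag-rise-decline shape", {
  # degenerate shape: no rise, no decline, no noise -> constant baseline
  flat <- activity_profile_spec(baseline_rate = 5, fold_rise = 1,
                                decline_fraction = 1, noise_cv = 0)
  a <- generate_activity_profile(flat)
  expect_equal(a$rate, rep(5, length(flat$days)))

  # noiseless parameterization: baseline 4 rising 17.6-fold peaks at 70.4 on
  # the plateau day (sampling days chosen to land on the peak)
  spec <- activity_profile_spec(baseline_rate = 4, fold_rise = 17.6,
                                rise_day = 32, decline_day = 62,
                                decline_fraction = 0.5, noise_cv = 0,
                                days = seq(13, 76, by = 7))
  a <- generate_activity_profile(spec)
  expect_equal(max(a$rate), 70.4, tolerance = 1e-12)
  expect_equal(a$rate[a$day == 62], 70.4, tolerance = 1e-12)
  expect_equal(a$rate[a$day <= 32], rep(4, sum(spec$days <= 32)))
  # decline reaches decline_fraction x peak at the last day
  expect_equal(a$rate[a$day == 76], 0.5 * 70.4, tolerance = 1e-12)
})

test_that("activity profile is deterministic given a seed and validates its spec", {
  spec <- activity_profile_spec(noise_cv = 0.2)
  a1 <- generate_activity_profile(spec, seed = 99)
  a2 <- generate_activity_profile(spec, seed = 99)
  expect_identical(a1, a2)
  a3 <- generate_activity_profile(spec, seed = 100)
  expect_false(identical(a1$rate, a3$rate))

  expect_error(activity_profile_spec(baseline_rate = -1), "baseline_rate")
  expect_error(activity_profile_spec(rise_day = 60, decline_day = 30),
               "rise_day")
  expect_error(activity_profile_spec(noise_cv = -0.1), "noise_cv")
  expect_error(activity_profile_spec(days = c(13, 13, 20)), "days")
})

test_that("synthetic plates are reproducible and reject bad dilutions", {
  p1 <- generate_plate(10, noise_sd = 5, seed = 3)
  p2 <- generate_plate(10, noise_sd = 5, seed = 3)
  expect_identical(p1$kinetics, p2$kinetics)
  expect_error(generate_plate(10, dilution = 0), "dilution")
  expect_error(generate_plate(10, dilution = 1.5), "dilution")
  # noiseless blank wells are perfectly flat
  blanks <- p1 <- generate_plate(10, noise_sd = 0)$kinetics
  blanks <- blanks[blanks$role == "blank", ]
  expect_true(all(tapply(blanks$fluorescence, blanks$well_id,
                         function(f) diff(range(f))) == 0))
})

test_that("community counts close to the drawn depths and echo the truth", {
  act <- generate_activity_profile(activity_profile_spec(noise_cv = 0),
                                   reactor = "R2", seed = 1)
  spec <- community_sim_spec(n_asvs = 80, n_responders = 5,
                             depth_mean = 20000, depth_sd = 3000)
  com <- generate_community(spec, act, seed = 5)
  expect_equal(unname(rowSums(com$counts)), com$truth$depths)
  expect_true(all(unlist(com$truth$responders) %in% colnames(com$counts)))
  expect_equal(nrow(com$metadata), nrow(com$counts))

  com2 <- generate_community(spec, act, seed = 5)
  expect_identical(com$counts, com2$counts)

  # no responders -> empty truth, a valid null experiment
  spec0 <- community_sim_spec(n_asvs = 40, n_responders = 0,
                              depth_mean = 15000, depth_sd = 0)
  com0 <- generate_community(spec0, act, seed = 2)
  expect_length(unlist(com0$truth$responders), 0)

  short <- act[1:3, ]
  expect_error(generate_community(spec, short), "4 time points")
})

test_that("planted responder log-proportions reproduce the activity z-scores in the noiseless limit", {
  act <- generate_activity_profile(activity_profile_spec(noise_cv = 0),
                                   reactor = "R1", seed = 1)
  spec <- community_sim_spec(n_asvs = 50, n_responders = 3,
                             responder_tracking = 1)
  com <- generate_community(spec, act, seed = 8)
  z_act <- zscore(act$rate)
  for (id in com$truth$responders$cellulase) {
    z_logp <- zscore(log(com$truth$expected_proportions[, id]))
    expect_equal(z_logp, z_act, tolerance = 1e-9)
  }
})

test_that("realized responder mean relative abundances stay in the specified range", {
  act <- generate_activity_profile(activity_profile_spec(noise_cv = 0.1),
                                   reactor = "R1", seed = 4)
  spec <- community_sim_spec(n_asvs = 200, n_responders = 5)
  rr <- spec$responder_rel_abundance_range
  for (s in 1:5) {
    com <- generate_community(spec, act, seed = 100 + s)
    rel <- to_relative(com$counts)
    means <- colMeans(rel[, unlist(com$truth$responders), drop = FALSE])
    expect_true(all(means >= rr[1] & means <= rr[2]),
                info = sprintf("seed %d: range %.2g-%.2g", s,
                               min(means), max(means)))
  }
})
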