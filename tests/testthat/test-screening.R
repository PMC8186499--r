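test_that("zscore standardizes with the sample sd and rejects constants", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(zscore(rep(4, 5)), "constant")
  expect_error(zscore(3), "at least 2")
  set.seed(1)
  z <- zscore(rnorm(20, 10, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("day alignment is injective, greedy and tolerance-bounded", {
  out <- align_days(c(13, 20, 27), c(13, 21, 27))
  expect_equal(out$activity_day, c(13, 20, 27))
  expect_equal(out$sample_day, c(13, 21, 27))

  # activity day too far from any sample day is dropped and logged
  expect_message(out <- align_days(c(13, 20, 40), c(13, 21)), "40")
  expect_equal(attr(out, "dropped"), 40)
  expect_equal(nrow(out), 2)

  ident <- align_days(c(5, 10, 15), c(5, 10, 15))
  expect_equal(ident$gap, rep(0, 3))

  # ties break toward the earlier sample day
  tie <- align_days(10, c(8, 12))
  expect_equal(tie$sample_day, 8)
})

test_that("KS statistic and exact p match frozen enumeration values", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  sep <- ks_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic, 1)
  expect_equal(sep$p_value, 0.1) # 2 of the 20 label assignments reach D = 1
  expect_identical(sep$method, "exact")

  expect_error(ks_two_sample(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("exact KS equals the enumeration oracle on randomized small samples", {
  set.seed(11)
  for (trial in 1:150) {
    m <- sample(3:6, 1)
    n <- sample(3:6, 1)
    if (trial %% 2 == 0) { # tied integer draws
      a <- sample(1:4, m, replace = TRUE)
      b <- sample(1:4, n, replace = TRUE)
    } else {
      a <- rnorm(m)
      b <- rnorm(n)
    }
    got <- ks_two_sample(a, b)
    want <- oracle_ks(a, b)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  }
})

test_that("exact KS agrees with stats::ks.test on tie-free data", {
  set.seed(12)
  for (trial in 1:25) {
    a <- rnorm(sample(5:10, 1))
    b <- rnorm(sample(5:10, 1), mean = runif(1, -1, 1))
    got <- ks_two_sample(a, b)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = TRUE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("KS screening retains self-similar ASVs and is order-blind", {
  act <- c(4, 4.5, 5, 9, 20, 45, 70, 60, 50, 40, 35)
  z_act <- zscore(act)
  rel <- cbind(
    self = act, # identical trajectory (screen z-scores internally)
    noisy = c(30, 31, 29, 33, 35, 38, 36, 34, 37, 39, 32),
    rare = c(1e-5, 0, 0, 2e-5, 0, 0, 1e-5, 0, 0, 0, 0))
  out <- ks_screen(rel, z_act, alpha = 0.05, min_prevalence = 4)
  self_row <- out[out$asv_id == "self", ]
  expect_true(self_row$retained)
  expect_equal(self_row$ks_D, 0)
  # sparse ASV fails the prevalence pre-filter
  expect_false("rare" %in% out$asv_id)
  expect_equal(attr(out, "n_screened"), 2)

  # the test compares value distributions, not orderings: any permutation of
  # a series gives the identical statistic and p-value
  set.seed(13)
  for (i in 1:5) {
    x <- rnorm(9)
    y <- rnorm(7)
    expect_identical(ks_two_sample(sample(x), y), ks_two_sample(x, y))
    expect_identical(ks_two_sample(rev(x), rev(y)), ks_two_sample(x, y))
  }
})

test_that("ranking selects perfect responders and reduces to squared correlation", {
  set.seed(14)
  act <- generate_activity_profile(activity_profile_spec(noise_cv = 0),
                                   seed = 1)
  z_act <- zscore(act$rate)
  n_days <- length(z_act)
  bg <- matrix(abs(rnorm(n_days * 50, 10, 2)), n_days, 50)
  planted <- outer(exp(z_act), c(5, 2, 1))
  rel <- cbind(planted, bg)
  colnames(rel) <- c(paste0("RESP_", 1:3), sprintf("BG_%02d", 1:50))
  rel <- rel / rowSums(rel)
  screened <- ks_screen(rel, z_act, alpha = 0.01)
  ranked <- rank_candidates(screened, rel, z_act, n_top = 3)
  expect_setequal(ranked$asv_id, paste0("RESP_", 1:3))

  ranked_all <- rank_candidates(screened, rel, z_act, n_top = 25)
  expect_equal(nrow(ranked_all), 25)
  for (i in seq_len(nrow(ranked_all))) {
    r <- cor(zscore(rel[, ranked_all$asv_id[i]]), z_act)
    expect_equal(ranked_all$r_squared[i], r^2, tolerance = 1e-12)
    expect_equal(ranked_all$slope[i], r, tolerance = 1e-12)
  }
  expect_true(all(diff(ranked_all$r_squared) <= 1e-12))
})

test_that("screening is invariant to count scaling and activity units", {
  act <- generate_activity_profile(activity_profile_spec(noise_cv = 0.05),
                                   reactor = "R1", seed = 3)
  com <- generate_community(
    community_sim_spec(n_asvs = 120, n_responders = 5,
                       depth_mean = 30000, depth_sd = 0),
    act, seed = 4)
  base <- suppressMessages(
    screen(com$counts, com$taxonomy, com$metadata, act, "R1", "cellulase"))

  doubled <- com$counts * 2L
  out2 <- suppressMessages(
    screen(doubled, com$taxonomy, com$metadata, act, "R1", "cellulase"))
  expect_equal(as.data.frame(base), as.data.frame(out2))

  # affine activity rescaling is absorbed by the z-score
  act_f <- act
  act_f$rate <- act_f$rate * 3.78 + 11
  out3 <- suppressMessages(
    screen(com$counts, com$taxonomy, com$metadata, act_f, "R1", "cellulase"))
  expect_equal(base$asv_id, out3$asv_id)
  expect_equal(base$r_squared, out3$r_squared, tolerance = 1e-9)
})

test_that("a null community ranks like shuffled-activity reruns", {
  act <- generate_activity_profile(activity_profile_spec(noise_cv = 0.1),
                                   reactor = "R1", seed = 5)
  com <- generate_community(
    community_sim_spec(n_asvs = 150, n_responders = 0,
                       depth_mean = 30000, depth_sd = 0),
    act, seed = 6)
  obs <- suppressMessages(
    screen(com$counts, com$taxonomy, com$metadata, act, "R1", "cellulase"))
  set.seed(7)
  null_means <- replicate(15, {
    sh <- act
    sh$rate <- sample(sh$rate)
    cand <- suppressMessages(
      screen(com$counts, com$taxonomy, com$metadata, sh, "R1", "cellulase"))
    mean(cand$r_squared)
  })
  # observed top-25 R2 level sits inside the shuffled-null spread
  expect_gte(mean(obs$r_squared), min(null_means) - 0.1)
  expect_lte(mean(obs$r_squared), max(null_means) + 0.1)
})

test_that("empty retention produces an empty ranking with a warning", {
  screened <- data.frame(asv_id = "a", ks_D = 1, ks_p = 0.001,
                         retained = FALSE, prevalence = 5)
  attr(screened, "n_screened") <- 1L
  expect_warning(out <- rank_candidates(screened, NULL, NULL), "no ASVs")
  expect_equal(nrow(out), 0)
})
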