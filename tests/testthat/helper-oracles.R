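# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementations.

# Brute-force two-sample KS: D from the ECDFs, exact p by enumerating every
# assignment of m labels to the pooled values with utils::combn.
oracle_ks <- function(a, b) {
  m <- length(a)
  n <- length(b)
  pooled <- c(a, b)
  dstat <- function(x, y) {
    pts <- sort(unique(c(x, y)))
    fx <- vapply(pts, function(v) mean(x <= v), numeric(1))
    fy <- vapply(pts, function(v) mean(y <= v), numeric(1))
    max(abs(fx - fy))
  }
  d_obs <- dstat(a, b)
  idx <- utils::combn(m + n, m)
  d_all <- apply(idx, 2, function(sel) dstat(pooled[sel], pooled[-sel]))
  list(statistic = d_obs, p_value = mean(d_all >= d_obs - 1e-12))
}

# RDA constrained fraction by explicit per-species regression with lm().
oracle_rda_r2 <- function(x, constraint, transform = "hellinger") {
  y <- if (transform == "hellinger") {
    sqrt(sweep(x, 1, rowSums(x), "/"))
  } else x
  ss_fit <- 0
  ss_tot <- 0
  for (j in seq_len(ncol(y))) {
    fit <- stats::lm(y[, j] ~ constraint)
    ss_fit <- ss_fit + sum((stats::fitted(fit) - mean(y[, j]))^2)
    ss_tot <- ss_tot + sum((y[, j] - mean(y[, j]))^2)
  }
  ss_fit / ss_tot
}

# Chi-square / N total inertia of a contingency-like table.
oracle_ca_inertia <- function(x) {
  n <- sum(x)
  e <- outer(rowSums(x), colSums(x)) / n
  sum((x - e)^2 / e) / n
}

# Chao1 from explicitly tallied frequency-of-frequencies.
oracle_chao1 <- function(counts) {
  tab <- table(counts[counts > 0])
  f1 <- if ("1" %in% names(tab)) as.numeric(tab[["1"]]) else 0
  f2 <- if ("2" %in% names(tab)) as.numeric(tab[["2"]]) else 0
  sum(counts > 0) + f1 * (f1 - 1) / (2 * (f2 + 1))
}
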