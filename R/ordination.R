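# Ordination: correspondence analysis (CA) of the chi-square residual
# matrix, activity-constrained redundancy analysis (RDA) with a permutation
# test, and Pearson correlation helpers for day-windowed series.

#' Correspondence analysis
#'
#' Eigen-decomposes the standardized chi-square residual matrix
#' `(P - r c') / sqrt(r c')` of the relative frequency table `P = X / N` by
#' singular value decomposition. The total inertia (sum of eigenvalues)
#' equals the table's chi-square statistic divided by its grand total.
#' Axis signs are canonicalized so the first nonzero feature loading on each
#' axis is positive.
#'
#' @param x non-negative matrix (samples x features) with no all-zero rows
#'   or columns.
#' @return list of class `"ordination_result"` with `method = "CA"`,
#'   `sample_scores` and `feature_scores` (principal coordinates),
#'   `eigenvalues` (non-increasing) and `total_inertia`. Degenerate tables
#'   yield fewer axes.
#' @export
correspondence_analysis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0) || any(!is.finite(x))) stopf("x must be finite, non-negative")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0))
    stopf("x must have no all-zero rows or columns")
  n <- sum(x)
  p <- x / n
  r <- rowSums(p)
  c <- colSums(p)
  s <- (p - outer(r, c)) / sqrt(outer(r, c))
  dec <- svd(s)
  tol <- max(dim(x)) * max(dec$d, 0) * .Machine$double.eps * 100
  keep <- which(dec$d > max(tol, 1e-12))
  eig <- dec$d[keep]^2
  if (!length(keep)) {
    return(structure(list(method = "CA",
                          sample_scores = matrix(0, nrow(x), 0,
                                                 dimnames = list(rownames(x), NULL)),
                          feature_scores = matrix(0, ncol(x), 0,
                                                  dimnames = list(colnames(x), NULL)),
                          eigenvalues = numeric(0), total_inertia = 0),
                     class = "ordination_result"))
  }
  u <- dec$u[, keep, drop = FALSE]
  v <- dec$v[, keep, drop = FALSE]
  # canonicalize: first nonzero feature loading positive per axis
  for (j in seq_along(keep)) {
    nz <- which(abs(v[, j]) > 1e-12)
    if (length(nz) && v[nz[1], j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  d <- dec$d[keep]
  sample_scores <- sweep(u, 1, sqrt(r), "/") %*% diag(d, length(d))
  feature_scores <- sweep(v, 1, sqrt(c), "/") %*% diag(d, length(d))
  ax <- paste0("CA", seq_along(keep))
  dimnames(sample_scores) <- list(rownames(x), ax)
  dimnames(feature_scores) <- list(colnames(x), ax)
  structure(list(method = "CA", sample_scores = sample_scores,
                 feature_scores = feature_scores, eigenvalues = eig,
                 total_inertia = sum(eig)),
            class = "ordination_result")
}

#' Hellinger transformation
#'
#' Square root of row-wise relative abundances; variance-stabilizes count
#' data for linear ordination.
#'
#' @param x samples x features non-negative matrix with positive row sums.
#' @return transformed matrix.
#' @export
hellinger <- function(x) {
  x <- as.matrix(x)
  totals <- rowSums(x)
  if (any(totals <= 0)) stopf("rows must have positive sums")
  sqrt(sweep(x, 1, totals, "/"))
}

#' Redundancy analysis constrained by a single activity variable
#'
#' Centers the (optionally Hellinger-transformed) species matrix, fits every
#' species by least squares on the centered constraint, and reports the
#' constrained fraction of variance `R^2 = var(fitted) / var(total)` together
#' with a permutation p-value: constraint values are permuted across samples
#' and `p = (1 + #\{R^2_perm >= R^2_obs\}) / (1 + n_permutations)`, so the
#' smallest attainable p with 999 permutations is 0.001.
#'
#' @param x samples x species abundance matrix.
#' @param constraint numeric vector, one value per sample, non-constant.
#' @param n_permutations number of constraint permutations (default 999).
#' @param transform `"hellinger"` (default) or `"none"`.
#' @param seed integer seed for the permutations.
#' @return list of class `"ordination_result"` with `method = "RDA"`,
#'   `sample_scores` (constrained axis RDA1 plus residual PC axes),
#'   `feature_scores`, `eig_constrained`, `eig_residual`,
#'   `constrained_fraction`, `adjusted_r_squared`, `permutation_p`,
#'   `n_permutations`, `seed`.
#' @export
rda <- function(x, constraint, n_permutations = 999,
                transform = c("hellinger", "none"), seed = NULL) {
  transform <- match.arg(transform)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stopf("rda needs at least 3 samples")
  if (length(constraint) != n)
    stopf("constraint length (%d) must match sample count (%d)",
          length(constraint), n)
  if (stats::sd(constraint) == 0)
    stopf("constraint is constant: no variance to constrain on")
  y <- if (transform == "hellinger") hellinger(x) else x
  yc <- scale(y, center = TRUE, scale = FALSE)
  r2_for <- function(con) {
    xc <- con - mean(con)
    b <- crossprod(yc, xc) / sum(xc^2) # per-species OLS slopes
    fitted <- xc %*% t(b)
    sum(fitted^2) / sum(yc^2)
  }
  xc <- constraint - mean(constraint)
  b <- crossprod(yc, xc)[, 1] / sum(xc^2)
  fitted <- xc %*% t(b)
  ss_tot <- sum(yc^2)
  ss_fit <- sum(fitted^2)
  r2 <- ss_fit / ss_tot
  resid <- yc - fitted

  perm_p <- NA_real_
  if (n_permutations > 0) {
    perm_p <- with_seed(seed, {
      hits <- 0L
      for (i in seq_len(n_permutations)) {
        if (r2_for(sample(constraint)) >= r2) hits <- hits + 1L
      }
      (1 + hits) / (1 + n_permutations)
    })
  }

  # constrained axis from the rank-1 fitted matrix; residual axes by PCA
  rda1_feature <- b / sqrt(sum(b^2))
  if (rda1_feature[which(abs(rda1_feature) > 1e-12)[1]] < 0)
    rda1_feature <- -rda1_feature
  rda1_sample <- fitted %*% rda1_feature
  dec <- svd(resid)
  keep <- which(dec$d > max(dec$d[1], 1) * 1e-10)
  n_res <- min(length(keep), 2L)
  res_scores <- dec$u[, seq_len(n_res), drop = FALSE] %*%
    diag(dec$d[seq_len(n_res)], n_res)
  res_feat <- dec$v[, seq_len(n_res), drop = FALSE]
  for (j in seq_len(n_res)) {
    nz <- which(abs(res_feat[, j]) > 1e-12)
    if (length(nz) && res_feat[nz[1], j] < 0) {
      res_feat[, j] <- -res_feat[, j]
      res_scores[, j] <- -res_scores[, j]
    }
  }
  sample_scores <- cbind(RDA1 = rda1_sample[, 1], res_scores)
  feature_scores <- cbind(RDA1 = rda1_feature, res_feat)
  colnames(sample_scores) <- colnames(feature_scores) <-
    c("RDA1", paste0("PC", seq_len(n_res), recycle0 = TRUE))
  rownames(sample_scores) <- rownames(x)
  rownames(feature_scores) <- colnames(x)
  q <- 1 # one constraint
  adj <- 1 - (1 - r2) * (n - 1) / (n - q - 1)
  structure(list(method = "RDA", sample_scores = sample_scores,
                 feature_scores = feature_scores,
                 eig_constrained = ss_fit / (n - 1),
                 eig_residual = dec$d[seq_len(n_res)]^2 / (n - 1),
                 total_inertia = ss_tot / (n - 1),
                 constrained_fraction = r2, adjusted_r_squared = adj,
                 permutation_p = perm_p, n_permutations = n_permutations,
                 seed = seed, transform = transform),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("%s ordination: %d samples, %d features\n", x$method,
              nrow(x$sample_scores), nrow(x$feature_scores)))
  if (x$method == "CA") {
    cat(sprintf("  total inertia: %.6g; first eigenvalues: %s\n",
                x$total_inertia,
                paste(signif(utils::head(x$eigenvalues, 4), 4), collapse = ", ")))
  } else {
    cat(sprintf("  constrained R2 = %.4f (adjusted %.4f), permutation p = %s (%d permutations)\n",
                x$constrained_fraction, x$adjusted_r_squared,
                format(x$permutation_p), x$n_permutations))
  }
  invisible(x)
}

#' Pearson correlation (with a day-window helper)
#'
#' `pearson()` is the standard product-moment coefficient with the
#' preconditions used throughout the pipeline (at least 3 paired points,
#' both series non-constant). `pearson_window()` restricts paired series to
#' a day range before correlating, for e.g. comparing methane production
#' with hydrolase activity during early feeding versus late feeding windows.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the correlation coefficient.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stopf("need at least 3 paired points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("both series must have nonzero variance")
  stats::cor(x, y)
}

#' @rdname pearson
#' @param days day stamps for the paired observations.
#' @param day_min,day_max inclusive day-window bounds.
#' @export
pearson_window <- function(days, x, y, day_min = -Inf, day_max = Inf) {
  sel <- days >= day_min & days <= day_max
  pearson(x[sel], y[sel])
}

#' Write ordination scores and summary as TSV
#'
#' @param x an `ordination_result`.
#' @param scores_path,summary_path output paths (NULL to skip either).
#' @return invisible list of written paths.
#' @export
write_ordination <- function(x, scores_path = NULL, summary_path = NULL) {
  written <- list()
  if (!is.null(scores_path)) {
    df <- data.frame(sample_id = rownames(x$sample_scores),
                     x$sample_scores, check.names = FALSE)
    write_tsv(df, scores_path)
    written$scores <- scores_path
  }
  if (!is.null(summary_path)) {
    if (x$method == "RDA") {
      df <- data.frame(method = "RDA", r_squared = x$constrained_fraction,
                       adjusted_r_squared = x$adjusted_r_squared,
                       p = x$permutation_p, n_permutations = x$n_permutations,
                       seed = if (is.null(x$seed)) NA else x$seed)
    } else {
      df <- data.frame(method = "CA", total_inertia = x$total_inertia,
                       n_axes = length(x$eigenvalues))
    }
    write_tsv(df, summary_path)
    written$summary <- summary_path
  }
  invisible(written)
}
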