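# Candidate screening: z-score normalization, day alignment, exact
# two-sample Kolmogorov-Smirnov selection, and regression ranking of ASVs
# against enzyme activity trajectories.

#' z-score normalization
#'
#' `(x - mean(x)) / sd(x)` with the sample (n-1 denominator) standard
#' deviation. Constant series cannot be normalized and raise an error;
#' callers must pre-exclude constant ASVs.
#'
#' @param x numeric vector, length >= 2.
#' @return the normalized vector (mean 0, sample sd 1).
#' @examples
#' zscore(c(1, 2, 3)) # -1 0 1
#' @export
zscore <- function(x) {
  if (length(x) < 2L) stopf("zscore needs at least 2 values")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stopf("zscore undefined for a constant series")
  (x - mean(x)) / s
}

#' Pair activity days with sampling days
#'
#' Weekly enzyme assays and weekly DNA sampling do not always fall on the
#' same calendar day; each activity day is paired with the nearest sample
#' day within `tolerance_days`. Pairing is injective and greedy by smallest
#' gap, ties resolved toward the earlier sample day; unpaired activity days
#' are dropped and reported in attribute `"dropped"`.
#'
#' @param activity_days,sample_days numeric day vectors.
#' @param tolerance_days maximum |gap| for a pairing (default 3).
#' @return data.frame (`activity_day`, `sample_day`, `gap`) ordered by
#'   activity day.
#' @export
align_days <- function(activity_days, sample_days, tolerance_days = 3) {
  activity_days <- sort(unique(activity_days))
  sample_days <- sort(unique(sample_days))
  cand <- expand.grid(activity_day = activity_days, sample_day = sample_days)
  cand$gap <- abs(cand$activity_day - cand$sample_day)
  cand <- cand[cand$gap <= tolerance_days, , drop = FALSE]
  cand <- cand[order(cand$gap, cand$sample_day), , drop = FALSE]
  used_a <- used_s <- numeric(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$activity_day[i] %in% used_a || cand$sample_day[i] %in% used_s)
      next
    keep[i] <- TRUE
    used_a <- c(used_a, cand$activity_day[i])
    used_s <- c(used_s, cand$sample_day[i])
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$activity_day), , drop = FALSE]
  rownames(out) <- NULL
  dropped <- setdiff(activity_days, out$activity_day)
  if (length(dropped))
    message(sprintf("align_days: dropped activity day(s) without a sample within %g d: %s",
                    tolerance_days, paste(dropped, collapse = ", ")))
  attr(out, "dropped") <- dropped
  out
}

#' Two-sample Kolmogorov-Smirnov test with exact small-sample p
#'
#' `D` is the supremum distance between the two empirical distribution
#' functions, evaluated at every distinct pooled value (a tie-aware
#' convention: with ties both one-sided deviations are assessed at each
#' pooled point). For `m + n <= 16` the p-value is exact, computed by
#' counting label assignments of the pooled multiset whose statistic reaches
#' the observed `D` (a block dynamic program over tied value groups, exact
#' in integer arithmetic even with ties); for larger samples the asymptotic
#' Kolmogorov tail is used. The default cutoff of 26 keeps the exact test in
#' force at the weekly time-series sizes this screen is built for (10-11
#' points per series), where the asymptotic tail is a poor approximation.
#'
#' @param a,b numeric vectors, each of length >= 3.
#' @param exact_max_total largest `m + n` for which the exact p is computed
#'   (default 26).
#' @return list with `statistic` (D), `p_value`, `method` ("exact" or
#'   "asymptotic"), `m`, `n`.
#' @examples
#' ks_two_sample(c(1, 2, 3), c(4, 5, 6)) # D = 1, exact p = 0.1
#' @export
ks_two_sample <- function(a, b, exact_max_total = 26) {
  if (length(a) < 3L || length(b) < 3L)
    stopf("both samples need at least 3 values")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stopf("samples must be finite")
  m <- length(a)
  n <- length(b)
  pooled <- sort(unique(c(a, b)))
  fa <- vapply(pooled, function(v) sum(a <= v), numeric(1)) / m
  fb <- vapply(pooled, function(v) sum(b <= v), numeric(1)) / n
  d <- max(abs(fa - fb))
  if (m + n <= exact_max_total) {
    p <- ks_exact_p(a, b)
    method <- "exact"
  } else {
    lambda <- sqrt(m * n / (m + n)) * d
    p <- ks_kolmogorov_tail(lambda)
    method <- "asymptotic"
  }
  list(statistic = d, p_value = p, method = method, m = m, n = n)
}

# Exact null P(D >= d_obs) under random labelling of the pooled multiset.
# Works on the integer statistic |A_j * n - B_j * m| evaluated at tied-block
# boundaries, so ties and floating-point comparison are handled exactly.
#' @keywords internal
#' @noRd
ks_exact_p <- function(a, b) {
  m <- length(a)
  n <- length(b)
  pooled <- sort(unique(c(a, b)))
  ca <- vapply(pooled, function(v) sum(a <= v), numeric(1))
  cb <- vapply(pooled, function(v) sum(b <= v), numeric(1))
  d_int <- max(abs(ca * n - cb * m)) # observed integer statistic
  s <- vapply(pooled, function(v) sum(a == v) + sum(b == v), numeric(1))
  # DP over blocks: ways[A+1] = weighted number of assignments with A of the
  # first blocks' members labelled 'a' and all boundary stats < d_int
  ways <- c(1, rep(0, m))
  cum <- 0
  for (j in seq_along(s)) {
    cum <- cum + s[j]
    new <- rep(0, m + 1)
    for (a_prev in 0:m) {
      w <- ways[a_prev + 1]
      if (w == 0) next
      take_max <- min(s[j], m - a_prev)
      for (take in 0:take_max) {
        a_cum <- a_prev + take
        b_cum <- cum - a_cum
        if (b_cum > n) next
        if (abs(a_cum * n - b_cum * m) >= d_int) next
        new[a_cum + 1] <- new[a_cum + 1] + w * choose(s[j], take)
      }
    }
    ways <- new
  }
  below <- ways[m + 1]
  1 - below / choose(m + n, m)
}

# Asymptotic Kolmogorov survival function Q(lambda).
#' @keywords internal
#' @noRd
ks_kolmogorov_tail <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' KS screen: select ASVs distributed like the activity series
#'
#' Applies the two-sample Kolmogorov-Smirnov test to z-score normalized
#' relative abundances against the z-scored activity values at the aligned
#' days. "Similar distribution" is operationalized as non-rejection:
#' an ASV is retained iff the KS p-value exceeds `alpha`. ASVs observed in
#' fewer than `min_prevalence` samples, or constant across samples, are
#' excluded before testing (their z-scores are degenerate). Note the KS test
#' compares value distributions and is blind to temporal ordering; ordering
#' is assessed by the subsequent regression ranking.
#'
#' @param rel samples x ASVs relative abundance matrix, rows in aligned day
#'   order.
#' @param z_activity z-scored activity values for the same aligned days.
#' @param alpha retention threshold (retained iff p > alpha; default 0.05).
#' @param min_prevalence minimum number of nonzero samples (default 4).
#' @return data.frame (`asv_id`, `ks_D`, `ks_p`, `retained`, `prevalence`)
#'   with attributes `n_screened` (ASVs tested) and `n_retained`.
#' @export
ks_screen <- function(rel, z_activity, alpha = 0.05, min_prevalence = 4) {
  if (nrow(rel) != length(z_activity))
    stopf("rel rows (%d) must match z_activity length (%d)",
          nrow(rel), length(z_activity))
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  prevalence <- colSums(rel > 0)
  variable <- apply(rel, 2, function(v) stats::sd(v) > 0)
  eligible <- prevalence >= min_prevalence & variable
  ids <- colnames(rel)[eligible]
  rows <- lapply(ids, function(id) {
    z_ab <- zscore(rel[, id])
    ks <- ks_two_sample(z_ab, z_activity)
    data.frame(asv_id = id, ks_D = ks$statistic, ks_p = ks$p_value,
               retained = ks$p_value > alpha,
               prevalence = prevalence[[id]],
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(asv_id = character(0), ks_D = numeric(0), ks_p = numeric(0),
               retained = logical(0), prevalence = numeric(0))
  rownames(out) <- NULL
  attr(out, "n_screened") <- length(ids)
  attr(out, "n_retained") <- sum(out$retained)
  out
}

#' Rank retained ASVs by regression fit to the activity series
#'
#' For each retained ASV, ordinary least squares of the z-scored abundance
#' on the z-scored activity; since both variables are standardized, the
#' slope equals Pearson's r and the ranking metric is `R^2 = r^2`
#' (descending). Ties break by higher mean relative abundance, then
#' lexicographic ASV id, so candidate tables are byte-reproducible. An
#' alternative reading of the ranking regression — the abundance/activity
#' ratio regressed on time ("ratio_trend") — is available via `method`.
#'
#' @param screened the [ks_screen()] result (only `retained` rows are
#'   ranked).
#' @param rel aligned relative abundance matrix (as given to `ks_screen`).
#' @param z_activity z-scored activity values.
#' @param taxonomy optional taxonomy data.frame for candidate labels.
#' @param n_top number of candidates to emit (default 25).
#' @param method `"z_on_z"` (default) or `"ratio_trend"`.
#' @param days day stamps, required for `method = "ratio_trend"`.
#' @param activity raw activity values, required for `"ratio_trend"`.
#' @return data.frame of class `"candidate_ranking"` with columns `rank`,
#'   `asv_id`, `taxonomy`, `ks_D`, `ks_p`, `r_squared`, `slope`,
#'   `mean_rel_abundance`; attributes `n_screened`, `n_retained`.
#' @export
rank_candidates <- function(screened, rel, z_activity, taxonomy = NULL,
                            n_top = 25, method = c("z_on_z", "ratio_trend"),
                            days = NULL, activity = NULL) {
  method <- match.arg(method)
  retained <- screened[screened$retained, , drop = FALSE]
  if (!nrow(retained)) {
    warnf("no ASVs retained by the KS screen: empty ranking")
    out <- data.frame(rank = integer(0), asv_id = character(0),
                      taxonomy = character(0), ks_D = numeric(0),
                      ks_p = numeric(0), r_squared = numeric(0),
                      slope = numeric(0), mean_rel_abundance = numeric(0))
    class(out) <- c("candidate_ranking", "data.frame")
    attr(out, "n_screened") <- attr(screened, "n_screened")
    attr(out, "n_retained") <- 0L
    return(out)
  }
  stats_list <- lapply(seq_len(nrow(retained)), function(i) {
    id <- retained$asv_id[i]
    v <- rel[, id]
    if (method == "z_on_z") {
      r <- stats::cor(zscore(v), z_activity)
      c(r_squared = r^2, slope = r)
    } else {
      if (is.null(days) || is.null(activity))
        stopf("ratio_trend ranking needs days and raw activity values")
      ratio <- v / activity
      fit <- ols_fit(days, ratio)
      c(r_squared = fit$r_squared, slope = fit$slope)
    }
  })
  st <- do.call(rbind, stats_list)
  out <- data.frame(asv_id = retained$asv_id, ks_D = retained$ks_D,
                    ks_p = retained$ks_p,
                    r_squared = st[, "r_squared"], slope = st[, "slope"],
                    mean_rel_abundance = colMeans(rel[, retained$asv_id,
                                                      drop = FALSE]),
                    stringsAsFactors = FALSE)
  ord <- order(-out$r_squared, -out$mean_rel_abundance, out$asv_id)
  out <- out[ord, , drop = FALSE]
  out <- utils::head(out, n_top)
  out$rank <- seq_len(nrow(out))
  lab <- if (!is.null(taxonomy)) {
    labels <- best_taxonomy_label(taxonomy)
    unname(labels[out$asv_id])
  } else NA_character_
  lab[is.na(lab)] <- "Unclassified"
  out$taxonomy <- lab
  out <- out[, c("rank", "asv_id", "taxonomy", "ks_D", "ks_p",
                 "r_squared", "slope", "mean_rel_abundance")]
  rownames(out) <- NULL
  class(out) <- c("candidate_ranking", "data.frame")
  attr(out, "n_screened") <- attr(screened, "n_screened")
  attr(out, "n_retained") <- nrow(retained)
  out
}

#' Screen one reactor-enzyme combination end to end
#'
#' Composition of the full candidate-identification procedure for one
#' reactor and one enzyme: depth-filter samples, convert to relative
#' abundance, align activity days with sampling days, z-score both series,
#' select ASVs by KS similarity, and rank the retained set by regression
#' fit. Deterministic given its inputs (no randomness involved).
#'
#' @param counts samples x ASVs count matrix (all reactors).
#' @param taxonomy taxonomy data.frame (or NULL).
#' @param metadata sample metadata (`sample_id`, `reactor`, `day`,
#'   `replicate`).
#' @param activity activity series data.frame covering the requested
#'   reactor/enzyme.
#' @param reactor,enzyme selection.
#' @param min_reads depth filter threshold (default 10,000).
#' @param ks_alpha KS retention threshold (default 0.05).
#' @param min_prevalence prevalence pre-filter (default 4).
#' @param n_top candidates to report (default 25).
#' @param align_tolerance day-pairing tolerance (default 3).
#' @param replicate which replicate's samples to screen (default 1, the
#'   replicate in which enzyme activities were assayed).
#' @param ranking ranking regression, `"z_on_z"` or `"ratio_trend"`.
#' @return a `candidate_ranking` (see [rank_candidates()]) with attributes
#'   `reactor`, `enzyme`, `days_used`.
#' @export
screen <- function(counts, taxonomy, metadata, activity, reactor, enzyme,
                   min_reads = 10000, ks_alpha = 0.05, min_prevalence = 4,
                   n_top = 25, align_tolerance = 3, replicate = 1,
                   ranking = c("z_on_z", "ratio_trend")) {
  ranking <- match.arg(ranking)
  act <- activity[activity$reactor == reactor & activity$enzyme == enzyme, ,
                  drop = FALSE]
  if (!nrow(act)) stopf("no activity data for %s / %s", reactor, enzyme)
  meta <- metadata[metadata$reactor == reactor &
                     metadata$replicate == replicate, , drop = FALSE]
  if (!nrow(meta)) stopf("no samples for reactor %s (replicate %s)",
                         reactor, replicate)
  counts <- counts[rownames(counts) %in% meta$sample_id, , drop = FALSE]
  counts <- filter_samples(counts, min_reads = min_reads)
  if (!nrow(counts)) stopf("no samples left after depth filtering")
  meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
  pairing <- align_days(act$day, meta$day, tolerance_days = align_tolerance)
  if (nrow(pairing) < 4L)
    stopf("fewer than 4 aligned time points for %s / %s", reactor, enzyme)
  act_use <- act[match(pairing$activity_day, act$day), , drop = FALSE]
  sample_ids <- meta$sample_id[match(pairing$sample_day, meta$day)]
  rel <- to_relative(counts[sample_ids, , drop = FALSE])
  z_act <- zscore(act_use$rate)
  screened <- ks_screen(rel, z_act, alpha = ks_alpha,
                        min_prevalence = min_prevalence)
  res <- rank_candidates(screened, rel, z_act, taxonomy = taxonomy,
                         n_top = n_top, method = ranking,
                         days = pairing$sample_day, activity = act_use$rate)
  attr(res, "reactor") <- reactor
  attr(res, "enzyme") <- enzyme
  attr(res, "days_used") <- pairing$sample_day
  res
}

#' Write a candidate table as TSV
#'
#' Columns mirror the published candidate tables: rank, ASV id, taxonomy
#' label, KS statistic and p, regression R-squared and slope, mean relative
#' abundance.
#'
#' @param x a `candidate_ranking`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(x, path) write_tsv(as.data.frame(x), path)
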