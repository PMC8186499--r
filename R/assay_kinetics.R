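# Fluorometric MUF hydrolase assay: standard curves, initial linear rates,
# blank correction, and per-day activity series.

# 4-methylumbelliferone molar mass is 176.17 g/mol, so 1 umol = 0.17617 mg.
MUF_MG_PER_UMOL <- 0.17617

#' Fit a MUF standard curve
#'
#' Fits fluorescence (arbitrary units, AU) against known MUF concentrations
#' (umol/L) by ordinary least squares and determines the linear range as the
#' widest low-concentration prefix whose fit attains `r2_threshold`. Standards
#' are prepared in the same slurry matrix as the kinetic wells (active or
#' heat-inactivated) so that matrix quenching cancels when the curve is
#' applied.
#'
#' @param standard_conc numeric vector of MUF concentrations (umol/L).
#' @param fluorescence numeric vector of mean fluorescence readings (AU).
#' @param r2_threshold minimum coefficient of determination for the linear
#'   range (default 0.99).
#' @param matrix matrix label, `"active"` or `"heat_inactivated"`.
#' @return An object of class `"muf_standard_curve"`: a list with `slope`
#'   (AU per umol/L), `intercept` (AU), `r_squared`, `linear_range`
#'   (umol/L, length 2), `matrix` and `n_points`.
#' @examples
#' fit_standard_curve(c(0, 1, 2), c(100, 300, 500))
#' @export
fit_standard_curve <- function(standard_conc, fluorescence,
                               r2_threshold = 0.99, matrix = "active") {
  if (length(standard_conc) != length(fluorescence))
    stopf("standard_conc and fluorescence must have equal length")
  ok <- is.finite(standard_conc) & is.finite(fluorescence)
  standard_conc <- standard_conc[ok]
  fluorescence <- fluorescence[ok]
  if (length(unique(standard_conc)) < 3L)
    stopf("need at least 3 distinct standard concentrations")
  ord <- order(standard_conc)
  conc <- standard_conc[ord]
  fl <- fluorescence[ord]
  # widest prefix (from the lowest concentration) meeting the r2 threshold
  idx <- seq_along(conc)
  fit <- NULL
  for (len in rev(idx)) {
    if (len < 3L) break
    if (length(unique(conc[seq_len(len)])) < 3L) next
    cand <- ols_fit(conc[seq_len(len)], fl[seq_len(len)])
    if (cand$r_squared >= r2_threshold) {
      fit <- cand
      fit$upper <- conc[len]
      break
    }
  }
  if (is.null(fit)) {
    fit <- ols_fit(conc, fl)
    fit$upper <- conc[length(conc)]
    warnf("no concentration prefix reached r2 >= %.3f; using full range (r2 = %.4f)",
          r2_threshold, fit$r_squared)
  }
  if (fit$slope <= 0)
    stopf("standard curve slope must be positive (got %.4g)", fit$slope)
  structure(list(slope = fit$slope, intercept = fit$intercept,
                 r_squared = fit$r_squared,
                 linear_range = c(min(conc), fit$upper),
                 matrix = matrix, n_points = fit$n),
            class = "muf_standard_curve")
}

#' @export
print.muf_standard_curve <- function(x, ...) {
  cat(sprintf("MUF standard curve (%s matrix)\n", x$matrix))
  cat(sprintf("  slope: %.4g AU per umol/L, intercept: %.4g AU, r2 = %.4f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  linear range: %.3g-%.3g umol/L (%d points)\n",
              x$linear_range[1], x$linear_range[2], x$n_points))
  invisible(x)
}

#' Estimate the initial linear hydrolysis rate of one kinetic well
#'
#' Product accumulation under substrate-saturated (zero-order) conditions is
#' linear until substrate depletion or product effects slow it down, so the
#' initial rate is taken from the longest window starting at the first
#' reading whose linear fit reaches `r2_threshold` (minimum 4 points; series
#' shorter than 6 points are fitted whole). The fluorescence slope (AU/min)
#' is converted to a MUF release rate of the undiluted slurry:
#' `slope / curve$slope` umol/L/min, times 60 min/h, times 0.17617 mg/umol,
#' divided by the slurry dilution.
#'
#' @param times reading times in minutes, strictly increasing, length >= 3.
#' @param fluorescence fluorescence readings (AU), same length as `times`.
#' @param curve a [fit_standard_curve()] object for the matching matrix.
#' @param dilution slurry dilution as a fraction in (0, 1] (e.g. 0.01 for 1%).
#' @param r2_threshold linearity criterion for the initial window
#'   (default 0.98).
#' @return list with `rate` (mg MUF/L/h, undiluted slurry), `slope_au_min`,
#'   `r_squared`, `window_n` (points used) and `qc_flags` (character).
#' @export
estimate_initial_rate <- function(times, fluorescence, curve, dilution,
                                  r2_threshold = 0.98) {
  if (!inherits(curve, "muf_standard_curve"))
    stopf("curve must be a muf_standard_curve")
  if (length(times) < 3L) stopf("kinetic well needs at least 3 readings")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  if (length(times) != length(fluorescence))
    stopf("times and fluorescence must have equal length")
  if (!all(is.finite(fluorescence))) stopf("fluorescence must be finite")
  if (!is.numeric(dilution) || length(dilution) != 1L ||
      dilution <= 0 || dilution > 1)
    stopf("dilution must be a fraction in (0, 1]")
  n <- length(times)
  flags <- character(0)
  if (n < 6L) {
    fit <- ols_fit(times, fluorescence)
  } else {
    fit <- NULL
    for (len in seq(n, 4L)) {
      cand <- ols_fit(times[seq_len(len)], fluorescence[seq_len(len)])
      if (cand$r_squared >= r2_threshold) {
        fit <- cand
        break
      }
    }
    if (is.null(fit)) {
      fit <- ols_fit(times, fluorescence)
      flags <- c(flags, "nonlinear_kinetics")
    }
  }
  rate <- fit$slope / curve$slope * 60 * MUF_MG_PER_UMOL / dilution
  list(rate = rate, slope_au_min = fit$slope, r_squared = fit$r_squared,
       window_n = fit$n, qc_flags = flags)
}

#' Blank-correct a hydrolysis rate
#'
#' Subtracts the rate measured in the matched heat-inactivated control
#' (non-enzymatic MUF release) and floors the result at zero, since negative
#' enzymatic activities are physically meaningless. A QC flag is raised when
#' the blank exceeds `blank_fraction` of the sample rate.
#'
#' @param sample_rate,blank_rate rates in mg MUF/L/h.
#' @param blank_fraction flagging threshold as a fraction of the sample rate
#'   (default 0.2).
#' @return list with `rate` (net, >= 0) and `qc_flags`.
#' @examples
#' blank_correct(70.4, 3.5)$rate # 66.9
#' @export
blank_correct <- function(sample_rate, blank_rate, blank_fraction = 0.2) {
  flags <- character(0)
  if (sample_rate > 0 && blank_rate > blank_fraction * sample_rate)
    flags <- c(flags, "high_blank")
  net <- max(sample_rate - blank_rate, 0)
  if (net == 0 && blank_rate > sample_rate) flags <- c(flags, "blank_exceeds_sample")
  list(rate = net, qc_flags = flags)
}

#' Average the rates from the two substrate concentrations
#'
#' Each sample is assayed at two substrate concentrations to verify that
#' hydrolysis is substrate-saturated; the reported activity is their
#' arithmetic mean. When the two rates disagree by more than `tolerance`
#' (relative to their mean) the saturation assumption is doubtful and the
#' independence flag is set.
#'
#' @param rate_high,rate_low rates (mg MUF/L/h) at the higher and lower
#'   substrate concentration.
#' @param tolerance relative-discrepancy threshold (default 0.25).
#' @return list with `rate` (mean), `independence_flag` (logical) and `sd`
#'   (standard deviation of the two rates).
#' @export
average_concentrations <- function(rate_high, rate_low, tolerance = 0.25) {
  m <- mean(c(rate_high, rate_low))
  flag <- if (m > 0) abs(rate_high - rate_low) / m > tolerance else FALSE
  list(rate = m, independence_flag = flag, sd = stats::sd(c(rate_high, rate_low)))
}

#' Read long-format plate kinetics
#'
#' Reads a delimited (CSV or TSV, auto-detected) long-format table of
#' plate-reader kinetics with one row per well per reading. Required columns:
#' `well_id`, `role` (sample/blank/standard), `substrate`, `substrate_conc`
#' (mmol/L; NA for standards), `matrix` (active/heat_inactivated),
#' `dilution`, `standard_conc` (umol/L; NA for kinetic wells), `time_min`,
#' `fluorescence`. Optional grouping columns `reactor`, `enzyme`, `day` are
#' carried through.
#'
#' @param path file path.
#' @return a validated data.frame.
#' @export
read_plate_kinetics <- function(path) {
  x <- read_delim_auto(path)
  validate_plate_kinetics(x)
}

#' @keywords internal
#' @noRd
validate_plate_kinetics <- function(x) {
  need <- c("well_id", "role", "substrate", "substrate_conc", "matrix",
            "dilution", "standard_conc", "time_min", "fluorescence")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stopf("plate kinetics table missing column(s): %s", paste(miss, collapse = ", "))
  bad_role <- setdiff(unique(x$role), c("sample", "blank", "standard"))
  if (length(bad_role))
    stopf("unknown well role(s): %s", paste(bad_role, collapse = ", "))
  bad_mat <- setdiff(unique(x$matrix), c("active", "heat_inactivated"))
  if (length(bad_mat))
    stopf("unknown matrix label(s): %s", paste(bad_mat, collapse = ", "))
  if (!all(is.finite(x$fluorescence)))
    stopf("fluorescence contains non-finite values")
  x
}

#' Compute a per-day activity series from plate kinetics
#'
#' Runs the full assay computation for every (reactor, enzyme, day) group in
#' a long-format kinetics table: fits matrix-specific MUF standard curves,
#' averages replicate wells reading-by-reading (default), estimates initial
#' linear rates for active sample wells and heat-inactivated blanks at each
#' substrate concentration, blank-corrects within concentration, and averages
#' the two substrate concentrations. Reported rates are for undiluted slurry
#' in mg MUF/L/h.
#'
#' @param plate long-format kinetics data.frame (see [read_plate_kinetics()]).
#' @param curve_r2 linear-range threshold for standard curves (default 0.99).
#' @param rate_r2 linearity threshold for the initial-rate window
#'   (default 0.98).
#' @param blank_fraction QC threshold for [blank_correct()].
#' @param conc_tolerance independence threshold for [average_concentrations()].
#' @param average_replicates average duplicate wells before rate fitting
#'   (default TRUE); otherwise rates are fitted per well and then averaged.
#' @return an activity series data.frame with columns `reactor`, `enzyme`,
#'   `day`, `rate`, `sd`, `qc_flags` (class `"activity_series"`).
#' @export
compute_activity_series <- function(plate, curve_r2 = 0.99, rate_r2 = 0.98,
                                    blank_fraction = 0.2, conc_tolerance = 0.25,
                                    average_replicates = TRUE) {
  plate <- validate_plate_kinetics(plate)
  for (col in c("reactor", "enzyme", "day")) {
    if (!col %in% names(plate)) plate[[col]] <- if (col == "day") 0 else "NA"
  }
  groups <- unique(plate[, c("reactor", "enzyme", "day")])
  out <- vector("list", nrow(groups))
  for (g in seq_len(nrow(groups))) {
    sub <- plate[plate$reactor == groups$reactor[g] &
                   plate$enzyme == groups$enzyme[g] &
                   plate$day == groups$day[g], , drop = FALSE]
    res <- assay_one_plate(sub, curve_r2, rate_r2, blank_fraction,
                           conc_tolerance, average_replicates)
    out[[g]] <- data.frame(reactor = groups$reactor[g],
                           enzyme = groups$enzyme[g],
                           day = groups$day[g],
                           rate = res$rate, sd = res$sd,
                           qc_flags = paste(res$qc_flags, collapse = ";"),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out <- out[order(out$reactor, out$enzyme, out$day), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("activity_series", "data.frame")
  out
}

# One (reactor, enzyme, day) plate: curves per matrix, rates per
# concentration, blank correction, concentration averaging.
#' @keywords internal
#' @noRd
assay_one_plate <- function(sub, curve_r2, rate_r2, blank_fraction,
                            conc_tolerance, average_replicates) {
  std <- sub[sub$role == "standard", , drop = FALSE]
  if (!nrow(std)) stopf("plate group has no standard wells")
  curves <- lapply(split(std, std$matrix), function(s) {
    per_well <- stats::aggregate(fluorescence ~ well_id + standard_conc,
                                 data = s, FUN = mean)
    fit_standard_curve(per_well$standard_conc, per_well$fluorescence,
                       r2_threshold = curve_r2, matrix = s$matrix[1])
  })
  curve_for <- function(matrix_label) {
    if (!is.null(curves[[matrix_label]])) return(curves[[matrix_label]])
    curves[[1L]] # fall back to the single prepared matrix
  }
  flags <- character(0)

  rate_for <- function(wells) {
    # wells: one role/matrix/substrate_conc group, possibly replicate wells
    curve <- curve_for(wells$matrix[1])
    dil <- wells$dilution[1]
    if (average_replicates) {
      avg <- stats::aggregate(fluorescence ~ time_min, data = wells, FUN = mean)
      avg <- avg[order(avg$time_min), ]
      est <- estimate_initial_rate(avg$time_min, avg$fluorescence, curve, dil,
                                   r2_threshold = rate_r2)
      list(rate = est$rate, qc = est$qc_flags)
    } else {
      ests <- lapply(split(wells, wells$well_id), function(w) {
        w <- w[order(w$time_min), ]
        estimate_initial_rate(w$time_min, w$fluorescence, curve, dil,
                              r2_threshold = rate_r2)
      })
      list(rate = mean(vapply(ests, `[[`, numeric(1), "rate")),
           qc = unique(unlist(lapply(ests, `[[`, "qc_flags"))))
    }
  }

  kin <- sub[sub$role %in% c("sample", "blank"), , drop = FALSE]
  concs <- sort(unique(kin$substrate_conc[kin$role == "sample"]), decreasing = TRUE)
  if (!length(concs)) stopf("plate group has no sample wells")
  net <- numeric(0)
  for (cc in concs) {
    sm <- kin[kin$role == "sample" & kin$substrate_conc == cc, , drop = FALSE]
    bl <- kin[kin$role == "blank" & kin$substrate_conc == cc, , drop = FALSE]
    s_est <- rate_for(sm)
    flags <- c(flags, s_est$qc)
    b_rate <- 0
    if (nrow(bl)) {
      b_est <- rate_for(bl)
      b_rate <- b_est$rate
    }
    corr <- blank_correct(s_est$rate, b_rate, blank_fraction)
    flags <- c(flags, corr$qc_flags)
    net <- c(net, corr$rate)
  }
  if (length(net) >= 2L) {
    avg <- average_concentrations(net[1], net[2], tolerance = conc_tolerance)
    if (avg$independence_flag) flags <- c(flags, "concentration_dependent")
    rate <- avg$rate
    sd <- avg$sd
  } else {
    rate <- net[1]
    sd <- NA_real_
  }
  list(rate = rate, sd = sd, qc_flags = unique(flags))
}

#' Write / read an activity series as TSV
#'
#' @param x an activity series data.frame.
#' @param path file path.
#' @return `path` (write) or the activity series (read).
#' @export
write_activity_series <- function(x, path) write_tsv(x, path)

#' @rdname write_activity_series
#' @export
read_activity_series <- function(path) {
  x <- read_delim_auto(path)
  need <- c("reactor", "enzyme", "day", "rate")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stopf("activity series missing column(s): %s", paste(miss, collapse = ", "))
  if (any(x$rate < 0)) stopf("activity rates must be non-negative")
  if (anyDuplicated(x[, c("reactor", "enzyme", "day")]))
    stopf("duplicate (reactor, enzyme, day) rows in activity series")
  class(x) <- c("activity_series", "data.frame")
  x
}
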