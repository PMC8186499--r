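# End-to-end orchestration: declarative run configuration, staged pipeline
# execution with manifest/logging, and the simulation-recovery harness.

#' Build and validate a pipeline run configuration
#'
#' A run configuration names the input files, the reactor/enzyme
#' combinations to screen, all thresholds, and the output directory. It can
#' also be read from a YAML file with [read_run_config()]. Validation is
#' performed up front so that an invalid configuration fails before any
#' stage runs.
#'
#' @param asv_table,taxonomy,metadata,activity input file paths (`activity`
#'   may instead be a `plate_kinetics` path, from which activities are
#'   computed).
#' @param plate_kinetics optional long-format kinetics file.
#' @param reactors,enzymes character vectors of combinations to screen
#'   (default: all present in the inputs).
#' @param min_reads sample depth filter (default 10000 reads).
#' @param ks_alpha KS retention threshold in (0,1) (default 0.05).
#' @param n_top candidate table size (default 25).
#' @param min_prevalence prevalence pre-filter (default 4).
#' @param align_tolerance day-pairing tolerance in days (default 3).
#' @param rate_r2,curve_r2 linearity thresholds for the assay stage.
#' @param independence_tolerance substrate-concentration discrepancy
#'   threshold (default 0.25).
#' @param n_permutations RDA permutations (default 999).
#' @param transform RDA transform, `"hellinger"` or `"none"`.
#' @param ranking candidate ranking regression (`"z_on_z"` default).
#' @param replicate replicate whose samples are screened (default 1).
#' @param seed integer root seed; required because the RDA stage permutes.
#' @param outdir output directory.
#' @return validated list of class `"run_config"`.
#' @export
run_config <- function(asv_table, taxonomy = NULL, metadata, activity = NULL,
                       plate_kinetics = NULL, reactors = NULL, enzymes = NULL,
                       min_reads = 10000, ks_alpha = 0.05, n_top = 25,
                       min_prevalence = 4, align_tolerance = 3,
                       rate_r2 = 0.98, curve_r2 = 0.99,
                       independence_tolerance = 0.25, n_permutations = 999,
                       transform = "hellinger", ranking = "z_on_z",
                       replicate = 1, seed = 1, outdir = "hydroscreen_out") {
  config <- list(asv_table = asv_table, taxonomy = taxonomy,
                 metadata = metadata, activity = activity,
                 plate_kinetics = plate_kinetics, reactors = reactors,
                 enzymes = enzymes, min_reads = min_reads,
                 ks_alpha = ks_alpha, n_top = n_top,
                 min_prevalence = min_prevalence,
                 align_tolerance = align_tolerance, rate_r2 = rate_r2,
                 curve_r2 = curve_r2,
                 independence_tolerance = independence_tolerance,
                 n_permutations = n_permutations, transform = transform,
                 ranking = ranking, replicate = replicate, seed = seed,
                 outdir = outdir)
  validate_run_config(config)
  class(config) <- "run_config"
  config
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' @keywords internal
#' @noRd
validate_run_config <- function(config) {
  if (is.null(config$asv_table)) stopf("config: asv_table path is required")
  if (is.null(config$metadata)) stopf("config: metadata path is required")
  if (is.null(config$activity) && is.null(config$plate_kinetics))
    stopf("config: either activity or plate_kinetics is required")
  if (config$ks_alpha <= 0 || config$ks_alpha >= 1)
    stopf("config: ks_alpha must be in (0, 1), got %g", config$ks_alpha)
  if (config$min_reads < 0) stopf("config: min_reads must be >= 0")
  if (!is_count(config$n_top) || config$n_top < 1)
    stopf("config: n_top must be a positive count")
  if (config$rate_r2 <= 0 || config$rate_r2 > 1 ||
      config$curve_r2 <= 0 || config$curve_r2 > 1)
    stopf("config: r2 thresholds must be in (0, 1]")
  if (config$independence_tolerance < 0)
    stopf("config: independence_tolerance must be >= 0")
  if (!is_count(config$n_permutations))
    stopf("config: n_permutations must be a count")
  if (!config$transform %in% c("hellinger", "none"))
    stopf("config: transform must be 'hellinger' or 'none'")
  if (!config$ranking %in% c("z_on_z", "ratio_trend"))
    stopf("config: ranking must be 'z_on_z' or 'ratio_trend'")
  if ((config$n_permutations > 0) && is.null(config$seed))
    stopf("config: seed is required when permutations are requested")
  invisible(config)
}

#' Run the full pipeline
#'
#' Executes the stages in order — assay (if plate kinetics are given),
#' community profiling (depth filter + alpha diversity), RDA ordination per
#' reactor-enzyme combination, and candidate screening — writing an activity
#' TSV, a diversity TSV, ordination summaries, one candidate table per
#' reactor-enzyme combination, and a JSON manifest (configuration echo,
#' input checksums, package version, per-stage log, output list). Identical
#' configuration and inputs give identical outputs.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  note <- function(stage, msg) {
    log[[length(log) + 1L]] <<- list(stage = stage, message = msg)
  }
  outputs <- character(0)

  # stage: inputs
  input_paths <- Filter(Negate(is.null),
                        config[c("asv_table", "taxonomy", "metadata",
                                 "activity", "plate_kinetics")])
  for (p in input_paths) if (!file.exists(p))
    stopf("stage inputs: missing input file %s", p)
  counts <- read_asv_table(config$asv_table)
  taxonomy <- if (!is.null(config$taxonomy)) read_taxonomy(config$taxonomy)
  metadata <- read_sample_metadata(config$metadata)
  miss_meta <- setdiff(rownames(counts), metadata$sample_id)
  if (length(miss_meta))
    stopf("stage inputs: samples without metadata: %s",
          paste(miss_meta, collapse = ", "))
  note("inputs", sprintf("read %d samples x %d ASVs", nrow(counts),
                         ncol(counts)))

  # stage: assay
  if (!is.null(config$plate_kinetics)) {
    plate <- read_plate_kinetics(config$plate_kinetics)
    activity <- compute_activity_series(plate, curve_r2 = config$curve_r2,
                                        rate_r2 = config$rate_r2,
                                        conc_tolerance = config$independence_tolerance)
    note("assay", sprintf("computed %d activity points from plate kinetics",
                          nrow(activity)))
  } else {
    activity <- read_activity_series(config$activity)
    note("assay", sprintf("loaded %d activity points", nrow(activity)))
  }
  activity_path <- file.path(config$outdir, "activity.tsv")
  write_activity_series(activity, activity_path)
  outputs <- c(outputs, activity_path)

  # stage: profile
  filtered <- filter_samples(counts, min_reads = config$min_reads)
  removed <- attr(filtered, "removed")
  if (length(removed))
    note("profile", sprintf("dropped low-depth sample(s): %s",
                            paste(removed, collapse = ", ")))
  if (!nrow(filtered)) stopf("stage profile: no samples pass the read filter")
  diversity <- alpha_diversity(filtered)
  diversity_path <- file.path(config$outdir, "alpha_diversity.tsv")
  write_tsv(diversity, diversity_path)
  outputs <- c(outputs, diversity_path)
  note("profile", sprintf("%d samples retained; alpha diversity written",
                          nrow(filtered)))

  reactors <- config$reactors
  if (is.null(reactors)) reactors <- sort(unique(activity$reactor))
  enzymes <- config$enzymes
  if (is.null(enzymes)) enzymes <- sort(unique(activity$enzyme))

  # stages: ordinate + screen, per reactor-enzyme combination
  ord_rows <- list()
  combo_i <- 0L
  for (reactor in reactors) {
    for (enzyme in enzymes) {
      combo_i <- combo_i + 1L
      act <- activity[activity$reactor == reactor &
                        activity$enzyme == enzyme, , drop = FALSE]
      if (!nrow(act)) stopf("stage ordinate: no activity for %s / %s",
                            reactor, enzyme)
      meta <- metadata[metadata$reactor == reactor &
                         metadata$replicate == config$replicate, ,
                       drop = FALSE]
      sub <- filtered[rownames(filtered) %in% meta$sample_id, , drop = FALSE]
      if (!nrow(sub)) stopf("stage ordinate: no samples for reactor %s",
                            reactor)
      meta <- meta[match(rownames(sub), meta$sample_id), , drop = FALSE]
      pairing <- align_days(act$day, meta$day,
                            tolerance_days = config$align_tolerance)
      sample_ids <- meta$sample_id[match(pairing$sample_day, meta$day)]
      act_use <- act$rate[match(pairing$activity_day, act$day)]
      sub <- sub[sample_ids, , drop = FALSE]
      sub <- sub[, colSums(sub) > 0, drop = FALSE]
      ord <- rda(sub, act_use, n_permutations = config$n_permutations,
                 transform = config$transform,
                 seed = config$seed + 1000L * combo_i)
      ord_rows[[combo_i]] <- data.frame(reactor = reactor, enzyme = enzyme,
                                        r_squared = ord$constrained_fraction,
                                        adjusted_r_squared = ord$adjusted_r_squared,
                                        p = ord$permutation_p,
                                        n_permutations = ord$n_permutations,
                                        n_samples = nrow(sub),
                                        seed = config$seed + 1000L * combo_i)
      note("ordinate", sprintf("%s/%s: RDA R2 = %.3f, p = %.4g", reactor,
                               enzyme, ord$constrained_fraction,
                               ord$permutation_p))

      cand <- screen(filtered, taxonomy, metadata, activity, reactor, enzyme,
                     min_reads = config$min_reads,
                     ks_alpha = config$ks_alpha,
                     min_prevalence = config$min_prevalence,
                     n_top = config$n_top,
                     align_tolerance = config$align_tolerance,
                     replicate = config$replicate, ranking = config$ranking)
      cand_path <- file.path(config$outdir,
                             sprintf("candidates_%s_%s.tsv", reactor, enzyme))
      write_candidates(cand, cand_path)
      outputs <- c(outputs, cand_path)
      note("screen", sprintf("%s/%s: %d screened, %d retained, %d reported",
                             reactor, enzyme, attr(cand, "n_screened"),
                             attr(cand, "n_retained"), nrow(cand)))
    }
  }
  ordination_path <- file.path(config$outdir, "ordination_summary.tsv")
  write_tsv(do.call(rbind, ord_rows), ordination_path)
  outputs <- c(outputs, ordination_path)

  manifest <- list(
    package = "hydroscreen",
    version = as.character(utils::packageVersion("hydroscreen")),
    config = unclass(config),
    input_checksums = as.list(tools::md5sum(unlist(input_paths))),
    outputs = outputs,
    candidate_tables = grep("candidates_", outputs, value = TRUE),
    log = log)
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate communities and evaluate screening recovery
#'
#' For each responder-tracking level and seed: generate an activity profile
#' and a synthetic community with planted responders, run the full screen,
#' and tabulate recovery (fraction of planted responders among the top-N
#' candidates) and background intrusion (non-planted ASVs in the top-N).
#'
#' @param tracking_levels responder-tracking correlations to simulate.
#' @param n_seeds simulations per level.
#' @param sim_spec base [community_sim_spec()] (tracking is overridden per
#'   level).
#' @param profile_spec [activity_profile_spec()] for the activity series.
#' @param n_top candidate list size (default 25).
#' @param seed root seed; per-run seeds are derived from it.
#' @param enzyme simulated enzyme label.
#' @return data.frame (`tracking`, `seed`, `n_planted`, `n_recovered`,
#'   `recovery`, `intrusion`) with a per-level `summary` attribute (median
#'   recovery).
#' @export
simulate_and_evaluate <- function(tracking_levels = c(0.5, 0.7, 0.9, 1.0),
                                  n_seeds = 10,
                                  sim_spec = community_sim_spec(),
                                  profile_spec = activity_profile_spec(),
                                  n_top = 25, seed = 1,
                                  enzyme = "cellulase") {
  rows <- list()
  for (li in seq_along(tracking_levels)) {
    level <- tracking_levels[li]
    spec <- sim_spec
    spec$responder_tracking <- level
    for (si in seq_len(n_seeds)) {
      run_seed <- (seed + 7919L * li + 104729L * si) %% .Machine$integer.max
      act <- generate_activity_profile(profile_spec, reactor = "R1",
                                       enzyme = enzyme, seed = run_seed)
      com <- generate_community(spec, act, seed = run_seed + 1L)
      cand <- screen(com$counts, com$taxonomy, com$metadata, act,
                     reactor = "R1", enzyme = enzyme, n_top = n_top)
      planted <- com$truth$responders[[enzyme]]
      hit <- sum(planted %in% cand$asv_id)
      rows[[length(rows) + 1L]] <-
        data.frame(tracking = level, seed = run_seed,
                   n_planted = length(planted), n_recovered = hit,
                   recovery = hit / max(1, length(planted)),
                   intrusion = nrow(cand) - hit)
    }
  }
  out <- do.call(rbind, rows)
  summ <- stats::aggregate(recovery ~ tracking, data = out, FUN = stats::median)
  names(summ)[2] <- "median_recovery"
  attr(out, "summary") <- summ
  out
}
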