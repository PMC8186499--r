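# Programmatic fixtures: a small three-reactor synthetic study written as
# delimited text files, reused by the pipeline and acceptance tests.

# Distinct lag-rise-decline shapes per reactor, two enzymes each.
fixture_activity <- function(seed = 11) {
  specs <- list(
    R1 = activity_profile_spec(baseline_rate = 20, fold_rise = 2,
                               rise_day = 39, decline_day = 67,
                               decline_fraction = 0.85, noise_cv = 0.08),
    R2 = activity_profile_spec(baseline_rate = 4, fold_rise = 17.6,
                               rise_day = 32, decline_day = 62,
                               decline_fraction = 0.5, noise_cv = 0.08),
    R3 = activity_profile_spec(baseline_rate = 8, fold_rise = 7.9,
                               rise_day = 13, decline_day = 41,
                               decline_fraction = 0.4, noise_cv = 0.08))
  rows <- list()
  i <- 0L
  for (reactor in names(specs)) {
    for (enzyme in c("cellulase", "xylanase")) {
      i <- i + 1L
      rows[[i]] <- generate_activity_profile(specs[[reactor]],
                                             reactor = reactor,
                                             enzyme = enzyme,
                                             seed = seed + i)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("activity_series", "data.frame")
  out
}

# Three per-reactor communities sharing one ASV id space; returns combined
# counts/metadata plus per-reactor truth.
fixture_study <- function(seed = 11, n_asvs = 220, n_responders = 5,
                          depth_mean = 25000, depth_sd = 4000) {
  activity <- fixture_activity(seed)
  spec <- community_sim_spec(n_asvs = n_asvs, n_responders = n_responders,
                             depth_mean = depth_mean, depth_sd = depth_sd)
  counts <- NULL
  metadata <- NULL
  taxonomy <- NULL
  truth <- list()
  for (reactor in unique(activity$reactor)) {
    act <- activity[activity$reactor == reactor, , drop = FALSE]
    com <- generate_community(spec, act, seed = seed + match(reactor, c("R1", "R2", "R3")))
    counts <- rbind(counts, com$counts)
    metadata <- rbind(metadata, com$metadata)
    if (is.null(taxonomy)) taxonomy <- com$taxonomy
    truth[[reactor]] <- com$truth
  }
  list(activity = activity, counts = counts, metadata = metadata,
       taxonomy = taxonomy, truth = truth)
}

# Write the study as the delimited files run_pipeline() consumes.
write_fixture_files <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    asv_table = file.path(dir, "counts.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    activity = file.path(dir, "activity.tsv"))
  counts_df <- data.frame(sample_id = rownames(study$counts), study$counts,
                          check.names = FALSE)
  utils::write.table(counts_df, paths$asv_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$taxonomy, paths$taxonomy, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$metadata, paths$metadata, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_activity_series(study$activity, paths$activity)
  paths
}
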