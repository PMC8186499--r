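make_counts <- function(totals, n_asvs = 8, seed = 1) {
  set.seed(seed)
  m <- t(vapply(totals, function(tot) {
    as.integer(rmultinom(1, tot, prob = runif(n_asvs))[, 1])
  }, integer(n_asvs)))
  dimnames(m) <- list(sprintf("S%02d", seq_along(totals)),
                      sprintf("ASV_%03d", seq_len(n_asvs)))
  m
}

test_that("read filter keeps samples at or above the threshold", {
  counts <- make_counts(c(12000, 9999, 10000))
  out <- suppressMessages(filter_samples(counts, min_reads = 10000))
  expect_identical(rownames(out), c("S01", "S03"))
  expect_identical(attr(out, "removed"), "S02")

  all_ok <- suppressMessages(filter_samples(counts, min_reads = 100))
  expect_equal(nrow(all_ok), 3)

  expect_warning(
    empty <- suppressMessages(filter_samples(counts, min_reads = 1e6)),
    "below")
  expect_equal(nrow(empty), 0)
})

test_that("relative abundances close to one and reject zero-total samples", {
  m <- matrix(c(2L, 2L, 4L), 1, dimnames = list("a", c("x", "y", "z")))
  expect_equal(unname(to_relative(m)[1, ]), c(0.25, 0.25, 0.5))
  m0 <- rbind(m, b = c(0L, 0L, 0L))
  expect_error(to_relative(m0), "zero total")
  r <- to_relative(make_counts(c(5000, 8000, 20000)))
  expect_equal(unname(rowSums(r)), rep(1, 3), tolerance = 1e-9)
})

test_that("Chao1 matches its closed form and a tally oracle", {
  expect_equal(chao1(c(5, 5, 5)), 3)
  expect_equal(chao1(c(1, 1, 2)), 3.5)
  set.seed(9)
  for (i in 1:20) {
    v <- rpois(200, lambda = 0.7)
    expect_equal(chao1(v), oracle_chao1(v))
    # estimator dominates observed richness; equality iff f1 <= 1
    expect_gte(chao1(v), sum(v > 0))
    expect_identical(chao1(v) == sum(v > 0), sum(v == 1) <= 1)
  }
})

test_that("Shannon index matches hand-computed values and its bound", {
  expect_equal(shannon(rep(5, 4)), log(4))
  expect_equal(shannon(c(0, 7, 0)), 0)
  expect_equal(shannon(c(1, 1, 2)), 1.0397, tolerance = 1e-4)
  expect_equal(shannon(c(1, 1, 2), base = 2), 1.5)
  set.seed(10)
  for (i in 1:10) {
    v <- rpois(50, 2)
    v[1] <- v[1] + 1L # guard against all-zero draws
    expect_lte(shannon(v), log(sum(v > 0)) + 1e-12)
  }
})

test_that("taxonomic aggregation conserves totals and pools unresolved ranks", {
  counts <- make_counts(c(4000, 6000), n_asvs = 4)
  taxonomy <- data.frame(
    asv_id = colnames(counts),
    domain = "Bacteria", phylum = "P1", class = "C1", order = "O1",
    family = c("F1", "F1", "F2", "F2"),
    genus = c("G1", "G1", "G2", ""),
    species = "", stringsAsFactors = FALSE)
  ag <- aggregate_taxon(counts, taxonomy, rank = "genus")
  expect_setequal(colnames(ag), c("G1", "G2", "F2 (unclassified)"))
  expect_equal(unname(ag[, "G1"]),
               unname(counts[, 1] + counts[, 2]))
  expect_equal(rowSums(ag), rowSums(counts))
  expect_identical(aggregate_taxon(counts, taxonomy, rank = "asv"), counts)

  # filtering and aggregating commute (aggregation preserves totals)
  f_then_a <- aggregate_taxon(
    suppressMessages(filter_samples(counts, 5000)), taxonomy, "family")
  a_then_f <- suppressMessages(filter_samples(
    aggregate_taxon(counts, taxonomy, "family"), 5000))
  expect_equal(f_then_a, a_then_f, ignore_attr = TRUE)
})

test_that("alpha diversity summarizes every sample", {
  counts <- make_counts(c(4000, 9000, 15000))
  d <- alpha_diversity(counts)
  expect_equal(d$reads, unname(rowSums(counts)))
  expect_equal(d$chao1, unname(apply(counts, 1, chao1)))
})

test_that("delimited round trips preserve counts, taxonomy and metadata", {
  study <- fixture_study(seed = 21, n_asvs = 30, n_responders = 2,
                         depth_mean = 12000, depth_sd = 0)
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(study, dir)
  counts <- read_asv_table(paths$asv_table)
  expect_equal(counts, study$counts)
  tax <- read_taxonomy(paths$taxonomy)
  expect_equal(tax$genus, study$taxonomy$genus)
  meta <- read_sample_metadata(paths$metadata)
  expect_equal(meta$sample_id, study$metadata$sample_id)
  act <- read_activity_series(paths$activity)
  expect_equal(act$rate, study$activity$rate, tolerance = 1e-9)

  # ASVs-as-rows orientation is auto-detected
  t_path <- file.path(dir, "counts_t.tsv")
  tdf <- data.frame(asv_id = colnames(study$counts), t(study$counts),
                    check.names = FALSE)
  utils::write.table(tdf, t_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_asv_table(t_path), study$counts)
})

test_that("semicolon-delimited lineages parse into ranks", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "tax.tsv")
  writeLines(c("asv_id\ttaxonomy",
               "ASV_1\tBacteria;Firmicutes;Clostridia;Oscillospirales;Ruminococcaceae;Ruminiclostridium;",
               "ASV_2\tBacteria;Spirochaetota"), path)
  tax <- read_taxonomy(path)
  expect_equal(tax$genus, c("Ruminiclostridium", ""))
  expect_equal(tax$phylum, c("Firmicutes", "Spirochaetota"))
  lab <- best_taxonomy_label(tax)
  expect_equal(unname(lab), c("Ruminiclostridium", "Spirochaetota"))
})
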