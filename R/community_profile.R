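# ASV count-table handling: readers, read-depth filtering, relative
# abundance, alpha diversity, and taxonomic aggregation.

TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family",
                    "genus", "species")

#' Read an ASV count table
#'
#' Reads a delimited (TSV/CSV) count table with ASVs as rows or columns;
#' orientation is auto-detected from the header: a first column named
#' `asv_id` (or `ASV`, `OTU`, `#OTU ID`) means ASVs are rows, `sample_id`
#' (or `sample`) means samples are rows. The returned matrix always has
#' samples as rows and ASVs as columns.
#'
#' @param path file path.
#' @return integer matrix, samples x ASVs.
#' @export
read_asv_table <- function(path) {
  x <- read_delim_auto(path)
  if (ncol(x) < 2L) stopf("count table must have an id column plus counts")
  id_col <- names(x)[1]
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- as.character(x[[1]])
  asv_names <- c("asv_id", "asv", "otu", "#otu id", "zotu")
  sample_names <- c("sample_id", "sample")
  key <- tolower(id_col)
  if (key %in% asv_names) m <- t(m)
  else if (!key %in% sample_names && !grepl("sample", key)) {
    # fall back: id values looking like ASV/OTU ids mean ASVs are rows
    if (all(grepl("^(asv|otu|zotu)", tolower(rownames(m))))) m <- t(m)
  }
  storage.mode(m) <- "integer"
  validate_asv_counts(m)
}

#' Read a BIOM-format (JSON) ASV table
#'
#' Thin wrapper over `biomformat::read_biom()`; BIOM stores observations
#' (ASVs) by samples, which is transposed to the samples-by-ASVs orientation
#' used throughout.
#'
#' @param path path to a BIOM JSON file.
#' @return integer matrix, samples x ASVs.
#' @export
read_biom_table <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stopf("reading BIOM files requires the biomformat package")
  b <- biomformat::read_biom(path)
  m <- t(as.matrix(biomformat::biom_data(b)))
  storage.mode(m) <- "integer"
  validate_asv_counts(m)
}

#' @keywords internal
#' @noRd
validate_asv_counts <- function(m) {
  if (!is.matrix(m)) stopf("counts must be a matrix (samples x ASVs)")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stopf("count matrix needs sample row names and ASV column names")
  if (any(!is.finite(m)) || any(m < 0))
    stopf("counts must be finite and non-negative")
  m
}

#' Read a taxonomy table
#'
#' Accepts either a two-column table (`asv_id`, `taxonomy`) with
#' semicolon-delimited 7-rank lineages, or a wide table with one column per
#' rank. Missing ranks are stored as empty strings.
#'
#' @param path file path.
#' @return data.frame with columns `asv_id` and the 7 ranks
#'   (domain..species).
#' @export
read_taxonomy <- function(path) {
  x <- read_delim_auto(path)
  names(x)[1] <- "asv_id"
  if (all(TAXONOMY_RANKS %in% tolower(names(x)))) {
    names(x) <- tolower(names(x))
    return(x[, c("asv_id", TAXONOMY_RANKS)])
  }
  if (ncol(x) < 2L) stopf("taxonomy table needs a lineage column")
  lineage <- strsplit(as.character(x[[2]]), ";\\s*")
  ranks <- t(vapply(lineage, function(l) {
    l <- sub("^[a-z]__", "", l) # tolerate greengenes-style prefixes
    length(l) <- length(TAXONOMY_RANKS)
    ifelse(is.na(l), "", l)
  }, character(length(TAXONOMY_RANKS))))
  out <- data.frame(asv_id = x$asv_id, ranks, stringsAsFactors = FALSE)
  names(out) <- c("asv_id", TAXONOMY_RANKS)
  out
}

#' Read sample metadata
#'
#' @param path TSV/CSV keyed by `sample_id` with columns `reactor`, `day`
#'   and optionally `replicate`.
#' @return data.frame.
#' @export
read_sample_metadata <- function(path) {
  x <- read_delim_auto(path)
  need <- c("sample_id", "reactor", "day")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stopf("sample metadata missing column(s): %s", paste(miss, collapse = ", "))
  if (!"replicate" %in% names(x)) x$replicate <- 1L
  if (anyDuplicated(x$sample_id)) stopf("duplicate sample_id in metadata")
  x
}

#' Remove low-depth samples
#'
#' Drops samples whose total read count is strictly below `min_reads`
#' (default 10,000 reads). Removed sample ids are reported via `message()`
#' and stored in attribute `"removed"`; an all-removed table yields an empty
#' matrix with a warning, not an error.
#'
#' @param counts samples x ASVs count matrix.
#' @param min_reads minimum per-sample total (kept iff total >= min_reads).
#' @return the filtered count matrix.
#' @export
filter_samples <- function(counts, min_reads = 10000) {
  counts <- validate_asv_counts(counts)
  totals <- rowSums(counts)
  keep <- totals >= min_reads
  removed <- rownames(counts)[!keep]
  if (length(removed))
    message(sprintf("filter_samples: removed %d sample(s) below %d reads: %s",
                    length(removed), min_reads, paste(removed, collapse = ", ")))
  if (!any(keep))
    warnf("all %d samples fall below %d reads", nrow(counts), min_reads)
  out <- counts[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Convert counts to relative abundances
#'
#' @param counts samples x ASVs count matrix with positive sample totals
#'   (filter zero-total samples first).
#' @return matrix of fractions; each row sums to 1.
#' @export
to_relative <- function(counts) {
  counts <- validate_asv_counts(counts)
  totals <- rowSums(counts)
  if (any(totals <= 0))
    stopf("sample(s) with zero total reads: %s (filter before normalizing)",
          paste(rownames(counts)[totals <= 0], collapse = ", "))
  sweep(counts, 1, totals, "/")
}

#' Chao1 richness estimate (bias-corrected)
#'
#' `S_obs + f1 * (f1 - 1) / (2 * (f2 + 1))` where `f1` and `f2` are the
#' numbers of singleton and doubleton ASVs; the bias-corrected form is
#' defined even when no doubletons are observed.
#'
#' @param counts integer count vector for one sample.
#' @return the richness estimate (>= observed richness).
#' @examples
#' chao1(c(1, 1, 2)) # 3.5
#' @export
chao1 <- function(counts) {
  if (any(counts < 0)) stopf("counts must be non-negative")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity index
#'
#' `-sum(p * log(p))` over taxa with nonzero counts; natural log by default
#' (configurable via `base`).
#'
#' @param counts count vector for one sample.
#' @param base logarithm base (default `exp(1)`, i.e. nats).
#' @return the Shannon index H.
#' @examples
#' shannon(rep(5, 4)) # log(4)
#' @export
shannon <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stopf("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stopf("sample has zero total count")
  p <- counts[counts > 0] / total
  -sum(p * log(p, base = base))
}

#' Alpha diversity summary per sample
#'
#' @param counts samples x ASVs count matrix.
#' @return data.frame with `sample_id`, `reads`, `observed`, `chao1`,
#'   `shannon`.
#' @export
alpha_diversity <- function(counts) {
  counts <- validate_asv_counts(counts)
  data.frame(sample_id = rownames(counts),
             reads = rowSums(counts),
             observed = rowSums(counts > 0),
             chao1 = apply(counts, 1, chao1),
             shannon = apply(counts, 1, shannon),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate an ASV table at a taxonomic rank
#'
#' Sums counts of ASVs sharing the lineage label at `rank`. ASVs unresolved
#' at that rank are pooled under their nearest classified parent, labelled
#' `"<parent> (unclassified)"`; fully unclassified ASVs pool under
#' `"Unclassified"`. `rank = "asv"` returns the table unchanged. Sample
#' totals are preserved.
#'
#' @param counts samples x ASVs count matrix.
#' @param taxonomy taxonomy data.frame from [read_taxonomy()].
#' @param rank one of domain, phylum, class, order, family, genus, species,
#'   or asv.
#' @return samples x taxa aggregated count matrix.
#' @export
aggregate_taxon <- function(counts, taxonomy, rank = "genus") {
  counts <- validate_asv_counts(counts)
  rank <- match.arg(rank, c(TAXONOMY_RANKS, "asv"))
  if (rank == "asv") return(counts)
  labels <- taxon_labels(taxonomy, rank)
  lab <- labels[match(colnames(counts), taxonomy$asv_id)]
  lab[is.na(lab)] <- "Unclassified"
  groups <- split(seq_len(ncol(counts)), lab)
  out <- vapply(groups, function(idx)
    rowSums(counts[, idx, drop = FALSE]), numeric(nrow(counts)))
  if (nrow(counts) == 1L) out <- matrix(out, nrow = 1,
                                        dimnames = list(rownames(counts),
                                                        names(groups)))
  out
}

#' @keywords internal
#' @noRd
taxon_labels <- function(taxonomy, rank) {
  ri <- match(rank, TAXONOMY_RANKS)
  vapply(seq_len(nrow(taxonomy)), function(i) {
    lineage <- as.character(taxonomy[i, TAXONOMY_RANKS[seq_len(ri)]])
    lineage[is.na(lineage)] <- ""
    if (nzchar(lineage[ri])) return(lineage[ri])
    resolved <- which(nzchar(lineage))
    if (!length(resolved)) return("Unclassified")
    sprintf("%s (unclassified)", lineage[max(resolved)])
  }, character(1))
}

#' Best-resolved taxonomy label per ASV
#'
#' Deepest non-empty rank of each lineage, used to annotate candidate
#' tables.
#'
#' @param taxonomy taxonomy data.frame.
#' @return named character vector keyed by `asv_id`.
#' @export
best_taxonomy_label <- function(taxonomy) {
  out <- vapply(seq_len(nrow(taxonomy)), function(i) {
    lineage <- as.character(taxonomy[i, TAXONOMY_RANKS])
    lineage[is.na(lineage)] <- ""
    resolved <- which(nzchar(lineage))
    if (!length(resolved)) "Unclassified" else lineage[max(resolved)]
  }, character(1))
  stats::setNames(out, taxonomy$asv_id)
}
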