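# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Closed-form simple OLS of y on x. Returns slope, intercept, r_squared.
# r_squared is defined as 1 when the residual and total sums of squares are
# both numerically zero (a perfectly flat series fits a flat line).
#' @keywords internal
#' @noRd
ols_fit <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stopf("need at least 2 points for a line fit")
  mx <- mean(x)
  my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx <= 0) stopf("zero spread in x: cannot fit a slope")
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  ss_tot <- sum((y - my)^2)
  ss_res <- sum((y - intercept - slope * x)^2)
  scale <- max(ss_tot, mean(y^2) * n, 1)
  r2 <- if (ss_tot <= 1e-12 * scale) 1 else 1 - ss_res / ss_tot
  list(slope = slope, intercept = intercept,
       r_squared = max(0, min(1, r2)), n = n)
}

#' @keywords internal
#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && abs(x - round(x)) < 1e-8

#' @keywords internal
#' @noRd
read_delim_auto <- function(path) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

#' @keywords internal
#' @noRd
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
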