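#' Kruskal-Wallis rank test between two groups
#'
#' Shared primitive of every differential-coexpression screen in the
#' pipeline: compares the distribution of `values` between the two levels
#' of `groups` using the tie-corrected Kruskal-Wallis H statistic with a
#' chi-square (1 df) p-value.
#'
#' An input in which every value is tied carries no rank information; it is
#' defined to return `statistic = 0`, `p_value = 1` rather than an error,
#' because degenerate product vectors (e.g. a gene that is constant zero)
#' do occur on synthetic and filtered data.
#'
#' @param values Numeric vector of observations.
#' @param groups Vector with exactly two distinct levels, same length as
#'   `values`.
#' @return A `TestResult` list: `statistic` (H), `p_value`, `n`.
#' @examples
#' kw_test(c(1, 2, 3, 4, 5, 6), rep(c("A", "B"), each = 3))
#' @export
kw_test <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("`values` and `groups` must have the same length")
  }
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  lev <- unique(groups)
  if (length(lev) != 2L) {
    stop("`groups` must have exactly 2 distinct levels, got ", length(lev))
  }
  if (min(table(groups)) < 2L) {
    stop("each group needs at least 2 observations")
  }
  if (length(unique(values)) == 1L) {
    return(test_result(0, 1, length(values)))
  }
  kt <- stats::kruskal.test(values, factor(groups))
  test_result(unname(kt$statistic), kt$p.value, length(values))
}

#' Pearson correlation test
#'
#' Sample Pearson r with a two-sided p-value from the t distribution on
#' n - 2 degrees of freedom; used for every edge of the differential
#' coexpression network.
#'
#' @param x,y Numeric vectors of equal length (>= 3), both non-constant.
#' @return A `TestResult` list with `statistic` = r in `[-1, 1]`.
#' @examples
#' pearson_test(1:4, c(4, 3, 2, 1))
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: constant vector has no defined correlation")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  test_result(unname(ct$estimate), ct$p.value, length(x))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment preserving input order. The adjustment is always
#' applied within a single test family declared by the caller (one screen
#' stage, one genome-wide scan, one enrichment battery); this function
#' never pools across families.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return An `AdjustedPValues` list: `raw` and `adjusted`, same order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))$adjusted
#' @export
bh_adjust <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stop("all p-values must lie in [0, 1]")
  }
  list(raw = p_values, adjusted = stats::p.adjust(p_values, method = "BH"))
}

test_result <- function(statistic, p_value, n) {
  structure(list(statistic = statistic, p_value = p_value, n = n),
            class = "oxaging_test_result")
}

#' @export
print.oxaging_test_result <- function(x, ...) {
  cat(sprintf("TestResult: statistic = %.6g, p = %.4g, n = %d\n",
              x$statistic, x$p_value, x$n))
  invisible(x)
}

# Fast internal KW H/p on a precomputed two-group split; used by the
# vectorised genome-wide scans where kruskal.test()'s formula/NA handling
# overhead dominates. Must agree with kw_test (asserted in tests).
.kw_fast <- function(values, is_g1) {
  n <- length(values)
  r <- rank(values)
  n1 <- sum(is_g1)
  n2 <- n - n1
  h <- 12 / (n * (n + 1)) *
    (sum(r[is_g1])^2 / n1 + sum(r[!is_g1])^2 / n2) - 3 * (n + 1)
  ties <- table(values)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr == 0) return(c(0, 1))
  h <- h / tie_corr
  c(h, stats::pchisq(h, df = 1, lower.tail = FALSE))
}
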