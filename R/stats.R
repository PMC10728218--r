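# Group-comparison statistics and effect sizes.

#' Mann-Whitney U test
#'
#' Rank-sum test of two independent samples. The statistic is
#' `U = #{x_i > y_j} + 0.5 * #{x_i = y_j}` (the convention in which complete
#' separation with all x below all y gives U = 0). The p-value is exact for
#' small samples without ties and uses the tie-corrected normal
#' approximation otherwise (via [stats::wilcox.test()]).
#'
#' @param x,y Numeric samples (both nonempty).
#' @return One-row tibble with `u`, `p_value`, `n_x`, `n_y`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) abort("both samples must be nonempty.")
  wt <- suppressWarnings(wilcox.test(x, y, exact = NULL, correct = TRUE))
  tibble(u = unname(wt$statistic), p_value = wt$p.value,
         n_x = length(x), n_y = length(y))
}

#' Cliff's delta effect size
#'
#' `delta = (#{x_i > y_j} - #{x_i < y_j}) / (n_x * n_y)`, the difference in
#' the probabilities that a value from `x` exceeds one from `y` and vice
#' versa. Ranges over `[-1, 1]`; 0 means stochastic equality.
#'
#' @param x,y Numeric samples (both nonempty).
#' @return A single number in `[-1, 1]`.
#' @export
#' @examples
#' cliffs_delta(c(1, 2), c(1, 3))   # (1 - 2) / 4
cliffs_delta <- function(x, y) {
  if (!length(x) || !length(y)) abort("both samples must be nonempty.")
  d <- outer(x, y, "-")
  (sum(d > 0) - sum(d < 0)) / (length(x) * length(y))
}

#' Cohen's d from group summary statistics
#'
#' Standardized mean difference `(mean1 - mean2) / s_pooled` with the pooled
#' standard deviation
#' `s_pooled = sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2))`.
#'
#' @param mean1,sd1,n1 First group's mean, SD and size.
#' @param mean2,sd2,n2 Second group's mean, SD and size.
#' @return A single number.
#' @export
#' @examples
#' cohens_d(42.95, 18.09, 22, 39.29, 16.12, 24)
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) abort("need n >= 2 per group.")
  if (sd1 < 0 || sd2 < 0) abort("standard deviations must be non-negative.")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) abort("pooled standard deviation is zero.")
  (mean1 - mean2) / sp
}

#' Cramer's V association effect size
#'
#' `V = sqrt(chi2 / (n (min(r, c) - 1)))` with the Pearson chi-square
#' statistic computed without continuity correction.
#'
#' @param table Matrix of non-negative integer counts (r x c, total > 0).
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' cramers_v(matrix(c(12, 14, 10, 10), 2))
cramers_v <- function(table) {
  table <- as.matrix(table)
  check_contingency(table)
  chi2 <- suppressWarnings(chisq.test(table, correct = FALSE))$statistic
  unname(sqrt(chi2 / (sum(table) * (min(dim(table)) - 1))))
}

#' Chi-square and Fisher's exact tests of a contingency table
#'
#' Pearson chi-square without Yates continuity correction, and the two-sided
#' Fisher exact test (hypergeometric).
#'
#' @param table Matrix of counts (2 x 2 for Fisher).
#' @return One-row tibble with `statistic` (chi-square only) and `p_value`.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  check_contingency(table)
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble(statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' @rdname chi_square_test
#' @export
fisher_exact_test <- function(table) {
  table <- as.matrix(table)
  check_contingency(table)
  if (!all(dim(table) == c(2, 2))) abort("Fisher's exact test needs a 2x2 table.")
  ft <- fisher.test(table)
  tibble(statistic = NA_real_, p_value = ft$p.value)
}

check_contingency <- function(table) {
  if (any(table < 0) || any(table != round(table))) {
    abort("contingency table must hold non-negative integer counts.")
  }
  if (sum(table) == 0) abort("contingency table total must be positive.")
  invisible(table)
}
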