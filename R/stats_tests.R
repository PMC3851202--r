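#' Two-proportion z-test (pooled variance)
#'
#' Tests equality of two binomial proportions with the pooled-variance
#' z statistic z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2)), where p is
#' the pooled proportion, and a two-sided p-value from the standard
#' normal. When the pooled proportion is 0 or 1 (no variability under
#' the null) z is defined as 0 and p as 1.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return List of class `prop_z` with `x1`, `n1`, `x2`, `n2`, `p1`,
#'   `p2`, `z`, `p_two_sided`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  if (n1 < 1L || n2 < 1L) stop("both group sizes must be >= 1")
  if (x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2)
    stop("counts must satisfy 0 <= x <= n")
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp <= 0 || pp >= 1) {
    z <- 0; p <- 1
  } else {
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(x1 = x1, n1 = n1, x2 = x2, n2 = n2, p1 = p1, p2 = p2,
                 z = z, p_two_sided = p),
            class = "prop_z")
}

#' @export
print.prop_z <- function(x, ...) {
  cat(sprintf("two-proportion z-test: %d/%d (%.2f%%) vs %d/%d (%.2f%%)\n",
              x$x1, x$n1, 100 * x$p1, x$x2, x$n2, 100 * x$p2))
  cat(sprintf("  z = %.4f, two-sided p = %.4g\n", x$z, x$p_two_sided))
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic on an r x c contingency table with expected counts
#' from the margins and (r-1)(c-1) degrees of freedom. No continuity
#' correction by default (appropriate for the large counts this package
#' produces); set `correct = TRUE` for the Yates-corrected 2x2 form.
#'
#' @param table Matrix of nonnegative counts, at least 2x2, with no
#'   all-zero row or column.
#' @param correct Apply Yates continuity correction (2x2 only)?
#' @return List of class `chisq_independence` with `observed`,
#'   `statistic`, `dof`, `p_value`.
#' @export
chi_square_independence <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("need at least a 2x2 table")
  if (any(table < 0)) stop("counts must be nonnegative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all-zero row or column margin")
  res <- suppressWarnings(chisq.test(table, correct = correct))
  structure(list(observed = table,
                 statistic = unname(res$statistic),
                 dof = unname(res$parameter),
                 p_value = unname(res$p.value)),
            class = "chisq_independence")
}

#' @export
print.chisq_independence <- function(x, ...) {
  cat(sprintf("chi-square independence: X2 = %.4f, dof = %d, p = %.4g\n",
              x$statistic, x$dof, x$p_value))
  invisible(x)
}

#' Upper-tail hypergeometric probability P[X >= k]
#'
#' Exact enrichment p-value: the probability of drawing at least `k`
#' annotated proteins in a sample of `n` from a universe of `N`
#' containing `K` annotated, computed by summation in log space
#' (lchoose) for numerical stability.
#'
#' @param k Observed annotated count in the sample.
#' @param K Annotated count in the universe.
#' @param n Sample size.
#' @param N Universe size.
#' @return p-value in \[0, 1\].
#' @export
hypergeometric_upper <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("invalid hypergeometric counts: need 0 <= k <= min(K, n), K <= N, n <= N")
  if (k <= max(0L, n - (N - K))) return(1)
  i <- k:min(K, n)
  logt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  mx <- max(logt)
  min(1, exp(mx + log(sum(exp(logt - mx)))))
}

#' Bonferroni adjustment
#'
#' Family-wise error control: each p-value is multiplied by the number
#' of tests `m` and capped at 1. `m` may exceed the length of the list
#' (tests performed but not reported still count).
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @param m Number of tests, at least `length(p_values)`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (m < length(p_values)) stop("m must be >= number of p-values")
  p.adjust(p_values, method = "bonferroni", n = m)
}

#' log2 enrichment ratio of a term between two sets
#'
#' log2 of the ratio of the term's proportion in the test set to its
#' proportion in the background set. Defined only when the term occurs
#' in both sets; a zero count yields `NA` with a warning.
#'
#' @param count_test,total_test Term count and set size in the test set.
#' @param count_bg,total_bg Term count and set size in the background.
#' @return log2 ratio (numeric), `NA` if undefined.
#' @export
log2_enrichment_ratio <- function(count_test, total_test, count_bg, total_bg) {
  if (count_test < 1 || count_bg < 1) {
    warning("log2 enrichment ratio undefined for zero counts")
    return(NA_real_)
  }
  log2((count_test / total_test) / (count_bg / total_bg))
}

#' Percent increase implied by a log2 enrichment ratio
#'
#' 100 * (2^r - 1), rounded to the nearest integer percent: a log2
#' ratio of 0.5 corresponds to a 41% increase in the term's proportion.
#'
#' @param log2_ratio Numeric log2 ratio.
#' @return Integer percent.
#' @export
percent_increase <- function(log2_ratio) {
  round(100 * (2^log2_ratio - 1))
}

#' Number of distinct modification states of a protein
#'
#' A protein with `n_sites` modifiable sites, each independently
#' unmodified or carrying one of `n_ptm_types` modification types, can
#' exist as (n_ptm_types + 1)^n_sites molecular species: 2^n for a
#' single modification type, 3^n for two.
#'
#' @param n_sites Number of modifiable sites (>= 0).
#' @param n_ptm_types Number of distinct modification types (>= 1).
#' @return Number of states (numeric to allow large exponents).
#' @export
ptm_state_count <- function(n_sites, n_ptm_types) {
  if (n_sites < 0 || n_ptm_types < 1) stop("need n_sites >= 0, n_ptm_types >= 1")
  (n_ptm_types + 1)^n_sites
}
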