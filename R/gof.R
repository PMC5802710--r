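#' Chi-squared goodness of fit of an affected:unaffected split
#'
#' Compares a group's observed (affected, unaffected) counts with fixed
#' reference proportions using the two-category Pearson statistic
#' \deqn{\chi^2 = \sum_{c} (O_c - E_c)^2 / E_c, \qquad E_c = n\,p_c,}
#' with df = 1 and no continuity correction. The p-value is the upper-tail
#' chi-squared probability.
#'
#' @param n_affected Observed affected count.
#' @param n Group size (>= 1).
#' @param reference Length-2 reference proportions (affected, unaffected) in
#'   (0, 1) summing to 1; defaults to 20:80.
#' @return An object of class `gof_result`: `chi2`, `df`, `p`, `observed`,
#'   `expected`, `reference`.
#' @export
#' @examples
#' gof_test(11, 31)                       # chi2 = 4.65
#' gof_test(6, 30)                        # observed equals expected: chi2 = 0
#' gof_test(7, 12, c(0.35, 0.65))         # chi2 = 2.87
gof_test <- function(n_affected, n, reference = c(0.20, 0.80)) {
  n <- as.integer(n)
  n_affected <- as.integer(n_affected)
  if (is.na(n) || n < 1L) stop("'n' must be an integer >= 1", call. = FALSE)
  if (is.na(n_affected) || n_affected < 0L || n_affected > n) {
    stop("'n_affected' must be an integer in [0, n]", call. = FALSE)
  }
  reference <- check_reference(reference)
  expected <- reference * n
  if (any(expected == 0)) {
    stop("degenerate reference: an expected count is 0", call. = FALSE)
  }
  observed <- c(affected = n_affected, unaffected = n - n_affected)
  chi2 <- sum((observed - expected)^2 / expected)
  structure(
    list(chi2 = chi2, df = 1L, p = chi2_sf(chi2, 1L),
         observed = observed, expected = expected, reference = reference),
    class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("chi-squared GOF: X2(%d) = %.4g, p = %.4g\n", x$df, x$chi2, x$p))
  cat(sprintf("  observed %d:%d, expected %.2f:%.2f (reference %.2f:%.2f)\n",
              x$observed[1], x$observed[2], x$expected[1], x$expected[2],
              x$reference[1], x$reference[2]))
  invisible(x)
}

#' Upper-tail chi-squared probability
#'
#' Survival function of the chi-squared distribution; for df = 1 this equals
#' `erfc(sqrt(x/2))`, i.e. the two-sided normal tail at `z = sqrt(x)`.
#'
#' @param x Non-negative statistic.
#' @param df Degrees of freedom (integer >= 1).
#' @return `P(X >= x)` for `X ~ chi-squared(df)`.
#' @export
#' @examples
#' chi2_sf(3.841, 1)  # ~0.050
chi2_sf <- function(x, df) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("'x' must be finite and >= 0", call. = FALSE)
  }
  df <- as.integer(df)
  if (any(is.na(df)) || any(df < 1L)) {
    stop("'df' must be an integer >= 1", call. = FALSE)
  }
  stats::pchisq(x, df, lower.tail = FALSE)
}

#' Recover integer affected counts from a printed GOF statistic
#'
#' Published goodness-of-fit statistics are internally redundant: given the
#' group size and the reference proportions, the observed integer affected
#' count can be recovered by exhaustive search over all counts `0..n` for
#' those whose statistic rounds to the printed value. A unique result
#' certifies which split the statistic was computed from; an empty result
#' flags an inconsistency (reported, not thrown).
#'
#' @param chi2_printed The rounded statistic as printed.
#' @param n Group size.
#' @param reference Length-2 reference proportions.
#' @param tol_dp Decimal places the printed value is rounded to (default 2).
#' @return Integer vector of matching counts (possibly empty).
#' @export
#' @examples
#' invert_gof(4.65, 31)            # 11
#' invert_gof(2.87, 12, c(0.35, 0.65))  # 7
invert_gof <- function(chi2_printed, n, reference = c(0.20, 0.80), tol_dp = 2L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be an integer >= 1", call. = FALSE)
  tol_dp <- as.integer(tol_dp)
  counts <- 0:n
  stat <- vapply(counts, function(x) gof_test(x, n, reference)$chi2, numeric(1))
  counts[abs(round(stat, tol_dp) - round(chi2_printed, tol_dp)) < 1e-9]
}
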