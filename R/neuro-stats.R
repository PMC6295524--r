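# Statistical comparisons used for benchmarking tracking systems against
# each other.

#' Two-sample F-test for equal variances from summary statistics
#'
#' `f = var1 / var2` exactly as given (no reordering), with a two-tailed
#' p-value from the F distribution.
#'
#' @param var1,var2 sample variances (> 0).
#' @param df1,df2 degrees of freedom (>= 1).
#' @return list with `f`, `df1`, `df2`, `p_value`.
#' @export
f_test_equal_variance <- function(var1, df1, var2, df2) {
  if (!is_scalar_num(var1) || !is_scalar_num(var2) || var1 <= 0 || var2 <= 0)
    abort("variances must be positive")
  if (df1 < 1 || df2 < 1) abort("degrees of freedom must be >= 1")
  f <- var1 / var2
  p_lower <- stats::pf(f, df1, df2)
  p <- 2 * min(p_lower, 1 - p_lower)
  list(f = f, df1 = df1, df2 = df2, p_value = min(p, 1))
}

#' Wilcoxon signed rank test (normal approximation)
#'
#' Paired two-sided test on `x - y` (or on `x` alone as differences). Zero
#' differences are dropped; tied absolute differences get averaged ranks;
#' the z statistic uses the normal approximation with continuity correction
#' and the tie-corrected variance, and carries the sign of the rank-sum
#' direction (positive when `x` tends to exceed `y`).
#'
#' @param x first sample, or the differences if `y` is NULL.
#' @param y optional second (paired) sample.
#' @return list with `z`, `p_value`, `n` (nonzero pairs), `statistic` (the
#'   positive-rank sum W+).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; test undefined")
    return(list(z = NA_real_, p_value = NA_real_, n = 0L, statistic = NA_real_))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  dev <- w_pos - mu
  cc <- 0.5 * sign(dev)
  z <- if (sigma2 > 0) (dev - cc) / sqrt(sigma2) else 0
  p <- min(2 * stats::pnorm(-abs(z)), 1)
  list(z = z, p_value = p, n = n, statistic = w_pos)
}

#' One-sample test of proportions (normal approximation)
#'
#' `Z = (phat - p0) / sqrt(p0 (1 - p0) / n)`.
#'
#' @param successes number of successes (0..n).
#' @param n number of trials (>= 1).
#' @param p0 null proportion, in (0, 1).
#' @return list with `z`, `p_one_sided` (upper tail), `p_two_sided`,
#'   `estimate` (phat).
#' @export
proportion_z_test <- function(successes, n, p0 = 0.5) {
  if (!is_scalar_num(p0) || p0 <= 0 || p0 >= 1) abort("p0 must be in (0, 1)")
  if (n < 1 || successes < 0 || successes > n) abort("need 0 <= successes <= n, n >= 1")
  phat <- successes / n
  z <- (phat - p0) / sqrt(p0 * (1 - p0) / n)
  list(z = z,
       p_one_sided = stats::pnorm(z, lower.tail = FALSE),
       p_two_sided = min(2 * stats::pnorm(-abs(z)), 1),
       estimate = phat)
}

#' Holm-Bonferroni adjusted p-values
#'
#' Step-down adjustment with monotonicity enforcement, capped at 1.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
holm_bonferroni <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    abort("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "holm")
}
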