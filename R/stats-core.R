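#' Statistical primitives for TRG group comparisons
#'
#' All two-sample tests in the package return a one-row tibble with the
#' same columns (`statistic`, `p_value`, `method`, `alternative`, `n1`,
#' `n2`, `degenerate`) so downstream modules can row-bind results from
#' different tests into a single report.
#'
#' @name stats-core
#' @keywords internal
NULL

test_result <- function(statistic, p_value, method, alternative, n1, n2,
                        degenerate = FALSE) {
  tibble::tibble(
    statistic = as.numeric(statistic),
    p_value = min(max(as.numeric(p_value), 0), 1),
    method = method,
    alternative = alternative,
    n1 = as.integer(n1),
    n2 = as.integer(n2),
    degenerate = degenerate
  )
}

#' Fisher Z-transformation of a correlation coefficient
#'
#' Maps a Pearson correlation r in (-1, 1) to z = 0.5 * log((1 + r) / (1 - r)),
#' the variance-stabilizing transform that makes correlation estimates
#' comparable (and averageable) across expression datasets of different size.
#'
#' @param r Numeric vector of correlations, all strictly inside (-1, 1).
#'   `NA` values pass through as `NA`.
#' @return Numeric vector of z-values.
#' @examples
#' fisher_z(0.5)     # 0.5 * log(3)
#' fisher_z(-0.5)    # odd symmetry
#' @export
fisher_z <- function(r) {
  bad <- !is.na(r) & abs(r) >= 1
  if (any(bad)) {
    stop("fisher_z() requires |r| < 1; offending value(s): ",
         paste(format(r[bad]), collapse = ", "))
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Inverse of the Fisher Z-transformation
#'
#' @param z Numeric vector of z-values.
#' @return Correlations in (-1, 1).
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Pearson correlation with explicit zero-variance handling
#'
#' Thin wrapper around [stats::cor()] that enforces the preconditions the
#' coexpression module relies on: vectors of equal length >= 3, and a
#' *missing* (never zero) result when either vector has no variance, so
#' degenerate probes drop out of downstream averages instead of diluting
#' them.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return A single correlation in `[-1, 1]`, or `NA` if either input has
#'   zero variance.
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("pearson_r() requires equal-length vectors")
  if (length(x) < 3) stop("pearson_r() requires length >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# midranks of the pooled sample, split back into the two groups
pooled_midranks <- function(x, y) {
  r <- rank(c(x, y), ties.method = "average")
  list(rx = r[seq_along(x)], ry = r[-seq_along(x)])
}

# Mann-Whitney U for group x against y from midranks
mann_whitney_u <- function(x, y) {
  sum(pooled_midranks(x, y)$rx) - length(x) * (length(x) + 1) / 2
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Rank-sum test with midranks for ties.  For small samples
#' (`n1 + n2 <= exact_threshold`) the null distribution of the
#' Mann-Whitney U statistic is computed by exhaustive enumeration over all
#' `choose(n1 + n2, n1)` group assignments of the pooled values, which is
#' exact even under ties.  Larger samples use the normal approximation with
#' tie-corrected variance and a continuity correction.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param alternative One of `"two_sided"`, `"greater"`, `"less"`;
#'   `"greater"` means x tends to exceed y.
#' @param exact_threshold Use exact enumeration when `n1 + n2` is at most
#'   this value (default 12, where `choose(12, 6) = 924` assignments).
#' @return One-row tibble (see [stats-core]); `statistic` is the
#'   Mann-Whitney U for `x`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two_sided", "greater", "less"),
                              exact_threshold = 12) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    return(test_result(n1 * n2 / 2, 1, "wilcoxon", alternative, n1, n2,
                       degenerate = TRUE))
  }
  u <- mann_whitney_u(x, y)
  if (n1 + n2 <= exact_threshold) {
    p <- wilcoxon_exact_p(pooled, n1, u, alternative)
  } else {
    p <- wilcoxon_normal_p(pooled, n1, n2, u, alternative)
  }
  test_result(u, p, "wilcoxon", alternative, n1, n2)
}

# exact null distribution of U by enumeration over group assignments
wilcoxon_exact_p <- function(pooled, n1, u, alternative) {
  r <- rank(pooled, ties.method = "average")
  idx <- utils::combn(length(pooled), n1)
  us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  p_ge <- mean(us >= u - eps)
  p_le <- mean(us <= u + eps)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two_sided = min(1, 2 * min(p_ge, p_le)))
}

wilcoxon_normal_p <- function(pooled, n1, n2, u, alternative) {
  n <- n1 + n2
  ties <- table(pooled)
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  sigma <- sqrt(sigma2)
  # continuity correction of 0.5 toward the mean
  z_g <- (u - mu - 0.5) / sigma
  z_l <- (u - mu + 0.5) / sigma
  switch(alternative,
         greater = stats::pnorm(z_g, lower.tail = FALSE),
         less = stats::pnorm(z_l),
         two_sided = {
           z <- (abs(u - mu) - 0.5) / sigma
           min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
         })
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum over the pooled data points of the absolute difference
#' between the two empirical CDFs; the p-value comes from the asymptotic
#' Kolmogorov distribution evaluated at `sqrt(n1 * n2 / (n1 + n2)) * D`.
#'
#' @param x,y Numeric vectors.
#' @return One-row tibble (see [stats-core]); `statistic` is D.
#' @export
ks_two_sample <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  pts <- sort(unique(c(x, y)))
  d <- max(abs(stats::ecdf(x)(pts) - stats::ecdf(y)(pts)))
  degen <- length(pts) == 1L
  ne <- n1 * n2 / (n1 + n2)
  p <- kolmogorov_sf(sqrt(ne) * d)
  test_result(d, p, "ks", "two_sided", n1, n2, degenerate = degen)
}

# survival function of the Kolmogorov distribution, Q(lambda)
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) when drawing `n` items without replacement from a population
#' of `N` containing `K` marked items.  The sum runs over the upper tail in
#' log-space (log binomial coefficients combined with log-sum-exp) so very
#' small enrichment p-values do not underflow.
#'
#' @param N Population size.
#' @param K Marked items in the population.
#' @param n Number drawn.
#' @param k Observed marked items among the drawn.
#' @return Upper-tail probability in `[0, 1]`.
#' @examples
#' hypergeom_tail(10, 5, 5, 5)   # 1 / choose(10, 5)
#' @export
hypergeom_tail <- function(N, K, n, k) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1, length(k) == 1)
  if (K > N || n > N || k > min(K, n) || k < 0 || any(c(N, K, n) < 0)) {
    stop("hypergeom_tail(): inconsistent counts (need 0 <= k <= min(K, n), ",
         "n <= N, K <= N); got N=", N, " K=", K, " n=", n, " k=", k)
  }
  i <- k:min(K, n)
  lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

#' Pearson chi-squared test on a 2x2 contingency table
#'
#' @param table 2x2 matrix of non-negative counts with all row and column
#'   sums positive.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return One-row tibble (see [stats-core]); 1 degree of freedom.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    which_margin <- c(
      if (rs[1] == 0) "row 1", if (rs[2] == 0) "row 2",
      if (cs[1] == 0) "column 1", if (cs[2] == 0) "column 2")
    stop("chi_square_2x2(): empty margin (", paste(which_margin, collapse = ", "),
         "); the test is undefined")
  }
  expected <- outer(rs, cs) / sum(table)
  dev <- abs(table - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  test_result(stat, p, "chi2", "two_sided", rs[1], rs[2])
}

#' Welch two-sample t-test
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom; reduces to the classical equal-variance case when the two
#' sample variances agree.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param alternative One of `"two_sided"`, `"greater"`, `"less"`.
#' @return One-row tibble (see [stats-core]) with a `df` column appended.
#' @export
t_test_two_sample <- function(x, y,
                              alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0) {
    res <- test_result(0, 1, "ttest", alternative, n1, n2, degenerate = TRUE)
    res$df <- NA_real_
    return(res)
  }
  se2 <- v1 / n1 + v2 / n2
  stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- switch(alternative,
              greater = stats::pt(stat, df, lower.tail = FALSE),
              less = stats::pt(stat, df),
              two_sided = 2 * stats::pt(abs(stat), df, lower.tail = FALSE))
  res <- test_result(stat, p, "ttest", alternative, n1, n2)
  res$df <- df
  res
}

#' Bonferroni correction
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @param m Number of tests; defaults to `length(p_values)` and must be at
#'   least that.
#' @return Adjusted p-values, `pmin(1, m * p)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("bonferroni(): p-values must lie in [0, 1]")
  }
  if (m < length(p_values)) stop("bonferroni(): m must be >= length(p_values)")
  pmin(1, m * p_values)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator: the probability that a randomly
#' chosen positive is scored above a randomly chosen negative, with tied
#' scores contributing 1/2.  Identical to trapezoidal integration of the
#' ROC curve.
#'
#' @param scores Numeric vector of classifier scores.
#' @param labels Binary vector (0/1 or logical) of the same length; both
#'   classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("roc_auc(): both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
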