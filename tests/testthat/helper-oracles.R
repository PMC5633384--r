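# Independent brute-force oracles used across the test suite.  These are
# deliberately naive re-derivations (enumeration, pair counting, direct
# arithmetic) kept separate from the package's own code paths.

# Exhaustive null distribution of the Mann-Whitney U statistic: every
# assignment of the pooled values to a group of size n1 is enumerated and
# the tail probability read off directly.
oracle_wilcoxon_p <- function(x, y, alternative = "two_sided") {
  pooled <- c(x, y)
  n1 <- length(x)
  rk <- rank(pooled)
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(ix) sum(rk[ix]) - n1 * (n1 + 1) / 2)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  ge <- sum(us >= u_obs - eps) / length(us)
  le <- sum(us <= u_obs + eps) / length(us)
  switch(alternative,
         greater = ge, less = le,
         two_sided = min(1, 2 * min(ge, le)))
}

# Upper-tail hypergeometric probability by direct summation of binomial
# coefficient ratios (no logs).
oracle_hypergeom_tail <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# AUC by counting positive-negative score pairs.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Pair-counting agreement between two partitions (adjusted Rand index),
# computed from the raw contingency table.
oracle_pair_agreement <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
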