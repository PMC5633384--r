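test_that("fisher_z evaluates the log formula, is odd, and round-trips", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-12)
  expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-12)
  expect_error(fisher_z(1), "offending")
  expect_error(fisher_z(-1.2), "offending")
  expect_true(is.na(fisher_z(NA_real_)))
})

test_that("pearson_r matches hand computation and flags zero variance as missing", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), 0.981981, tolerance = 1e-6)
  expect_true(is.na(pearson_r(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pearson_r(1:2, 1:2), "length >= 3")
  expect_error(pearson_r(1:4, 1:3), "equal-length")
})

test_that("wilcoxon rank-sum: trivial cases and a hand-enumerated example", {
  res <- wilcoxon_rank_sum(c(3, 1, 4), c(4, 1, 3))
  expect_equal(res$p_value, 1)
  res <- wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3), alternative = "greater")
  expect_equal(res$p_value, 1 / 20, tolerance = 1e-12)
  allsame <- wilcoxon_rank_sum(c(2, 2), c(2, 2, 2))
  expect_true(allsame$degenerate)
  expect_equal(allsame$p_value, 1)
})

test_that("exact wilcoxon p equals the enumeration oracle for n1+n2 <= 10, with ties", {
  withr::with_seed(41, {
    for (i in 1:40) {
      n1 <- sample(1:5, 1); n2 <- sample(1:5, 1)
      vals <- sample(1:4, n1 + n2, replace = TRUE)  # heavy ties
      x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
      for (alt in c("two_sided", "greater", "less")) {
        expect_equal(wilcoxon_rank_sum(x, y, alt)$p_value,
                     oracle_wilcoxon_p(x, y, alt), tolerance = 1e-12)
      }
    }
  })
})

test_that("exact wilcoxon agrees with wilcox.test on tie-free data", {
  withr::with_seed(42, {
    for (i in 1:20) {
      x <- rnorm(5); y <- rnorm(6)
      expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                   stats::wilcox.test(x, y, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  })
})

test_that("large-sample wilcoxon matches the tie-corrected continuity-corrected reference", {
  withr::with_seed(43, {
    for (i in 1:20) {
      x <- sample(1:10, 25, replace = TRUE)
      y <- sample(1:10, 30, replace = TRUE) + rbinom(30, 1, 0.3)
      expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                   stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
                   tolerance = 1e-10)
    }
  })
})

test_that("KS statistic from the ECDF walk and asymptotic p match the reference", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(c(1, 2), c(5, 6))$statistic, 1)
  expect_equal(ks_two_sample(c(1, 2), c(1.5, 3))$statistic, 0.5)
  withr::with_seed(44, {
    for (i in 1:20) {
      x <- rnorm(20); y <- rnorm(25, 0.4)
      ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
      mine <- ks_two_sample(x, y)
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_lt(abs(mine$p_value - ref$p.value), 1e-4)
    }
  })
})

test_that("hypergeometric tail is exact against direct summation for N <= 30", {
  expect_equal(hypergeom_tail(10, 5, 5, 0), 1)
  expect_equal(hypergeom_tail(10, 5, 5, 5), 1 / 252, tolerance = 1e-12)
  withr::with_seed(45, {
    for (i in 1:60) {
      N <- sample(2:30, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
      k <- sample(0:min(K, n), 1)
      expect_equal(hypergeom_tail(N, K, n, k),
                   oracle_hypergeom_tail(N, K, n, k), tolerance = 1e-12)
      expect_equal(hypergeom_tail(N, K, n, k),
                   stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  })
  expect_error(hypergeom_tail(10, 12, 5, 3), "inconsistent")
  expect_error(hypergeom_tail(10, 5, 5, 6), "inconsistent")
})

test_that("chi-squared 2x2: independence, proportional rows, hand fixture", {
  flat <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_equal(chi_square_2x2(matrix(c(7, 7, 3, 3), 2))$statistic, 0)
  fix <- chi_square_2x2(matrix(c(20, 10, 5, 15), 2))
  expect_equal(fix$statistic, 8.333, tolerance = 1e-3)
  ref <- stats::chisq.test(matrix(c(20, 10, 5, 15), 2), correct = FALSE)
  expect_equal(fix$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(fix$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 3), 2)), "empty margin")
})

test_that("Welch t: trivial cases, antisymmetry, hand fixture, reference agreement", {
  same <- t_test_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  a <- t_test_two_sample(c(1, 2, 3), c(4, 5, 6))
  b <- t_test_two_sample(c(4, 5, 6), c(1, 2, 3))
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$statistic, -3.674, tolerance = 1e-3)
  expect_equal(a$df, 4, tolerance = 1e-12)
  withr::with_seed(46, {
    x <- rnorm(12); y <- rnorm(9, 1, 2)
    ref <- stats::t.test(x, y)
    mine <- t_test_two_sample(x, y)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  })
  degen <- t_test_two_sample(c(2, 2), c(2, 2))
  expect_true(degen$degenerate)
})

test_that("bonferroni clips at 1, preserves order, never decreases", {
  expect_equal(bonferroni(0.5, 1), 0.5)
  expect_equal(bonferroni(c(0.3, 0.01), 5), c(1, 0.05))
  expect_equal(bonferroni(rep(1, 4)), rep(1, 4))
  withr::with_seed(47, {
    p <- runif(20)
    adj <- bonferroni(p, 25)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_equal(order(adj), order(pmin(1, 25 * p)))
  })
  expect_error(bonferroni(c(0.2, 1.4)), "\\[0, 1\\]")
  expect_error(bonferroni(rep(0.1, 5), m = 3), "m must be")
})

test_that("roc_auc equals brute-force pair counting on random instances", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  withr::with_seed(48, {
    for (i in 1:200) {
      n <- sample(4:30, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
      scores <- round(rnorm(n), 1)  # rounding forces ties
      expect_equal(roc_auc(scores, labels), oracle_auc_pairs(scores, labels),
                   tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("complement-label symmetry of AUC for tie-free scores", {
  withr::with_seed(49, {
    scores <- rnorm(40)
    labels <- rbinom(40, 1, 0.4)
    labels[1:2] <- c(0, 1)
    expect_equal(roc_auc(scores, labels) + roc_auc(scores, 1 - labels), 1,
                 tolerance = 1e-12)
  })
})

test_that("two-sample tests hold their size under the null", {
  withr::with_seed(50, {
    n_sim <- 2000
    rej <- matrix(FALSE, n_sim, 3)
    for (i in seq_len(n_sim)) {
      x <- rnorm(30); y <- rnorm(30)
      rej[i, 1] <- wilcoxon_rank_sum(x, y)$p_value < 0.05
      rej[i, 2] <- ks_two_sample(x, y)$p_value < 0.05
      rej[i, 3] <- t_test_two_sample(x, y)$p_value < 0.05
    }
    rates <- colMeans(rej)
    expect_true(all(rates >= 0.03 & rates <= 0.07),
                info = paste("rejection rates:", paste(round(rates, 4), collapse = " ")))
  })
})
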