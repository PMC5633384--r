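four_class_fixture <- function(n_per = 50, seed = 71) {
  withr::with_seed(seed, {
    cls <- rep(c("TRG-E", "TRG-NE", "Shared-E", "Shared-NE"), each = n_per)
    tibble::tibble(
      gene = sprintf("g%03d", seq_along(cls)),
      conservation = ifelse(startsWith(cls, "TRG"), "TRG", "shared"),
      essential = endsWith(cls, "-E"),
      four_class = cls,
      trg_excluded_by_domain = FALSE)
  })
}

test_that("disorder comparison detects a planted ordered-fraction shift", {
  classes <- four_class_fixture(150)
  withr::with_seed(72, {
    of <- numeric(nrow(classes))
    of[classes$four_class == "TRG-E"] <- rbeta(150, 5.5, 4.5)    # mean 0.55
    of[classes$four_class == "TRG-NE"] <- rbeta(150, 7, 3)       # mean 0.70
    of[classes$four_class == "Shared-E"] <- rbeta(150, 8.5, 1.5) # mean 0.85
    of[classes$four_class == "Shared-NE"] <- rbeta(150, 8, 2)
  })
  features <- tibble::tibble(gene = classes$gene, ordered_fraction = of)
  res <- disorder_compare(features, classes)
  expect_true(all(res$tests$p_value < 0.01))
  expect_true(all(res$tests$method == "ks"))
  expect_equal(nrow(res$summary), 4)
  expect_true(all(res$summary$q50 >= 0 & res$summary$q50 <= 1))
})

test_that("identical disorder distributions give D = 0; equal-value groups flag degeneracy", {
  classes <- four_class_fixture(10)
  same <- tibble::tibble(gene = classes$gene,
                         ordered_fraction = rep(seq(0.1, 1, 0.1), 4))
  res <- disorder_compare(same, classes)
  expect_equal(res$tests$statistic, c(0, 0))
  flat <- tibble::tibble(gene = classes$gene, ordered_fraction = 0.5)
  resf <- disorder_compare(flat, classes)
  expect_true(all(resf$tests$degenerate))
  expect_error(disorder_compare(same[1:20, ], classes,
                                comparisons = list(c("TRG-E", "nope"))),
               "empty class")
})

test_that("coiled-coil comparison builds the right 2x2 tables", {
  classes <- four_class_fixture(25)
  # TRG-E: 20/5 with coil; TRG-NE: 10/15 -> the worked chi-square fixture
  cc <- c(rep(TRUE, 20), rep(FALSE, 5), rep(TRUE, 10), rep(FALSE, 15),
          rep(TRUE, 10), rep(FALSE, 15), rep(TRUE, 5), rep(FALSE, 20))
  features <- tibble::tibble(gene = classes$gene, has_coiled_coil = cc)
  res <- coiled_coil_compare(features, classes)
  first <- res$tests[res$tests$group2 == "TRG-NE", ]
  expect_equal(first$statistic, 8.333, tolerance = 1e-3)
  expect_equal(first$fraction1, 0.8)
  expect_equal(first$fraction2, 0.4)
  expect_equal(res$fractions$fraction[res$fractions$four_class == "TRG-E"], 0.8)
  # equal fractions -> statistic 0
  eqf <- tibble::tibble(gene = classes$gene,
                        has_coiled_coil = rep(rep(c(TRUE, FALSE), c(10, 15)), 4))
  expect_equal(coiled_coil_compare(eqf, classes)$tests$statistic, c(0, 0))
  # empty margin surfaces the class names
  none <- tibble::tibble(gene = classes$gene, has_coiled_coil = FALSE)
  expect_error(coiled_coil_compare(none, classes), "TRG-E vs TRG-NE")
})

test_that("planted coiled-coil enrichment is detected in most random draws", {
  classes <- four_class_fixture(150)
  hits <- withr::with_seed(73, {
    vapply(1:100, function(i) {
      cc <- logical(nrow(classes))
      cc[classes$four_class == "TRG-E"] <- rbinom(150, 1, 0.5) == 1
      cc[classes$four_class != "TRG-E"] <- rbinom(450, 1, 0.2) == 1
      features <- tibble::tibble(gene = classes$gene, has_coiled_coil = cc)
      all(coiled_coil_compare(features, classes)$tests$p_value < 0.01)
    }, logical(1))
  })
  expect_gte(mean(hits), 0.95)
})

test_that("class rate report reproduces printed TRG proportions exactly", {
  # two functional classes with the published counts: 7/200 and 36/231
  n1 <- 200; n2 <- 231
  genes <- sprintf("y%03d", seq_len(n1 + n2))
  rates <- tibble::tibble(
    gene = genes,
    dnds = c(rep(0.057, n1), rep(0.113, n2)),
    functional_class = c(rep("amino acid biosynthesis", n1),
                         rep("chromosome segregation", n2)))
  classes <- tibble::tibble(
    gene = genes,
    conservation = c(rep(c("TRG", "shared"), c(7, n1 - 7)),
                     rep(c("TRG", "shared"), c(36, n2 - 36))),
    essential = FALSE,
    four_class = "Shared-NE",
    trg_excluded_by_domain = FALSE)
  rep <- class_rate_analysis(rates, classes)
  aa <- rep[rep$functional_class == "amino acid biosynthesis", ]
  cs <- rep[rep$functional_class == "chromosome segregation", ]
  expect_equal(aa$trg_percent, 3.5)
  expect_equal(aa$n_trg, 7L)
  expect_equal(cs$trg_percent, 15.6)
  expect_equal(cs$n_trg, 36L)
  expect_equal(aa$median_dnds, 0.057)
  expect_equal(cs$median_dnds, 0.113)
  expect_equal(aa$direction, "lower")
  expect_equal(cs$direction, "higher")
})

test_that("the t-test background includes the class itself", {
  withr::with_seed(74, {
    genes <- sprintf("g%03d", 1:120)
    rates <- tibble::tibble(
      gene = genes,
      dnds = c(rgamma(40, 2, 20), rgamma(80, 2, 10)),
      functional_class = rep(c("slow", "other"), c(40, 80)))
  })
  classes <- tibble::tibble(gene = genes, conservation = "shared",
                            essential = FALSE, four_class = "Shared-NE",
                            trg_excluded_by_domain = FALSE)
  rep <- class_rate_analysis(rates, classes)
  slow <- rep[rep$functional_class == "slow", ]
  # against ALL genes (class included), not just the complement
  all_bg <- t_test_two_sample(rates$dnds[1:40], rates$dnds)
  excl_bg <- t_test_two_sample(rates$dnds[1:40], rates$dnds[41:120])
  expect_equal(slow$statistic, all_bg$statistic, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(slow$statistic, excl_bg$statistic)))
})

test_that("a class matching the background tests near p = 1 and unmatched genes drop", {
  withr::with_seed(75, {
    genes <- sprintf("g%03d", 1:200)
    d <- rgamma(200, 2, 15)
    rates <- tibble::tibble(gene = genes, dnds = d,
                            functional_class = rep(c("a", "b"), 100))
  })
  classes <- tibble::tibble(gene = genes[1:190], conservation = "shared",
                            essential = FALSE, four_class = "Shared-NE",
                            trg_excluded_by_domain = FALSE)
  expect_message(rep <- class_rate_analysis(rates, classes), "dropping 10")
  expect_true(all(rep$p_value > 0.2))
  expect_true(all(rep$trg_proportion >= 0 & rep$trg_proportion <= 1))
  expect_true(all(rep$median_dnds >= min(d) & rep$median_dnds <= max(d)))
  # no randomness in the report itself
  rep2 <- suppressMessages(class_rate_analysis(rates, classes))
  expect_identical(rep, rep2)
})

test_that("essential-TRG fraction is only reported for classes with enough TRGs", {
  genes <- sprintf("g%02d", 1:60)
  rates <- tibble::tibble(gene = genes, dnds = rep(c(0.05, 0.1), 30),
                          functional_class = rep(c("rich", "poor"), c(40, 20)))
  classes <- tibble::tibble(
    gene = genes,
    conservation = c(rep("TRG", 25), rep("shared", 15), rep("TRG", 5),
                     rep("shared", 15)),
    essential = c(rep(TRUE, 10), rep(FALSE, 50)),
    four_class = "x", trg_excluded_by_domain = FALSE)
  rep <- class_rate_analysis(rates, classes, min_trg = 20)
  rich <- rep[rep$functional_class == "rich", ]
  expect_equal(rich$essential_trg_fraction, 10 / 25)
  expect_true(is.na(rep$essential_trg_fraction[rep$functional_class == "poor"]))
})
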