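make_lineage <- function() {
  tibble::tibble(
    taxon = c("t_focal", "t_in1", "t_out1", "t_out2"),
    in_lineage = c(TRUE, TRUE, FALSE, FALSE),
    genome_label = c("Focal", "Sister", "Cousin", "Distant"),
    phylo_rank = 1:4
  )
}

hit <- function(gene, taxon, e, len, qlen = 100) {
  tibble::tibble(query_gene = gene, subject_id = paste0(taxon, "_s"),
                 e_value = e, align_length = len, query_length = qlen,
                 subject_taxon = taxon)
}

test_that("the homology rule is applied with strict inequalities", {
  lin <- make_lineage()
  hits <- dplyr::bind_rows(
    hit("g_shared", "t_out1", 1e-7, 40),    # qualifies: shared
    hit("g_trg", "t_out1", 1e-3, 40),       # E too weak
    hit("g_trg", "t_out2", 1e-8, 10),       # coverage too low
    hit("g_inonly", "t_in1", 1e-50, 90),    # in-lineage hits never disqualify
    hit("g_edge", "t_out1", 1e-6, 31),      # E exactly at cutoff: not < 1e-6
    hit("g_edge2", "t_out1", 1e-8, 30)      # coverage exactly 0.30: not > 0.30
  )
  out <- classify_trg(hits, lin)
  cons <- setNames(out$conservation, out$gene)
  expect_equal(cons[["g_shared"]], "shared")
  expect_equal(cons[["g_trg"]], "TRG")
  expect_equal(cons[["g_inonly"]], "TRG")
  expect_equal(cons[["g_edge"]], "TRG")
  expect_equal(cons[["g_edge2"]], "TRG")
  expect_false(any(out$trg_excluded_by_domain))
})

test_that("a domain re-labels a would-be TRG as shared with the flag set", {
  lin <- make_lineage()
  hits <- hit("g1", "t_in1", 1e-30, 80)
  domains <- tibble::tibble(gene = c("g1", "g2"), domains = c("IPR000001", ""))
  out <- classify_trg(hits, lin, domains, genes = c("g1", "g2"))
  expect_equal(out$conservation[out$gene == "g1"], "shared")
  expect_true(out$trg_excluded_by_domain[out$gene == "g1"])
  expect_equal(out$conservation[out$gene == "g2"], "TRG")
  # the flag implies shared, never TRG
  expect_true(all(out$conservation[out$trg_excluded_by_domain] == "shared"))
})

test_that("catalog genes with no hits are TRGs; unknown taxa and bad coverage error", {
  lin <- make_lineage()
  hits <- hit("g1", "t_out1", 1e-9, 50)
  out <- classify_trg(hits, lin, genes = c("g1", "g_nohit"))
  expect_equal(out$conservation[out$gene == "g_nohit"], "TRG")
  expect_error(classify_trg(hit("g", "t_unknown", 1e-9, 50), lin), "t_unknown")
  expect_error(classify_trg(hit("g", "t_out1", 1e-9, 150, qlen = 100), lin),
               "coverage > 1")
})

test_that("classification is order-independent and monotone in the cutoffs", {
  lin <- make_lineage()
  withr::with_seed(7, {
    hits <- dplyr::bind_rows(lapply(1:60, function(i) {
      hit(paste0("g", sample(1:30, 1)),
          sample(lin$taxon, 1),
          10^runif(1, -12, -1),
          sample(10:95, 1))
    }))
  })
  genes <- paste0("g", 1:30)
  base <- classify_trg(hits, lin, genes = genes)
  shuffled <- classify_trg(hits[sample(nrow(hits)), ], lin, genes = genes)
  expect_equal(dplyr::arrange(base, gene), dplyr::arrange(shuffled, gene))
  # tightening either cutoff never shrinks the TRG set
  trgs <- function(e_max, min_cov) {
    out <- classify_trg(hits, lin, genes = genes, e_max = e_max, min_cov = min_cov)
    out$gene[out$conservation == "TRG"]
  }
  t0 <- trgs(1e-6, 0.30)
  expect_true(all(t0 %in% trgs(1e-8, 0.30)))
  expect_true(all(t0 %in% trgs(1e-6, 0.50)))
})

test_that("relaxed_scan reproduces the strict call and is monotone along each axis", {
  lin <- make_lineage()
  # 4 TRGs; one has a weak out-lineage hit visible only at relaxed cutoffs
  hits <- dplyr::bind_rows(
    hit("trg1", "t_in1", 1e-20, 80),
    hit("trg2", "t_in1", 1e-20, 80),
    hit("trg3", "t_in1", 1e-20, 80),
    hit("trg4", "t_out1", 1e-4, 15),   # weak: e 1e-4, coverage 0.15
    hit("sh1", "t_out2", 1e-30, 70)
  )
  scan <- relaxed_scan(hits, lin,
                       coverage_grid = c(0.30, 0.10, 0.05),
                       e_grid = c(1e-6, 1e-2))
  strict <- dplyr::filter(scan, cov_cutoff == 0.30, e_cutoff == 1e-6)
  expect_equal(strict$frac_unmatched, 1)
  relaxed <- dplyr::filter(scan, cov_cutoff == 0.05, e_cutoff == 1e-2)
  expect_equal(relaxed$frac_unmatched, 0.75)  # 3 of the 4 TRGs still unmatched
  # monotone: fraction never increases when either cutoff is relaxed
  by_cov <- scan |> dplyr::arrange(e_cutoff, dplyr::desc(cov_cutoff)) |>
    dplyr::group_by(e_cutoff) |>
    dplyr::summarise(mono = all(diff(frac_unmatched) <= 0))
  expect_true(all(by_cov$mono))
  by_e <- scan |> dplyr::arrange(cov_cutoff, e_cutoff) |>
    dplyr::group_by(cov_cutoff) |>
    dplyr::summarise(mono = all(diff(frac_unmatched) <= 0))
  expect_true(all(by_e$mono))
})

test_that("best_hit_profile orders genomes by rank, floors absent hits at 0 and clamps E=0", {
  lin <- make_lineage()
  hits <- dplyr::bind_rows(
    hit("g1", "t_focal", 0, 99),       # E = 0 clamped
    hit("g1", "t_in1", 1e-50, 80),
    hit("g1", "t_in1", 1e-20, 60),     # best per genome wins
    hit("g2", "t_out2", 1e-5, 50)
  )
  prof <- best_hit_profile(hits, lin, genes = c("g1", "g_none"))
  g1 <- dplyr::filter(prof, gene == "g1")
  expect_equal(g1$phylo_rank, 1:4)
  expect_equal(g1$neg_log10_e, c(180, 50, 0, 0))
  gn <- dplyr::filter(prof, gene == "g_none")
  expect_equal(gn$neg_log10_e, rep(0, 4))
})

test_that("four classes are the conservation x essentiality cross", {
  cons <- tibble::tibble(gene = paste0("g", 1:6),
                         conservation = c("TRG", "TRG", "shared", "shared",
                                          "TRG", "shared"),
                         trg_excluded_by_domain = FALSE)
  cls <- assign_four_classes(cons, essential_genes = c("g1", "g3"))
  expect_equal(cls$four_class,
               c("TRG-E", "TRG-NE", "Shared-E", "Shared-NE", "TRG-NE",
                 "Shared-NE"))
  none <- assign_four_classes(cons, character())
  expect_true(all(endsWith(none$four_class, "-NE")))
  expect_error(assign_four_classes(cons, "g_absent"), "absent from the catalog")
  counts <- four_class_counts(cls)
  expect_equal(counts$n, c(1L, 2L, 1L, 2L))
  expect_equal(sum(counts$n), nrow(cons))
})

test_that("hit tables and lineage tables round-trip through their readers", {
  dir <- withr::local_tempdir()
  hp <- file.path(dir, "hits.tsv")
  writeLines(c(
    "# blast outfmt 6 extension",
    "qseqid\tsseqid\tevalue\tlength\tqlen\tstaxid",
    "g1\ts1\t1e-08\t50\t100\tt_out1",
    "g2\ts2\t0.001\t20\t80\tt_in1"
  ), hp)
  h <- read_homology_hits(hp)
  expect_equal(h$query_gene, c("g1", "g2"))
  expect_equal(h$e_value, c(1e-8, 1e-3))
  # headerless variant parses identically
  hp2 <- file.path(dir, "hits2.tsv")
  writeLines(c("g1\ts1\t1e-08\t50\t100\tt_out1"), hp2)
  expect_equal(read_homology_hits(hp2)$align_length, 50L)

  lp <- file.path(dir, "lineage.tsv")
  writeLines(c("t_focal\t1\tFocal\t1", "t_out1\t0\tCousin\t2"), lp)
  l <- read_lineage(lp)
  expect_equal(l$in_lineage, c(TRUE, FALSE))

  dp <- file.path(dir, "domains.tsv")
  writeLines(c("g1\tIPR1,IPR2", "g2\t"), dp)
  d <- read_domains(dp)
  expect_equal(d$domains, c("IPR1,IPR2", ""))
})
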