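# Erdos-Renyi-style planted-partition graph over named nodes
planted_partition_edges <- function(sizes, p_in, p_out, seed) {
  n <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)
  nodes <- sprintf("n%03d", seq_len(n))
  pairs <- utils::combn(n, 2)
  withr::with_seed(seed, {
    same <- block[pairs[1, ]] == block[pairs[2, ]]
    keep <- stats::rbinom(ncol(pairs), 1, ifelse(same, p_in, p_out)) == 1
  })
  list(edges = tibble::tibble(gene_a = nodes[pairs[1, keep]],
                              gene_b = nodes[pairs[2, keep]]),
       truth = stats::setNames(block, nodes))
}

test_that("edge canonicalization merges reverses/duplicates and drops self-loops", {
  raw <- tibble::tibble(gene_a = c("a", "b", "a", "c"),
                        gene_b = c("b", "a", "a", "d"))
  expect_message(net <- as_network(raw), "self-loop")
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$nodes, c("a", "b", "c", "d"))
  deg <- network_degrees(net)
  expect_equal(deg$degree[deg$gene == "a"], 1)
})

test_that("degrees: triangle all 2, star hub 5 and leaves 1", {
  tri <- as_network(tibble::tibble(gene_a = c("a", "b", "c"),
                                   gene_b = c("b", "c", "a")))
  expect_equal(network_degrees(tri)$degree, rep(2L, 3))
  star <- as_network(tibble::tibble(gene_a = "hub",
                                    gene_b = paste0("leaf", 1:5)))
  deg <- network_degrees(star)
  expect_equal(deg$degree[deg$gene == "hub"], 5L)
  expect_equal(sort(deg$degree), c(rep(1L, 5), 5L))
})

test_that("degree_compare detects a planted degree bias in essential TRGs", {
  pp <- planted_partition_edges(c(30, 30), p_in = 0.5, p_out = 0.5, seed = 61)
  # wire 12 extra hubs: TRG-E genes connect to many extra partners
  nodes <- names(pp$truth)
  classes <- tibble::tibble(
    gene = nodes,
    conservation = "TRG",
    essential = seq_along(nodes) <= 12,
    four_class = ifelse(seq_along(nodes) <= 12, "TRG-E", "TRG-NE"),
    trg_excluded_by_domain = FALSE)
  classes$four_class[41:60] <- "Shared-E"
  extra <- tidyr::expand_grid(gene_a = nodes[1:12], gene_b = nodes[13:55])
  net <- as_network(dplyr::bind_rows(pp$edges, extra))
  res <- degree_compare(net, classes)
  tt <- res$tests
  expect_lt(tt$p_value[tt$group2 == "TRG-NE"], 0.01)
  expect_lt(tt$p_value[tt$group2 == "Shared-E"], 0.01)
  expect_true(all(res$degrees$degree >= 1))
})

test_that("MCL separates disjoint components and keeps K2 together", {
  two_tri <- as_network(tibble::tibble(
    gene_a = c("a", "b", "c", "x", "y", "z"),
    gene_b = c("b", "c", "a", "y", "z", "x")))
  mcl <- mcl_cluster(two_tri)
  expect_equal(nrow(mcl$clusters), 2)
  mem <- mcl$membership
  expect_equal(length(unique(mem$cluster_id[mem$gene %in% c("a", "b", "c")])), 1)
  expect_equal(length(unique(mem$cluster_id[mem$gene %in% c("x", "y", "z")])), 1)
  k2 <- mcl_cluster(as_network(tibble::tibble(gene_a = "p", gene_b = "q")))
  expect_equal(nrow(k2$clusters), 1)
  expect_equal(k2$membership$cluster_id, c(1L, 1L))
  expect_error(mcl_cluster(two_tri, inflation = 1), "inflation")
})

test_that("MCL output is a partition and flow stays column-stochastic", {
  pp <- planted_partition_edges(c(25, 25, 25, 25), 0.3, 0.01, seed = 62)
  net <- as_network(pp$edges)
  mcl <- mcl_cluster(net)
  expect_setequal(mcl$membership$gene, net$nodes)
  expect_equal(anyDuplicated(mcl$membership$gene), 0)
  expect_equal(sum(mcl$clusters$size), length(net$nodes))
  expect_lt(mcl$max_col_deviation, 1e-12)
  # cluster ids dense from 1 and ordered by decreasing size
  expect_equal(sort(unique(mcl$membership$cluster_id)),
               seq_len(nrow(mcl$clusters)))
  expect_true(all(diff(mcl$clusters$size) <= 0))
})

test_that("MCL recovers a planted partition with high pair agreement", {
  pp <- planted_partition_edges(c(25, 25, 25, 25), 0.3, 0.01, seed = 63)
  mcl <- mcl_cluster(as_network(pp$edges), inflation = 1.5)
  found <- mcl$membership$cluster_id[match(names(pp$truth),
                                           mcl$membership$gene)]
  agree <- oracle_pair_agreement(found, pp$truth)
  expect_gte(agree, 0.9)
  skip_if_not_installed("mclust")
  expect_equal(agree, mclust::adjustedRandIndex(found, pp$truth),
               tolerance = 1e-12)
})

test_that("cluster count is non-increasing as inflation decreases", {
  pp <- planted_partition_edges(c(25, 25, 25, 25), 0.3, 0.01, seed = 64)
  net <- as_network(pp$edges)
  counts <- vapply(c(1.2, 1.5, 2.0, 5.0),
                   function(i) nrow(mcl_cluster(net, inflation = i)$clusters),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("pruning leaves small-graph partitions unchanged", {
  pp <- planted_partition_edges(c(20, 20, 20), 0.4, 0.02, seed = 65)
  net <- as_network(pp$edges)
  on <- mcl_cluster(net, prune_below = 1e-5)
  off <- mcl_cluster(net, prune_below = 0)
  expect_equal(on$membership, off$membership)
})

test_that("cluster enrichment matches the exact hypergeometric oracle", {
  # one 40-node cluster holding all 10 annotated genes in a 400-node universe
  nodes <- sprintf("g%03d", 1:400)
  mcl <- structure(list(
    membership = tibble::tibble(
      gene = nodes, cluster_id = rep(1:10, each = 40)),
    clusters = tibble::tibble(cluster_id = 1:10, size = 40L)),
    class = "trg_mcl")
  annotated <- nodes[1:10]  # all inside cluster 1
  res <- enrich_clusters(mcl, annotated, min_size = 31)
  top <- res[res$cluster_id == 1, ]
  expect_equal(top$p_raw, hypergeom_tail(400, 10, 40, 10), tolerance = 1e-15)
  expect_equal(top$p_raw, oracle_hypergeom_tail(400, 10, 40, 10),
               tolerance = 1e-12)
  expect_equal(unique(res$m_tests), 10L)
  expect_equal(res$p_bonferroni, pmin(1, res$p_raw * 10))
  expect_true(all(res$p_bonferroni >= res$p_raw & res$p_bonferroni <= 1))
  # saturation: annotated = universe -> all p_raw = 1
  sat <- enrich_clusters(mcl, nodes)
  expect_equal(sat$p_raw, rep(1, 10))
  # min_size filter excludes everything -> empty with warning
  expect_warning(none <- enrich_clusters(mcl, annotated, min_size = 41),
                 "min_size")
  expect_equal(nrow(none), 0)
  expect_error(enrich_clusters(mcl, "not_a_node"), "universe")
})

test_that("set enrichment: perfect overlap minimal, zero overlap p = 1", {
  universe <- sprintf("u%02d", 1:20)
  members <- universe[1:10]
  annotations <- list(
    perfect = members,
    partial = universe[c(1:8, 11, 12)],   # k=8, K=10
    none = universe[11:15])
  res <- enrich_sets(members, annotations, universe)
  expect_equal(res$set_id[1], "perfect")
  expect_equal(res$p_raw[res$set_id == "none"], 1)
  expect_equal(res$p_raw[res$set_id == "partial"],
               oracle_hypergeom_tail(20, 10, 10, 8), tolerance = 1e-12)
  expect_message(
    skip <- enrich_sets(members, c(annotations, list(out = c("zz1", "zz2"))),
                        universe),
    "disjoint")
  expect_false("out" %in% skip$set_id)
  expect_equal(unique(skip$m_tests), 3L)
})
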