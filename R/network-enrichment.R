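#' Build a simple undirected network from an edge tibble
#'
#' @param edges Tibble with columns `gene_a`, `gene_b` and optional
#'   `weight` (default 1); self-loops dropped, duplicate and reversed
#'   pairs merged (see [read_edge_list()]).
#' @return Object of class `trg_network`: list with `nodes` (character)
#'   and `edges` (canonical tibble).
#' @export
as_network <- function(edges) {
  if (!"weight" %in% names(edges)) edges$weight <- 1
  edges <- tidy_edges(edges[c("gene_a", "gene_b", "weight")])
  structure(list(nodes = sort(union(edges$gene_a, edges$gene_b)),
                 edges = edges),
            class = "trg_network")
}

#' @export
print.trg_network <- function(x, ...) {
  cat("Undirected network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

# dense weighted adjacency matrix of a trg_network
adjacency_matrix <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  ia <- match(net$edges$gene_a, net$nodes)
  ib <- match(net$edges$gene_b, net$nodes)
  A[cbind(ia, ib)] <- net$edges$weight
  A[cbind(ib, ia)] <- net$edges$weight
  A
}

#' Node degrees (distinct neighbors)
#'
#' @param net A `trg_network`.
#' @return Tibble with columns `gene`, `degree`.
#' @export
network_degrees <- function(net) {
  tab <- table(c(net$edges$gene_a, net$edges$gene_b))
  tibble::tibble(gene = net$nodes,
                 degree = as.integer(tab[net$nodes]))
}

#' Compare protein-interaction degrees between gene classes
#'
#' Degrees are counts of distinct interaction partners; only genes with at
#' least one interaction (i.e. present in the network) enter.  Runs
#' Wilcoxon rank-sum tests for essential vs nonessential restricted
#' proteins and essential restricted vs shared essential proteins.
#'
#' @param net A `trg_network`.
#' @param classes Tibble from [assign_four_classes()].
#' @return List with `degrees` (tibble `gene`, `degree`, `four_class`),
#'   `tests` and `summary` as in [context_group_tests()].
#' @export
degree_compare <- function(net, classes) {
  deg <- network_degrees(net) |>
    dplyr::filter(.data$degree >= 1)
  joined <- dplyr::inner_join(deg, classes[c("gene", "four_class")],
                              by = "gene")
  if (nrow(joined) == 0) {
    stop("degree_compare(): no network node matches the class table")
  }
  res <- context_group_tests(
    dplyr::transmute(joined, gene = .data$gene, value = .data$degree),
    classes)
  list(degrees = joined, tests = res$tests, summary = res$summary)
}

#' Markov Clustering (MCL) of an undirected network
#'
#' Classic MCL: self-loops (weight 1) are added to the adjacency matrix,
#' columns are normalized to a stochastic flow matrix, and expansion
#' (matrix power) alternates with inflation (entrywise power followed by
#' column renormalization) until the flow stops changing.  Entries below
#' `prune_below` are zeroed (then columns renormalized) to keep the flow
#' sparse.  Clusters are read off the attractors: rows with positive
#' diagonal mass; each node joins the attractor holding the largest share
#' of its column (ties to the lowest-numbered attractor).
#'
#' @param net A `trg_network`.
#' @param inflation Inflation exponent (> 1; default 1.5 — smaller values
#'   give coarser clusters).
#' @param expansion Matrix-power for expansion (default 2).
#' @param prune_below Prune threshold for small flow entries
#'   (default 1e-5).
#' @param max_iter Iteration cap (default 100); a warning is raised and
#'   the current state returned if the flow has not converged.
#' @return Object of class `trg_mcl`: list with `membership` (tibble
#'   `gene`, `cluster_id`), `clusters` (tibble `cluster_id`, `size`),
#'   `parameters`, `iterations`, `converged`, `max_col_deviation` (worst
#'   departure from column-stochasticity seen after any renormalization).
#' @export
mcl_cluster <- function(net, inflation = 1.5, expansion = 2,
                        prune_below = 1e-5, max_iter = 100) {
  if (inflation <= 1) stop("mcl_cluster(): inflation must be > 1")
  A <- adjacency_matrix(net)
  diag(A) <- 1
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  iter <- 0
  max_dev <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    M_old <- M
    for (e in seq_len(expansion - 1)) M <- M %*% M_old  # M_old^expansion
    M <- M^inflation
    # prune small flow, but never a column's largest entry (a fully
    # pruned column would lose its probability mass)
    keep_i <- max.col(t(M))
    kept <- M[cbind(keep_i, seq_len(ncol(M)))]
    M[M < prune_below] <- 0
    M[cbind(keep_i, seq_len(ncol(M)))] <- kept
    M <- sweep(M, 2, colSums(M), "/")
    max_dev <- max(max_dev, max(abs(colSums(M) - 1)))
    if (max(abs(M - M_old)) < 1e-8) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("mcl_cluster(): flow not converged after ", max_iter,
            " iterations; returning current state")
  }
  attractors <- which(diag(M) > 0)
  if (length(attractors) == 0) attractors <- seq_along(net$nodes)
  owner <- apply(M[attractors, , drop = FALSE], 2, which.max)
  raw_id <- attractors[owner]
  # renumber dense from 1, ordered by decreasing cluster size
  sizes <- sort(table(raw_id), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  membership <- tibble::tibble(
    gene = net$nodes,
    cluster_id = as.integer(relabel[as.character(raw_id)]))
  structure(list(
    membership = membership,
    clusters = dplyr::count(membership, .data$cluster_id, name = "size"),
    parameters = list(inflation = inflation, expansion = expansion,
                      prune_below = prune_below, iterations = iter),
    iterations = iter, converged = converged,
    max_col_deviation = max_dev
  ), class = "trg_mcl")
}

#' @export
print.trg_mcl <- function(x, ...) {
  cat("MCL clustering:", nrow(x$clusters), "clusters over",
      nrow(x$membership), "nodes (inflation",
      x$parameters$inflation, ",", x$iterations, "iterations)\n")
  invisible(x)
}

#' Hypergeometric enrichment of an annotated gene set in network clusters
#'
#' Tests every cluster of at least `min_size` members for
#' over-representation of an annotated gene set (e.g. the TRGs) with the
#' hypergeometric upper tail, Bonferroni-corrected over the number of
#' clusters tested.  The universe is the clustered node set.
#'
#' @param mcl A `trg_mcl` object.
#' @param annotated Character vector of annotated genes (subset of the
#'   clustered nodes).
#' @param min_size Smallest cluster size tested (default 31, i.e.
#'   clusters with more than 30 members).
#' @return Tibble with columns `cluster_id`, `n` (cluster size), `k`
#'   (annotated members), `K` (annotated total), `N` (universe size),
#'   `p_raw`, `p_bonferroni`, `m_tests`, sorted by `p_raw`.  Empty (with
#'   a warning) when no cluster reaches `min_size`.
#' @export
enrich_clusters <- function(mcl, annotated, min_size = 31) {
  universe <- mcl$membership$gene
  stray <- setdiff(annotated, universe)
  if (length(stray) > 0) {
    stop("enrich_clusters(): annotated genes outside the clustered ",
         "universe: ", paste(utils::head(stray, 5), collapse = ", "))
  }
  big <- mcl$clusters$cluster_id[mcl$clusters$size >= min_size]
  if (length(big) == 0) {
    warning("enrich_clusters(): no cluster reaches min_size = ", min_size)
    return(tibble::tibble(cluster_id = integer(), n = integer(),
                          k = integer(), K = integer(), N = integer(),
                          p_raw = numeric(), p_bonferroni = numeric(),
                          m_tests = integer()))
  }
  N <- length(universe)
  K <- length(annotated)
  res <- purrr::map_dfr(big, function(cid) {
    members <- mcl$membership$gene[mcl$membership$cluster_id == cid]
    k <- length(intersect(members, annotated))
    tibble::tibble(cluster_id = cid, n = length(members), k = k,
                   K = K, N = N,
                   p_raw = hypergeom_tail(N, K, length(members), k))
  })
  res$m_tests <- length(big)
  res$p_bonferroni <- bonferroni(res$p_raw, length(big))
  dplyr::arrange(res, .data$p_raw)
}

#' Hypergeometric enrichment of annotations in one gene set
#'
#' For a set of genes of interest (e.g. the members of a network cluster),
#' tests each annotation term of a collection for over-representation
#' against a gene universe, Bonferroni-corrected over the number of terms
#' with any presence in the universe (terms entirely outside the universe
#' are skipped with a note).
#'
#' @param member_genes Character vector: the gene set of interest.
#' @param annotations Named list of character vectors (term -> genes).
#' @param universe Character vector: the background gene universe;
#'   `member_genes` must be a subset.
#' @return Tibble with columns `set_id`, `k`, `n`, `K`, `N`, `p_raw`,
#'   `p_bonferroni`, `m_tests`, sorted by `p_raw`.
#' @export
enrich_sets <- function(member_genes, annotations, universe) {
  stray <- setdiff(member_genes, universe)
  if (length(stray) > 0) {
    stop("enrich_sets(): member genes outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  }
  in_universe <- lapply(annotations, intersect, universe)
  skipped <- names(annotations)[lengths(in_universe) == 0]
  if (length(skipped) > 0) {
    message("enrich_sets(): skipping ", length(skipped),
            " annotation(s) disjoint from the universe")
  }
  keep <- names(annotations)[lengths(in_universe) > 0]
  N <- length(universe)
  n <- length(member_genes)
  res <- purrr::map_dfr(keep, function(term) {
    K <- length(in_universe[[term]])
    k <- length(intersect(member_genes, in_universe[[term]]))
    tibble::tibble(set_id = term, k = k, n = n, K = K, N = N,
                   p_raw = hypergeom_tail(N, K, n, k))
  })
  res$m_tests <- length(keep)
  res$p_bonferroni <- bonferroni(res$p_raw, length(keep))
  dplyr::arrange(res, .data$p_raw)
}
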