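#' Run the full TRG analysis pipeline
#'
#' Orchestrates every stage in dependency order: TRG classification,
#' coexpression pathway features, essentiality classification, genomic
#' context, network clustering and enrichment, protein features, and
#' evolutionary rates.  Only classification is mandatory; any stage whose
#' inputs are absent is skipped with a logged reason rather than
#' aborting.
#'
#' The configuration is a named list (or a YAML file with the same
#' structure) with two blocks: `inputs` (file paths: `hits`, `lineage`,
#' `essential` required; `domains`, `loci`, `expr_levels`,
#' `expr_manifest`, `pathways`, `tracks` (named list of bedGraph paths),
#' `ppi`, `protein_features`, `rates` optional) and `params`
#' (`e_max = 1e-6`, `min_cov = 0.30`, `min_support = 3`, `flank = 5000`,
#' `inflation = 1.5`, `min_cluster_size = 31`, `alpha = 0.5`,
#' `folds = 5`, `seed = 1`).
#'
#' @param config Named list or path to a YAML file.
#' @param out_dir Optional directory for per-stage TSVs and
#'   `report.json`.
#' @return A `trg_report` (see [run_stages()]).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  inputs <- config$inputs
  params <- config$params %||% list()
  need <- setdiff(c("hits", "lineage", "essential"), names(inputs))
  if (length(need) > 0) {
    stop("run_pipeline(): missing mandatory input(s): ",
         paste(need, collapse = ", "))
  }
  for (f in unlist(inputs)) {
    if (!file.exists(f)) stop("run_pipeline(): input file not found: ", f)
  }
  data <- list(
    hits = read_homology_hits(inputs$hits),
    lineage = read_lineage(inputs$lineage),
    essential_genes = read_essential_genes(inputs$essential))
  if (!is.null(inputs$domains)) data$domains <- read_domains(inputs$domains)
  if (!is.null(inputs$loci)) data$loci <- read_bed6(inputs$loci)
  if (!is.null(inputs$expr_levels)) {
    data$expr_levels <- read_gene_values(inputs$expr_levels)
  }
  if (!is.null(inputs$expr_manifest)) {
    data$datasets <- read_expression_manifest(inputs$expr_manifest)
  }
  if (!is.null(inputs$pathways)) data$pathways <- read_gene_sets(inputs$pathways)
  if (!is.null(inputs$tracks)) {
    data$tracks <- lapply(inputs$tracks, read_bedgraph)
  }
  if (!is.null(inputs$ppi)) data$ppi_edges <- read_edge_list(inputs$ppi)
  if (!is.null(inputs$protein_features)) {
    data$protein_features <- read_protein_features(inputs$protein_features)
  }
  if (!is.null(inputs$rates)) data$rates <- read_rates(inputs$rates)
  run_stages(data, params, out_dir = out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the analysis stages on in-memory inputs
#'
#' The engine behind [run_pipeline()]; also accepts a [generate_world()]
#' object directly, which is convenient for simulation studies.
#'
#' @param data Named list of input tibbles (`hits`, `lineage`,
#'   `essential_genes` required; `domains`, `loci`, `expr_levels`,
#'   `datasets`, `pathways`, `tracks`, `ppi_edges`, `protein_features`,
#'   `rates` optional), or a `trg_world`.
#' @param params Named list of thresholds (see [run_pipeline()]).
#' @param out_dir Optional output directory.
#' @return Object of class `trg_report`: list with one element per stage
#'   (`classification`, `coexpression`, `classifier`, `context`,
#'   `network`, `protein_features`, `rates`), `skipped` (named reasons),
#'   and `provenance`.
#' @export
run_stages <- function(data, params = list(), out_dir = NULL) {
  if (inherits(data, "trg_world")) data <- world_inputs(data)
  p <- utils::modifyList(list(
    e_max = 1e-6, min_cov = 0.30, min_support = 3, flank = 5000,
    inflation = 1.5, min_cluster_size = 31, alpha = 0.5, folds = 5,
    seed = 1), params)
  report <- list(stages = list(), skipped = list())

  # --- classification (mandatory) ------------------------------------
  gene_catalog <- unique(c(data$hits$query_gene, data$domains$gene,
                           data$essential_genes))
  conservation <- classify_trg(data$hits, data$lineage, data$domains,
                               genes = gene_catalog,
                               e_max = p$e_max, min_cov = p$min_cov)
  classes <- assign_four_classes(conservation, data$essential_genes)
  trgs <- classes$gene[classes$conservation == "TRG"]
  report$classification <- list(classes = classes,
                                counts = four_class_counts(classes))

  # --- coexpression features ----------------------------------------
  if (!is.null(data$datasets) && !is.null(data$pathways)) {
    measured <- unique(unlist(lapply(data$datasets, function(d) d$genes)))
    mean_z <- pairwise_mean_z(data$datasets, intersect(trgs, measured),
                              genes = unique(unlist(data$pathways)))
    features <- pathway_features(mean_z, data$pathways,
                                 min_support = p$min_support)
    per_pathway <- feature_class_tests(features, classes)
    report$coexpression <- list(features = features,
                                pathway_tests = per_pathway)
    # --- essentiality classifier -------------------------------------
    X <- features_matrix(features, impute = "column_mean")
    y <- classes$essential[match(rownames(X), classes$gene)]
    if (length(unique(y)) == 2 && min(table(y)) >= p$folds) {
      cv <- cross_validated_auc(X, y, k_folds = p$folds, alpha = p$alpha,
                                seed = p$seed)
      report$classifier <- list(
        cv = cv, cv_auc = cv$cv_auc, chosen_lambda = cv$chosen_lambda,
        single_feature = single_feature_auc(X, y, k_folds = p$folds,
                                            seed = p$seed),
        coefficients = tidy(cv$model))
    } else {
      report$skipped$classifier <- "too few essential TRGs to stratify folds"
    }
  } else {
    report$skipped$coexpression <- "skipped: no expression datasets or no pathways"
    report$skipped$classifier <- "skipped: requires coexpression features"
  }

  # --- genomic context -----------------------------------------------
  if (!is.null(data$loci) && !is.null(data$expr_levels)) {
    nb <- neighbor_expression(data$loci, data$expr_levels)
    self_tests <- context_group_tests(data$expr_levels, classes)
    nb_tests <- purrr::map(split(nb, nb$offset), function(d) {
      context_group_tests(
        dplyr::summarise(dplyr::group_by(d, .data$gene),
                         value = mean(.data$value), .groups = "drop"),
        classes)
    })
    report$context <- list(gene_itself = self_tests, neighbors = nb_tests)
  } else {
    report$skipped$context <- "skipped: no loci or no expression levels"
  }
  if (!is.null(data$loci) && !is.null(data$tracks)) {
    chromatin <- purrr::map(data$tracks, function(tr) {
      med <- window_median_signal(data$loci, tr, flank = p$flank)
      context_group_tests(
        dplyr::transmute(med, gene = .data$gene,
                         value = .data$median_signal), classes)
    })
    report$context$chromatin <- chromatin
  } else if (is.null(data$tracks)) {
    report$skipped$chromatin <- "skipped: no chromatin tracks"
  }

  # --- network --------------------------------------------------------
  if (!is.null(data$ppi_edges)) {
    net <- as_network(data$ppi_edges)
    degrees <- degree_compare(net, classes)
    mcl <- mcl_cluster(net, inflation = p$inflation)
    enrichment <- enrich_clusters(mcl, intersect(trgs, net$nodes),
                                  min_size = p$min_cluster_size)
    report$network <- list(degrees = degrees, mcl = mcl,
                           enrichment = enrichment,
                           n_significant = sum(enrichment$p_bonferroni < 0.05))
  } else {
    report$skipped$network <- "skipped: no edges"
  }

  # --- protein features ----------------------------------------------
  if (!is.null(data$protein_features)) {
    report$protein_features <- list(
      disorder = disorder_compare(data$protein_features, classes),
      coiled_coil = coiled_coil_compare(data$protein_features, classes))
  } else {
    report$skipped$protein_features <- "skipped: no protein feature table"
  }

  # --- evolutionary rates --------------------------------------------
  if (!is.null(data$rates)) {
    report$rates <- class_rate_analysis(data$rates, classes)
  } else {
    report$skipped$rates <- "skipped: no rate table"
  }

  report$provenance <- list(
    params = p, seed = p$seed,
    package_version = as.character(utils::packageVersion("trgtools")))
  report <- structure(report, class = "trg_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# per-pathway Wilcoxon of feature values between essential and
# nonessential TRGs (the panel-B style table)
feature_class_tests <- function(features, classes) {
  joined <- dplyr::inner_join(
    features, classes[c("gene", "four_class")],
    by = c(target = "gene"))
  joined |>
    dplyr::filter(!is.na(.data$value),
                  .data$four_class %in% c("TRG-E", "TRG-NE")) |>
    dplyr::group_by(.data$set_id) |>
    dplyr::group_modify(function(d, key) {
      a <- d$value[d$four_class == "TRG-E"]
      b <- d$value[d$four_class == "TRG-NE"]
      if (length(a) == 0 || length(b) == 0) {
        return(tibble::tibble(median_trg_e = NA_real_,
                              median_trg_ne = NA_real_,
                              statistic = NA_real_, p_value = NA_real_))
      }
      wt <- wilcoxon_rank_sum(a, b)
      tibble::tibble(median_trg_e = stats::median(a),
                     median_trg_ne = stats::median(b),
                     statistic = wt$statistic, p_value = wt$p_value)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$p_value)
}

# map a trg_world onto the input list run_stages() expects
world_inputs <- function(world) {
  list(hits = world$hits, lineage = world$lineage, domains = world$domains,
       essential_genes = world$essential_genes, loci = world$loci,
       expr_levels = world$expr_levels, datasets = world$datasets,
       pathways = world$pathways, tracks = world$tracks,
       ppi_edges = world$ppi_edges,
       protein_features = world$protein_features, rates = world$rates)
}

#' @export
print.trg_report <- function(x, ...) {
  cat("TRG pipeline report\n")
  print(x$classification$counts)
  if (!is.null(x$classifier)) {
    cat("classifier cv_auc:", round(x$classifier$cv_auc, 4), "\n")
  }
  if (!is.null(x$network)) {
    cat("network:", nrow(x$network$mcl$clusters), "clusters;",
        x$network$n_significant, "TRG-enriched after Bonferroni\n")
  }
  if (length(x$skipped) > 0) {
    cat("skipped stages:\n")
    for (s in names(x$skipped)) cat(" -", s, ":", x$skipped[[s]], "\n")
  }
  invisible(x)
}

#' @export
glance.trg_report <- function(x, ...) {
  counts <- x$classification$counts
  tibble::tibble(
    n_genes = sum(counts$n),
    n_trg = sum(counts$n[startsWith(counts$four_class, "TRG")]),
    n_trg_essential = counts$n[counts$four_class == "TRG-E"],
    cv_auc = if (!is.null(x$classifier)) x$classifier$cv_auc else NA_real_,
    n_enriched_clusters = if (!is.null(x$network))
      x$network$n_significant else NA_integer_,
    seed = x$provenance$seed)
}

#' Write a pipeline report to disk
#'
#' Per-stage TSVs plus a `report.json` carrying every test result and the
#' provenance block (deterministic payload: no timestamps).
#'
#' @param report A `trg_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$classification$classes,
                   file.path(dir, "classes.tsv"))
  if (!is.null(report$coexpression)) {
    readr::write_tsv(report$coexpression$features,
                     file.path(dir, "features.tsv"))
    readr::write_tsv(report$coexpression$pathway_tests,
                     file.path(dir, "pathway_tests.tsv"))
  }
  if (!is.null(report$classifier)) {
    readr::write_tsv(report$classifier$coefficients,
                     file.path(dir, "classifier_coefficients.tsv"))
    readr::write_tsv(report$classifier$single_feature,
                     file.path(dir, "single_feature_auc.tsv"))
  }
  if (!is.null(report$network)) {
    readr::write_tsv(report$network$mcl$membership,
                     file.path(dir, "clusters.tsv"))
    readr::write_tsv(report$network$enrichment,
                     file.path(dir, "cluster_enrichment.tsv"))
  }
  if (!is.null(report$rates)) {
    readr::write_tsv(report$rates, file.path(dir, "class_rates.tsv"))
  }
  jsonlite::write_json(report_payload(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# JSON-serializable summary of a report (stable across reruns)
report_payload <- function(report) {
  tests_of <- function(x) if (is.null(x)) NULL else x$tests
  list(
    counts = report$classification$counts,
    classifier = if (!is.null(report$classifier)) list(
      cv_auc = report$classifier$cv_auc,
      chosen_lambda = report$classifier$chosen_lambda,
      single_feature = report$classifier$single_feature),
    context = if (!is.null(report$context)) list(
      gene_itself = tests_of(report$context$gene_itself),
      neighbors = lapply(report$context$neighbors, tests_of),
      chromatin = lapply(report$context$chromatin, tests_of)),
    network = if (!is.null(report$network)) list(
      degree_tests = report$network$degrees$tests,
      enrichment = report$network$enrichment,
      n_significant = report$network$n_significant),
    protein_features = if (!is.null(report$protein_features)) list(
      disorder = report$protein_features$disorder$tests,
      coiled_coil = report$protein_features$coiled_coil$tests),
    rates = report$rates,
    skipped = report$skipped,
    provenance = report$provenance)
}

#' One-row headline summary of a pipeline report
#'
#' Extracts the comparisons between essential and nonessential TRGs that
#' summarize a run: the strongest Bonferroni-corrected pathway
#' coexpression difference, the flanking-expression, chromatin,
#' interaction-degree, disorder and coiled-coil p-values, the number of
#' Bonferroni-significant TRG-enriched network clusters, and the
#' cross-validated AUC of the essentiality classifier.  Convenient for
#' simulation studies that map over seeds.
#'
#' @param report A `trg_report`.
#' @return One-row tibble with columns `p_coexpression`, `p_neighbor`,
#'   `p_chromatin`, `p_degree`, `p_disorder`, `p_coiled_coil`,
#'   `n_enriched_clusters`, `cv_auc` (`NA` for skipped stages).
#' @export
report_headline <- function(report) {
  stopifnot(inherits(report, "trg_report"))
  vs_ne <- function(tests) {
    if (is.null(tests)) return(NA_real_)
    tests$p_value[tests$group1 == "TRG-E" & tests$group2 == "TRG-NE"]
  }
  p_coexpr <- if (!is.null(report$coexpression)) {
    pt <- report$coexpression$pathway_tests
    min(bonferroni(pt$p_value[!is.na(pt$p_value)], nrow(pt)))
  } else NA_real_
  nb1 <- report$context$neighbors[["1"]]
  tibble::tibble(
    p_coexpression = p_coexpr,
    p_neighbor = vs_ne(if (!is.null(nb1)) nb1$tests),
    p_chromatin = vs_ne(if (!is.null(report$context$chromatin$h3k79))
      report$context$chromatin$h3k79$tests),
    p_degree = vs_ne(if (!is.null(report$network))
      report$network$degrees$tests),
    p_disorder = vs_ne(if (!is.null(report$protein_features))
      report$protein_features$disorder$tests),
    p_coiled_coil = vs_ne(if (!is.null(report$protein_features))
      report$protein_features$coiled_coil$tests),
    n_enriched_clusters = if (!is.null(report$network))
      report$network$n_significant else NA_integer_,
    cv_auc = if (!is.null(report$classifier))
      report$classifier$cv_auc else NA_real_)
}
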