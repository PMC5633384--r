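#' Mean Fisher-Z coexpression between target genes and all other genes
#'
#' For every expression dataset in which both genes are measured (and both
#' have nonzero variance), the Pearson correlation between a target gene
#' and another gene is Fisher Z-transformed; the per-pair values are then
#' averaged across datasets.  Averaging on the Z scale makes correlations
#' comparable between datasets of different sample size.  Self-pairs are
#' dropped, and pairs with no valid dataset are absent from the output.
#'
#' @param datasets List of expression datasets as returned by
#'   [read_expression_dataset()] (each a list with `dataset_id`, `genes`,
#'   `values` = genes x samples matrix).
#' @param targets Character vector of target gene identifiers (typically
#'   the TRGs); each must be present in at least one dataset.
#' @param genes Optional character vector restricting the partner genes
#'   (e.g. the union of pathway members); default all measured genes.
#' @return Tibble with columns `target`, `gene`, `mean_z`, `n_datasets`
#'   (how many datasets contributed to the average).
#' @export
pairwise_mean_z <- function(datasets, targets, genes = NULL) {
  stopifnot(length(datasets) > 0, length(targets) > 0)
  measured <- unique(unlist(lapply(datasets, function(d) d$genes)))
  absent <- setdiff(targets, measured)
  if (length(absent) > 0) {
    stop("target gene(s) present in no expression dataset: ",
         paste(utils::head(absent, 5), collapse = ", "))
  }
  if (is.null(genes)) genes <- measured
  genes <- intersect(measured, genes)
  sum_z <- matrix(0, length(targets), length(genes),
                  dimnames = list(targets, genes))
  n_z <- matrix(0L, length(targets), length(genes),
                dimnames = list(targets, genes))
  for (d in datasets) {
    t_here <- intersect(targets, d$genes)
    g_here <- intersect(genes, d$genes)
    if (length(t_here) == 0 || length(g_here) == 0) next
    r <- suppressWarnings(
      stats::cor(t(d$values[t_here, , drop = FALSE]),
                 t(d$values[g_here, , drop = FALSE])))
    # zero-variance genes yield NA correlations and are skipped, never 0
    z <- fisher_z(clamp_r(r))
    ok <- !is.na(z)
    z[!ok] <- 0
    sum_z[t_here, g_here] <- sum_z[t_here, g_here] + z
    n_z[t_here, g_here] <- n_z[t_here, g_here] + ok
  }
  out <- tibble::tibble(
    target = rep(targets, times = length(genes)),
    gene = rep(genes, each = length(targets)),
    mean_z = as.vector(sum_z / ifelse(n_z == 0, NA, n_z)),
    n_datasets = as.vector(n_z)
  )
  dplyr::filter(out, .data$target != .data$gene, .data$n_datasets > 0)
}

# correlations of exactly +/-1 would map to infinite Z
clamp_r <- function(r) pmin(pmax(r, -0.999999), 0.999999)

#' Aggregate pair-level coexpression into TRG x pathway features
#'
#' For each target gene and gene set (e.g. a KEGG pathway), averages the
#' per-pair mean Fisher-Z values over the set's members, giving one number
#' for the correlation of that target to that functional module.  The
#' target itself is excluded when it belongs to the set.  Cells backed by
#' fewer than `min_support` (dataset x member) observations are missing.
#'
#' @param mean_z Tibble from [pairwise_mean_z()].
#' @param sets Named list of character vectors (set id -> member genes),
#'   e.g. from [read_gene_sets()].
#' @param min_support Minimum number of contributing (dataset, member)
#'   pairs for a cell to be reported (default 3).
#' @return Tibble with columns `target`, `set_id`, `value`, `support`,
#'   `n_members`; missing cells have `value = NA`.
#' @export
pathway_features <- function(mean_z, sets, min_support = 3) {
  if (length(sets) == 0) stop("empty gene-set collection")
  membership <- tibble::tibble(
    set_id = rep(names(sets), lengths(sets)),
    gene = unlist(sets, use.names = FALSE)
  )
  mean_z |>
    dplyr::inner_join(membership, by = "gene",
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$target, .data$set_id) |>
    dplyr::summarise(value = mean(.data$mean_z),
                     support = sum(.data$n_datasets),
                     n_members = dplyr::n(), .groups = "drop") |>
    dplyr::right_join(
      tidyr::expand_grid(target = unique(mean_z$target),
                         set_id = names(sets)),
      by = c("target", "set_id")) |>
    dplyr::mutate(
      support = dplyr::coalesce(.data$support, 0L),
      n_members = dplyr::coalesce(.data$n_members, 0L),
      value = ifelse(.data$support < min_support, NA, .data$value)
    ) |>
    dplyr::arrange(.data$target, .data$set_id)
}

#' Spread a long feature table into a numeric matrix
#'
#' @param features Tibble from [pathway_features()].
#' @param impute `"none"` keeps missing cells as `NA`; `"column_mean"`
#'   replaces them by the feature's mean over non-missing targets (cells
#'   in an all-missing column fall back to 0).
#' @return Numeric matrix, targets x feature columns.
#' @export
features_matrix <- function(features, impute = c("none", "column_mean")) {
  impute <- match.arg(impute)
  wide <- tidyr::pivot_wider(features[c("target", "set_id", "value")],
                             names_from = "set_id", values_from = "value")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$target
  if (impute == "column_mean") {
    for (j in seq_len(ncol(m))) {
      miss <- is.na(m[, j])
      if (any(miss)) {
        fill <- mean(m[!miss, j])
        m[miss, j] <- if (is.nan(fill)) 0 else fill
      }
    }
  }
  m
}
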