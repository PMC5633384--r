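#' Classify genes as taxonomically restricted or shared
#'
#' A gene is called a TRG (taxonomically restricted gene) when it has no
#' qualifying homology hit outside the focal lineage *and* encodes no
#' annotated protein domain.  A hit qualifies as evidence of homology when
#' its E-value is below `e_max` (strict `<`) over more than `min_cov` of
#' the query protein length (strict `>`), against a subject taxon outside
#' the lineage.  Hits to in-lineage taxa (self-hits, paralogs, close
#' relatives) never disqualify a gene.  Would-be TRGs that carry an
#' annotated domain are re-labelled shared and flagged in
#' `trg_excluded_by_domain`.
#'
#' @param hits Tibble of homology hits with columns `query_gene`,
#'   `subject_id`, `e_value`, `align_length`, `query_length`,
#'   `subject_taxon` (see [read_homology_hits()]).
#' @param lineage Lineage table with columns `taxon`, `in_lineage`
#'   (logical), `genome_label`, `phylo_rank` (see [read_lineage()]).
#' @param domains Optional domain table with columns `gene`, `domains`
#'   (comma-joined accessions, empty string for none); genes absent from
#'   the table are treated as domain-free.
#' @param genes Character vector: the gene catalog to classify.  Defaults
#'   to the genes present in `hits` (plus `domains`); genes with no hits
#'   at all are allowed and classified from the domain rule alone.
#' @param e_max E-value cutoff (default `1e-6`).
#' @param min_cov Minimum aligned fraction of the query protein length
#'   (default `0.30`).
#' @return Tibble with columns `gene`, `conservation` (`"TRG"` or
#'   `"shared"`) and `trg_excluded_by_domain`.
#' @export
classify_trg <- function(hits, lineage, domains = NULL, genes = NULL,
                         e_max = 1e-6, min_cov = 0.30) {
  check_hits(hits, lineage)
  if (is.null(genes)) {
    genes <- union(hits$query_gene, if (!is.null(domains)) domains$gene)
  }
  qualifying <- qualifying_out_hits(hits, lineage, e_max, min_cov)
  has_domain_gene <- domain_genes(domains)
  tibble::tibble(gene = genes) |>
    dplyr::mutate(
      out_homology = .data$gene %in% qualifying$query_gene,
      has_domain = .data$gene %in% has_domain_gene,
      conservation = ifelse(!.data$out_homology & !.data$has_domain,
                            "TRG", "shared"),
      trg_excluded_by_domain = !.data$out_homology & .data$has_domain
    ) |>
    dplyr::select("gene", "conservation", "trg_excluded_by_domain")
}

check_hits <- function(hits, lineage) {
  cov <- hits$align_length / hits$query_length
  if (any(cov > 1)) {
    stop("classify_trg(): alignment coverage > 1 for ",
         sum(cov > 1), " hit(s); align_length must not exceed query_length")
  }
  unmapped <- setdiff(unique(hits$subject_taxon), lineage$taxon)
  if (length(unmapped) > 0) {
    stop("unknown subject taxa not in the lineage table: ",
         paste(unmapped, collapse = ", "))
  }
  invisible(TRUE)
}

qualifying_out_hits <- function(hits, lineage, e_max, min_cov) {
  out_taxa <- lineage$taxon[!lineage$in_lineage]
  dplyr::filter(
    hits,
    .data$subject_taxon %in% out_taxa,
    .data$e_value < e_max,
    .data$align_length / .data$query_length > min_cov
  )
}

domain_genes <- function(domains) {
  if (is.null(domains) || nrow(domains) == 0) return(character())
  domains$gene[!is.na(domains$domains) & nzchar(domains$domains)]
}

#' Sensitivity scan of the TRG call over relaxed homology cutoffs
#'
#' Starting from the TRG set defined at the strict cutoffs, reports for
#' every combination of a relaxed coverage cutoff and a relaxed E-value
#' cutoff the fraction of those TRGs that *still* have no out-of-lineage
#' match.  Relaxing either cutoff can only add qualifying hits, so the
#' fraction is non-increasing along each grid axis.
#'
#' @inheritParams classify_trg
#' @param coverage_grid Numeric vector of coverage cutoffs to scan.
#' @param e_grid Numeric vector of E-value cutoffs to scan.
#' @param trg_genes Character vector of genes called TRG at the strict
#'   cutoffs; computed with [classify_trg()] (no domain table) when `NULL`.
#' @return Tibble with columns `cov_cutoff`, `e_cutoff`, `n_trg`,
#'   `n_unmatched`, `frac_unmatched`.
#' @export
relaxed_scan <- function(hits, lineage, coverage_grid, e_grid,
                         trg_genes = NULL, e_max = 1e-6, min_cov = 0.30) {
  stopifnot(length(coverage_grid) > 0, length(e_grid) > 0)
  if (is.null(trg_genes)) {
    cls <- classify_trg(hits, lineage, e_max = e_max, min_cov = min_cov)
    trg_genes <- cls$gene[cls$conservation == "TRG"]
  }
  out_taxa <- lineage$taxon[!lineage$in_lineage]
  out_hits <- dplyr::filter(hits,
                            .data$subject_taxon %in% out_taxa,
                            .data$query_gene %in% trg_genes) |>
    dplyr::mutate(coverage = .data$align_length / .data$query_length)
  tidyr::expand_grid(cov_cutoff = coverage_grid, e_cutoff = e_grid) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      n_trg = length(trg_genes),
      n_unmatched = .data$n_trg - dplyr::n_distinct(
        out_hits$query_gene[out_hits$e_value < .data$e_cutoff &
                              out_hits$coverage > .data$cov_cutoff]),
      frac_unmatched = .data$n_unmatched / .data$n_trg
    ) |>
    dplyr::ungroup()
}

#' Per-genome best-hit profile
#'
#' For each requested gene, the strongest homology hit (as -log10 of the
#' best E-value) in every genome of the lineage table, ordered from the
#' focal species outward by `phylo_rank`.  Genomes with no hit get 0
#' (an E-value floor of 1); E-values of 0 are clamped to 1e-180 before
#' taking the log.
#'
#' @inheritParams classify_trg
#' @param genes Character vector of genes to profile.
#' @return Tibble with columns `gene`, `genome_label`, `phylo_rank`,
#'   `in_lineage`, `neg_log10_e`, sorted by gene then `phylo_rank`.
#' @export
best_hit_profile <- function(hits, lineage, genes) {
  check_hits(hits, lineage)
  best <- hits |>
    dplyr::filter(.data$query_gene %in% genes) |>
    dplyr::left_join(lineage, by = c(subject_taxon = "taxon")) |>
    dplyr::group_by(.data$query_gene, .data$genome_label) |>
    dplyr::summarise(best_e = min(.data$e_value), .groups = "drop")
  tidyr::expand_grid(gene = genes,
                     lineage[c("genome_label", "phylo_rank", "in_lineage")]) |>
    dplyr::left_join(best, by = c(gene = "query_gene", "genome_label")) |>
    dplyr::mutate(
      neg_log10_e = ifelse(is.na(.data$best_e), 0,
                           -log10(pmax(.data$best_e, 1e-180)))
    ) |>
    dplyr::select(-"best_e") |>
    dplyr::arrange(.data$gene, .data$phylo_rank)
}

#' Cross conservation with essentiality into the four analysis classes
#'
#' Combines the TRG/shared call with an essential-gene list into the four
#' classes used throughout the comparisons: `TRG-E`, `TRG-NE`, `Shared-E`,
#' `Shared-NE`.
#'
#' @param conservation Tibble from [classify_trg()] (columns `gene`,
#'   `conservation`, optionally `trg_excluded_by_domain`).
#' @param essential_genes Character vector of essential gene identifiers;
#'   must be a subset of the catalog.
#' @return Tibble with columns `gene`, `conservation`, `essential`,
#'   `four_class`, `trg_excluded_by_domain`.
#' @export
assign_four_classes <- function(conservation, essential_genes) {
  missing <- setdiff(essential_genes, conservation$gene)
  if (length(missing) > 0) {
    stop("essential genes absent from the catalog: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) paste0(" (and ", length(missing) - 5, " more)"))
  }
  if (!"trg_excluded_by_domain" %in% names(conservation)) {
    conservation$trg_excluded_by_domain <- FALSE
  }
  conservation |>
    dplyr::mutate(
      essential = .data$gene %in% essential_genes,
      four_class = paste0(
        ifelse(.data$conservation == "TRG", "TRG", "Shared"),
        ifelse(.data$essential, "-E", "-NE"))
    ) |>
    dplyr::select("gene", "conservation", "essential", "four_class",
                  "trg_excluded_by_domain")
}

#' Count genes in each of the four analysis classes
#'
#' @param classes Tibble from [assign_four_classes()].
#' @return Tibble with columns `four_class`, `n`, in the fixed order
#'   TRG-E, TRG-NE, Shared-E, Shared-NE.
#' @export
four_class_counts <- function(classes) {
  lv <- c("TRG-E", "TRG-NE", "Shared-E", "Shared-NE")
  classes |>
    dplyr::count(four_class = factor(.data$four_class, levels = lv),
                 .drop = FALSE) |>
    dplyr::mutate(four_class = as.character(.data$four_class))
}
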