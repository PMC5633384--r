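#' Expression of genes flanking a gene of interest
#'
#' For each gene, collects the scalar expression levels of the genes `k`
#' positions away in genomic order (both directions pooled, strand
#' ignored), for each offset in `offsets`.  Genes are ordered within each
#' chromosome by start coordinate (ties by end, then identifier);
#' chromosome ends simply contribute fewer values — there is no
#' wraparound.
#'
#' @param loci Tibble of gene loci (`gene`, `chrom`, `start`, `end`,
#'   optionally `strand`), e.g. from [read_bed6()].
#' @param expr Tibble with columns `gene`, `value`: one scalar expression
#'   level per gene (genes without a value contribute nothing).
#' @param offsets Integer offsets to collect (default `1:3`).
#' @return Tibble with columns `gene`, `offset`, `side` (`"up"`/`"down"`),
#'   `neighbor`, `value`; one row per available neighbor with expression.
#' @export
neighbor_expression <- function(loci, expr, offsets = 1:3) {
  stopifnot(all(offsets >= 1))
  missing_chrom <- any(is.na(loci$chrom) | !nzchar(loci$chrom))
  if (missing_chrom) stop("neighbor_expression(): gene with unknown chromosome")
  ordered <- loci |>
    dplyr::arrange(.data$chrom, .data$start, .data$end, .data$gene) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(.pos = dplyr::row_number())
  purrr::map_dfr(offsets, function(k) {
    up <- ordered |>
      dplyr::mutate(neighbor = dplyr::lag(.data$gene, k)) |>
      dplyr::mutate(side = "up")
    down <- ordered |>
      dplyr::mutate(neighbor = dplyr::lead(.data$gene, k)) |>
      dplyr::mutate(side = "down")
    dplyr::bind_rows(up, down) |>
      dplyr::ungroup() |>
      dplyr::filter(!is.na(.data$neighbor)) |>
      dplyr::mutate(offset = k) |>
      dplyr::select("gene", "offset", "side", "neighbor")
  }) |>
    dplyr::inner_join(expr, by = c(neighbor = "gene")) |>
    dplyr::arrange(.data$gene, .data$offset)
}

#' Median chromatin signal in a window around each gene
#'
#' The window is the gene body extended by `flank` bases on each side
#' (clipped at coordinate 0).  The median of the track values overlapping
#' the window is weighted by the number of bases each interval contributes
#' inside the window; with an even split of mass the mean of the two
#' bracketing values is reported.  Genes whose window overlaps no track
#' interval get `NA`.
#'
#' @param loci Gene loci tibble (see [neighbor_expression()]).
#' @param track Signal track tibble (`chrom`, `start`, `end`, `value`),
#'   0-based half-open, non-overlapping within the track, e.g. from
#'   [read_bedgraph()].
#' @param flank Bases added on each side of the gene body (default 5000).
#' @return Tibble with columns `gene`, `median_signal`, `covered_bases`.
#' @export
window_median_signal <- function(loci, track, flank = 5000) {
  stopifnot(flank >= 0)
  out <- loci |>
    dplyr::mutate(win_start = pmax(.data$start - flank, 0),
                  win_end = .data$end + flank,
                  median_signal = NA_real_, covered_bases = 0)
  for (chr in unique(out$chrom)) {
    gi <- which(out$chrom == chr)
    tr <- track[track$chrom == chr, ]
    if (nrow(tr) == 0) next
    # 0-based half-open -> 1-based closed for IRanges
    windows <- IRanges::IRanges(out$win_start[gi] + 1, out$win_end[gi])
    ivals <- IRanges::IRanges(tr$start + 1, tr$end)
    hits <- IRanges::findOverlaps(windows, ivals)
    if (length(hits) == 0) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    w <- IRanges::width(IRanges::pintersect(windows[qh], ivals[sh]))
    for (q in unique(qh)) {
      sel <- qh == q
      out$median_signal[gi[q]] <- weighted_median(tr$value[sh[sel]], w[sel])
      out$covered_bases[gi[q]] <- sum(w[sel])
    }
  }
  out[c("gene", "median_signal", "covered_bases")]
}

# weighted median; even split of total mass -> mean of bracketing values
weighted_median <- function(values, weights) {
  ord <- order(values)
  v <- values[ord]; w <- weights[ord]
  cw <- cumsum(w)
  half <- sum(w) / 2
  i <- which(cw >= half)[1]
  if (cw[i] == half && i < length(v)) (v[i] + v[i + 1]) / 2 else v[i]
}

#' Wilcoxon comparisons of a per-gene quantity between gene classes
#'
#' Runs the two headline comparisons — essential TRGs against
#' nonessential TRGs, and essential TRGs against shared essentials — on
#' any per-gene scalar (flanking expression, window medians, degrees,
#' ...), plus box-plot-ready class summaries.
#'
#' @param values Tibble with columns `gene`, `value` (`NA` rows dropped).
#' @param classes Tibble from [assign_four_classes()].
#' @param comparisons List of 2-vectors of `four_class` labels to compare
#'   (first vs second).
#' @return List with `tests` (tibble: one [wilcoxon_rank_sum()] row per
#'   comparison plus `group1`, `group2` columns) and `summary` (tibble of
#'   per-class `n`, `median`, `q1`, `q3`).
#' @export
context_group_tests <- function(values, classes,
                                comparisons = list(c("TRG-E", "TRG-NE"),
                                                   c("TRG-E", "Shared-E"))) {
  joined <- values |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::inner_join(classes[c("gene", "four_class")], by = "gene")
  summary <- joined |>
    dplyr::group_by(.data$four_class) |>
    dplyr::summarise(n = dplyr::n(),
                     median = stats::median(.data$value),
                     q1 = stats::quantile(.data$value, 0.25),
                     q3 = stats::quantile(.data$value, 0.75),
                     .groups = "drop")
  tests <- purrr::map_dfr(comparisons, function(cmp) {
    a <- joined$value[joined$four_class == cmp[1]]
    b <- joined$value[joined$four_class == cmp[2]]
    if (length(a) == 0 || length(b) == 0) {
      stop("context_group_tests(): empty class in comparison ",
           cmp[1], " vs ", cmp[2])
    }
    dplyr::bind_cols(tibble::tibble(group1 = cmp[1], group2 = cmp[2]),
                     wilcoxon_rank_sum(a, b))
  })
  list(tests = tests, summary = summary)
}
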