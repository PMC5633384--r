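#' Compare predicted protein order between gene classes
#'
#' Kolmogorov-Smirnov comparisons of the per-protein ordered fraction
#' (share of residues predicted structured by an external disorder
#' predictor) between essential restricted proteins and (a) nonessential
#' restricted proteins, (b) shared essential proteins, plus
#' violin-plot-ready quantile summaries per class.
#'
#' @param features Tibble with columns `gene`, `ordered_fraction` (in
#'   `[0, 1]`), e.g. from [read_protein_features()].
#' @param classes Tibble from [assign_four_classes()].
#' @param comparisons List of 2-vectors of `four_class` labels.
#' @return List with `tests` (one [ks_two_sample()] row per comparison,
#'   with `group1`, `group2`) and `summary` (per-class `n` and deciles
#'   `q10`, `q25`, `q50`, `q75`, `q90`).
#' @export
disorder_compare <- function(features, classes,
                             comparisons = list(c("TRG-E", "TRG-NE"),
                                                c("TRG-E", "Shared-E"))) {
  joined <- dplyr::inner_join(features[c("gene", "ordered_fraction")],
                              classes[c("gene", "four_class")], by = "gene")
  summary <- joined |>
    dplyr::group_by(.data$four_class) |>
    dplyr::summarise(
      n = dplyr::n(),
      q10 = stats::quantile(.data$ordered_fraction, 0.10),
      q25 = stats::quantile(.data$ordered_fraction, 0.25),
      q50 = stats::quantile(.data$ordered_fraction, 0.50),
      q75 = stats::quantile(.data$ordered_fraction, 0.75),
      q90 = stats::quantile(.data$ordered_fraction, 0.90),
      .groups = "drop")
  tests <- purrr::map_dfr(comparisons, function(cmp) {
    a <- joined$ordered_fraction[joined$four_class == cmp[1]]
    b <- joined$ordered_fraction[joined$four_class == cmp[2]]
    if (length(a) == 0 || length(b) == 0) {
      stop("disorder_compare(): empty class in comparison ",
           cmp[1], " vs ", cmp[2])
    }
    dplyr::bind_cols(tibble::tibble(group1 = cmp[1], group2 = cmp[2]),
                     ks_two_sample(a, b))
  })
  list(tests = tests, summary = summary)
}

#' Compare coiled-coil prevalence between gene classes
#'
#' For each comparison, builds the 2x2 table of class membership against
#' presence of a predicted coiled-coil region and applies the Pearson
#' chi-squared test (1 df, no continuity correction).
#'
#' @param features Tibble with columns `gene`, `has_coiled_coil`
#'   (logical).
#' @inheritParams disorder_compare
#' @return List with `tests` (one [chi_square_2x2()] row per comparison
#'   plus the two class fractions) and `fractions` (per-class `n`,
#'   `n_coiled_coil`, `fraction`).
#' @export
coiled_coil_compare <- function(features, classes,
                                comparisons = list(c("TRG-E", "TRG-NE"),
                                                   c("TRG-E", "Shared-E"))) {
  joined <- dplyr::inner_join(features[c("gene", "has_coiled_coil")],
                              classes[c("gene", "four_class")], by = "gene")
  fractions <- joined |>
    dplyr::group_by(.data$four_class) |>
    dplyr::summarise(n = dplyr::n(),
                     n_coiled_coil = sum(.data$has_coiled_coil),
                     fraction = mean(.data$has_coiled_coil),
                     .groups = "drop")
  tests <- purrr::map_dfr(comparisons, function(cmp) {
    a <- joined$has_coiled_coil[joined$four_class == cmp[1]]
    b <- joined$has_coiled_coil[joined$four_class == cmp[2]]
    if (length(a) == 0 || length(b) == 0) {
      stop("coiled_coil_compare(): empty class in comparison ",
           cmp[1], " vs ", cmp[2])
    }
    tab <- rbind(c(sum(a), sum(!a)), c(sum(b), sum(!b)))
    res <- tryCatch(chi_square_2x2(tab), error = function(e) {
      stop("coiled_coil_compare() [", cmp[1], " vs ", cmp[2], "]: ",
           conditionMessage(e))
    })
    dplyr::bind_cols(
      tibble::tibble(group1 = cmp[1], group2 = cmp[2],
                     fraction1 = mean(a), fraction2 = mean(b)), res)
  })
  list(tests = tests, fractions = fractions)
}

#' Per-functional-class evolutionary-rate report
#'
#' For each functional class: the median dN/dS, a Welch t-test of the
#' class's dN/dS against *all* genes in the rate table (the class itself
#' included in the background, with the direction of the shift), the TRG
#' count and proportion, and — for classes with at least `min_trg`
#' TRGs — the fraction of the class's TRGs that are essential.
#'
#' @param rates Tibble with columns `gene`, `dnds`, `functional_class`
#'   (genes in several classes appear as duplicated rows), e.g. from
#'   [read_rates()].
#' @param classes Tibble from [assign_four_classes()]; rate-table genes
#'   missing from it are dropped (a message reports how many).
#' @param min_trg Minimum TRG count for the essential-TRG fraction to be
#'   reported (default 20).
#' @return Tibble with one row per functional class: `functional_class`,
#'   `n_genes`, `median_dnds`, `statistic`, `p_value`, `direction`
#'   (`"lower"`/`"higher"`), `n_trg`, `trg_proportion`,
#'   `trg_percent` (proportion rounded to 1 decimal percent),
#'   `essential_trg_fraction` (`NA` below `min_trg`).
#' @export
class_rate_analysis <- function(rates, classes, min_trg = 20) {
  known <- rates$gene %in% classes$gene
  if (any(!known)) {
    message("class_rate_analysis(): dropping ", sum(!known),
            " rate row(s) for genes absent from the class table")
    rates <- rates[known, ]
  }
  joined <- dplyr::inner_join(
    rates, classes[c("gene", "conservation", "essential")], by = "gene")
  background <- joined$dnds[!duplicated(joined$gene)]
  joined |>
    dplyr::group_by(.data$functional_class) |>
    dplyr::group_modify(function(d, key) {
      tt <- if (nrow(d) >= 2 && (stats::var(d$dnds) > 0 ||
                                 stats::var(background) > 0)) {
        t_test_two_sample(d$dnds, background)
      } else {
        tibble::tibble(statistic = NA_real_, p_value = NA_real_)
      }
      n_trg <- sum(d$conservation == "TRG")
      tibble::tibble(
        n_genes = nrow(d),
        median_dnds = stats::median(d$dnds),
        statistic = tt$statistic,
        p_value = tt$p_value,
        direction = ifelse(mean(d$dnds) < mean(background),
                           "lower", "higher"),
        n_trg = n_trg,
        trg_proportion = n_trg / nrow(d),
        trg_percent = round(100 * n_trg / nrow(d), 1),
        essential_trg_fraction = ifelse(
          n_trg >= min_trg,
          sum(d$conservation == "TRG" & d$essential) / n_trg, NA_real_)
      )
    }) |>
    dplyr::ungroup()
}
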