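#' Plot per-genome best-hit profiles
#'
#' Line plot of -log10 best E-value against phylogenetic distance for one
#' or more genes: shared genes decay slowly with distance while TRG
#' scores drop to zero immediately outside the lineage.
#'
#' @param profile Tibble from [best_hit_profile()].
#' @param cutoff Homology cutoff drawn as a dashed line (default
#'   `-log10(1e-6)`).
#' @return A ggplot object.
#' @export
plot_best_hit_profile <- function(profile, cutoff = -log10(1e-6)) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = stats::reorder(.data$genome_label,
                                                  .data$phylo_rank),
                               y = .data$neg_log10_e,
                               group = .data$gene, colour = .data$gene)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$in_lineage)) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::labs(x = "genome (ordered by phylogenetic distance)",
                  y = expression(-log[10] ~ "best E-value"),
                  shape = "in lineage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Box-style summary of a per-class context comparison
#'
#' Crossbar plot (median and interquartile range) of the class summaries
#' produced by [context_group_tests()], [degree_compare()] and friends.
#'
#' @param summary Tibble with columns `four_class`, `median`, `q1`, `q3`.
#' @param ylab Y-axis label.
#' @return A ggplot object.
#' @export
plot_class_summary <- function(summary, ylab = "value") {
  lv <- c("Shared-E", "Shared-NE", "TRG-E", "TRG-NE")
  summary$four_class <- factor(summary$four_class, levels = lv)
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$four_class, y = .data$median,
                               ymin = .data$q1, ymax = .data$q3,
                               fill = .data$four_class)) +
    ggplot2::geom_crossbar(width = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}

#' @describeIn cross_validated_auc Plot the cross-validation curve
#'   (pooled out-of-fold AUC against lambda, chosen lambda marked).
#' @param object A `trg_cv` object.
#' @param ... Unused.
#' @export
autoplot.trg_cv <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(.data$lambda, .data$auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$chosen_lambda,
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = "cross-validated AUC") +
    ggplot2::theme_minimal()
}

#' Plot the per-functional-class rate report
#'
#' Median dN/dS per functional class with the TRG percentage overlaid,
#' the figure-style view of [class_rate_analysis()].
#'
#' @param rate_report Tibble from [class_rate_analysis()].
#' @return A ggplot object.
#' @export
plot_class_rates <- function(rate_report) {
  d <- dplyr::arrange(rate_report, .data$median_dnds)
  d$functional_class <- factor(d$functional_class,
                               levels = d$functional_class)
  scale <- max(d$median_dnds) / max(d$trg_percent, 1)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$functional_class)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$median_dnds), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$trg_percent * scale, group = 1),
                       colour = "red") +
    ggplot2::geom_point(ggplot2::aes(y = .data$trg_percent * scale),
                        colour = "red") +
    ggplot2::scale_y_continuous(
      name = "median dN/dS",
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "TRG %")) +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
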