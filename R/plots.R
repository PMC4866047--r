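#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-gene driver scores
#'
#' ONC and TSG scores per gene and stratum, driver calls highlighted — the
#' ratiometric summary behind the 20/20 rule.
#'
#' @param scores A `driver_scores` tibble from [identify_mut_drivers()].
#' @param min_total Hide genes with fewer total mutations (default 5).
#' @return A ggplot object.
#' @export
plot_driver_scores <- function(scores, min_total = 5) {
  d <- scores |>
    filter(.data$n_total >= min_total) |>
    tidyr::pivot_longer(c("onc_score", "tsg_score"),
                        names_to = "score_type", values_to = "score") |>
    mutate(score_type = if_else(.data$score_type == "onc_score",
                                "ONC", "TSG"))
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$gene, .data$score),
    y = .data$score,
    colour = .data$score_type,
    shape = .data$qualifies
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0.2, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(x = NULL, y = "score (fraction of mutations)",
                  colour = "score", shape = "driver") +
    ggplot2::theme_minimal()
}

#' @rdname plot_driver_scores
#' @param object,... ggplot2 autoplot interface.
#' @export
autoplot.driver_scores <- function(object, ...) {
  plot_driver_scores(object, ...)
}

#' Plot cancer-cell-fraction distributions
#'
#' Per-gene CCF distributions with clonality annotated; mostly-clonal genes
#' sit against the right-hand edge.
#'
#' @param ccf Output of [estimate_ccf()] with a `gene` column.
#' @return A ggplot object.
#' @export
plot_ccf_distribution <- function(ccf) {
  ggplot2::ggplot(ccf, ggplot2::aes(x = .data$gene, y = .data$ccf,
                                    colour = .data$clonality)) +
    ggplot2::geom_jitter(width = 0.2, height = 0, alpha = 0.5, size = 1) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "cancer cell fraction") +
    ggplot2::theme_minimal()
}

#' Plot MATH-score distributions by group
#'
#' @param math_scores Tibble from [cohort_math_scores()].
#' @param groups Optional tibble `sample`, `group` (e.g. ER status).
#' @return A ggplot object.
#' @export
plot_math_distribution <- function(math_scores, groups = NULL) {
  d <- filter(math_scores, !is.na(.data$math))
  if (!is.null(groups)) {
    d <- inner_join(d, as_tibble(groups), by = "sample")
  } else {
    d$group <- "all"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$math, fill = .data$group)) +
    ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "MATH score", y = "tumours") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for the MATH-quartile comparison
#'
#' @param object A `km_math` object.
#' @param ... Unused.
#' @return A ggplot object with step curves per quartile group and the
#'   log-rank p in the subtitle.
#' @export
autoplot.km_math <- function(object, ...) {
  d <- tidy(object)
  d0 <- d |>
    group_by(.data$group) |>
    summarise(time = 0, estimate = 1, .groups = "drop")
  d <- bind_rows(d0, select(d, "group", "time", "estimate")) |>
    arrange(.data$group, .data$time)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$estimate,
                                  colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "months", y = "BCSS",
      subtitle = sprintf("log-rank p = %.3g", object$logrank_p)
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of a fitted Cox driver model
#'
#' @param object A `driver_cox` object.
#' @param ... Unused.
#' @return A ggplot object (hazard ratios with 95% CIs on a log scale).
#' @export
autoplot.driver_cox <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hazard_ratio, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lower, xmax = .data$ci_upper),
      height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Association heatmap for pairwise screens
#'
#' Log-odds of significant pairwise associations; mutual exclusivity in
#' purple, co-occurrence in green, following the field's convention.
#'
#' @param associations Result of [pairwise_comutation()].
#' @param significant_only Show only FDR-significant pairs (default TRUE).
#' @return A ggplot object.
#' @export
plot_association_matrix <- function(associations, significant_only = TRUE) {
  d <- associations
  if (significant_only) d <- filter(d, .data$significant)
  d <- mutate(d, log_odds_capped = pmax(pmin(.data$log_odds, 4), -4))
  ggplot2::ggplot(d, ggplot2::aes(.data$gene_a, .data$gene_b,
                                  fill = .data$log_odds_capped)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "purple4", mid = "white",
                                  high = "darkgreen", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log odds") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
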