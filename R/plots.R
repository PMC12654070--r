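#' Volcano plot of a Wald-ratio screen
#'
#' One point per metabolite-outcome test: the MR log-odds estimate per
#' 1-SD exposure on the x-axis, `-log10(p)` on the y-axis, faceted by
#' outcome, with dashed lines at the suggestive (`alpha`) and Bonferroni
#' thresholds.
#'
#' @param results MR result tibble (from [mr_wald()] or
#'   `tidy(mr_screen)`).
#' @param alpha Suggestive threshold (default 0.05).
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, alpha = 0.05) {
  bonf <- alpha / max(results$n_tests %||% nrow(results))
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$beta_mr, y = -log10(.data$pval),
                               color = .data$tier)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        color = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(bonf), linetype = "dashed",
                        color = "grey20") +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::scale_color_manual(values = c(significant = "#C0392B",
                                           suggestive = "#E67E22",
                                           null = "grey60")) +
    ggplot2::labs(x = "MR β (log-odds per 1-SD exposure)",
                  y = expression(-log[10](italic(p))), color = "tier") +
    ggplot2::theme_minimal()
}

#' Forest plot of odds ratios with confidence intervals
#'
#' One row per test: the odds ratio per 1-SD higher genetically predicted
#' exposure with its 95% CI, faceted by outcome. By default only
#' significant and suggestive rows are drawn (a full 83-row panel is
#' unreadable); set `tiers` to include `"null"`.
#'
#' @param results MR result tibble.
#' @param tiers Tiers to display.
#' @return A ggplot object.
#' @export
plot_forest <- function(results, tiers = c("significant", "suggestive")) {
  d <- filter(results, .data$tier %in% tiers)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or,
                                  y = stats::reorder(.data$metabolite, .data$or),
                                  color = .data$tier)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::scale_color_manual(values = c(significant = "#C0392B",
                                           suggestive = "#E67E22")) +
    ggplot2::labs(x = "OR per 1-SD exposure (95% CI)", y = NULL,
                  color = "tier") +
    ggplot2::theme_minimal()
}

#' @method autoplot mr_screen
#' @export
autoplot.mr_screen <- function(object, type = c("volcano", "forest"), ...) {
  type <- match.arg(type)
  if (type == "volcano") {
    plot_volcano(object$results, alpha = object$config$alpha)
  } else {
    plot_forest(object$results)
  }
}
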