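#' Volcano plot of a screen fit
#'
#' Effect estimate against evidence (-log10 lfdr), hits highlighted.
#'
#' @param x An `eb_screen_fit`.
#' @param label_top Number of top genes to label.
#' @return A ggplot object.
#' @export
plot_volcano <- function(x, label_top = 10) {
  d <- tidy(x)
  d$mlog_lfdr <- -log10(pmax(d$lfdr, 1e-300))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$beta_hat,
                                       y = .data$mlog_lfdr,
                                       colour = .data$hit)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "effect on lethality score (non-reference - reference)",
                  y = expression(-log[10] ~ "lfdr"), colour = "hit") +
    ggplot2::theme_minimal()
  top <- utils::head(d[order(d$lfdr), ], label_top)
  if (nrow(top)) {
    p <- p + ggplot2::geom_text(data = top,
                                ggplot2::aes(label = .data$gene),
                                vjust = -0.6, size = 2.7, show.legend = FALSE)
  }
  p
}

#' @method autoplot eb_screen_fit
#' @export
autoplot.eb_screen_fit <- function(object, ...) plot_volcano(object, ...)

#' Averaged ROC curves from a benchmark run
#'
#' @param roc Tibble from `attr(run_benchmark(..., roc = TRUE), "roc")`.
#' @return A ggplot object faceted by scenario.
#' @export
plot_roc <- function(roc) {
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::facet_grid(design ~ delta,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Benchmark summary plot: mean true/false positives per scenario
#'
#' @param bench Tibble from [run_benchmark()].
#' @return A ggplot object.
#' @export
plot_benchmark <- function(bench) {
  d <- tidyr::pivot_longer(bench[c("design", "delta", "method",
                                   "tp_mean", "fp_mean")],
                           cols = c("tp_mean", "fp_mean"),
                           names_to = "metric", values_to = "count")
  d$metric <- ifelse(d$metric == "tp_mean", "true positives",
                     "false positives")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$delta), y = .data$count,
                                  fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(metric ~ design, scales = "free_y") +
    ggplot2::labs(x = expression(Delta[g]), y = "mean genes per dataset") +
    ggplot2::theme_minimal()
}
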