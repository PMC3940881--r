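#' Volcano plot of per-CpG or per-window group differences
#'
#' @param results Either a volcano table from [volcano_table()], a per-CpG
#'   result tibble from [test_group_difference()], or an MBD comparison from
#'   [compare_mbd_groups()] (plotted as log2 fold change vs. `-log10 p`).
#' @param test For per-CpG results, which p-value family to plot.
#' @param fdr_threshold Significance flag level.
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, test = c("t", "wilcoxon"),
                         fdr_threshold = 0.05) {
  if ("p_nb" %in% names(results)) {
    dat <- tibble::tibble(
      diff = results$log_fc,
      neg_log10_p = results$neg_log10_p,
      significant = results$q_nb < fdr_threshold
    )
    xlab <- "log2 fold change (MBD read counts)"
  } else {
    if (!"neg_log10_p" %in% names(results)) {
      results <- volcano_table(results, test = test,
                               fdr_threshold = fdr_threshold)
    }
    dat <- results
    xlab <- "Difference in mean percent methylation (A - B)"
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$diff, y = .data$neg_log10_p,
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 name = paste0("q < ", fdr_threshold)) +
    ggplot2::labs(x = xlab, y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' Plot a Monte-Carlo power curve
#'
#' Power against the true between-group methylation difference, with the
#' target power drawn as a horizontal reference line (the classic red line
#' at 80%).
#'
#' @param x A `power_curve` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_power_curve <- function(x, ...) {
  stopifnot(inherits(x, "power_curve"))
  g <- ggplot2::ggplot(x$curve, ggplot2::aes(x = .data$delta,
                                             y = .data$power)) +
    ggplot2::geom_hline(yintercept = x$target, colour = "red",
                        linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "True difference in percent methylation (points)",
                  y = "Power") +
    ggplot2::theme_minimal()
  if (!is.na(x$mdd)) {
    g <- g + ggplot2::geom_vline(xintercept = x$mdd_interpolated,
                                 colour = "red", alpha = 0.4)
  }
  g
}

#' @rdname plot_power_curve
#' @param object A `power_curve` object.
#' @method autoplot power_curve
#' @export
autoplot.power_curve <- function(object, ...) plot_power_curve(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
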