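#' Over/under-representation scatter plot
#'
#' Plots the log2 ratio of observed to null-mean counts against the null
#' mean (log10 axis), one point per motif class; points above zero are
#' over-represented, points below suppressed. Significant motifs (adjusted
#' P at or below alpha) are highlighted.
#'
#' @param object a [significance_table()] result
#' @param ... unused
#' @return A ggplot object.
#' @method autoplot motif_significance
#' @export
autoplot.motif_significance <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[is.finite(df$log2_ratio) & df$null_mean > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_mean,
                                   y = .data$log2_ratio,
                                   colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red3")) +
    ggplot2::labs(
      x = "mean count in color-randomized networks",
      y = expression(log[2] * " (observed / randomized)"),
      colour = "significant",
      title = sprintf("Colored motifs, size %d (%s)", attr(object, "k"),
                      attr(object, "mode"))
    )
}

#' z-score histogram
#'
#' Histogram of motif z-scores, optionally normalized by `sqrt(n_rand)` so
#' histograms from runs with different ensemble sizes are comparable.
#'
#' @param table a [significance_table()] result
#' @param normalize `"none"` or `"sqrt_n"` (divide z by the square root of
#'   the number of randomizations)
#' @param bins histogram bins
#' @return A ggplot object.
#' @export
plot_zscore_histogram <- function(table, normalize = c("none", "sqrt_n"),
                                  bins = 50) {
  stopifnot(inherits(table, "motif_significance"))
  normalize <- match.arg(normalize)
  z <- table$z[is.finite(table$z)]
  xlab <- "z"
  if (normalize == "sqrt_n") {
    z <- z / sqrt(attr(table, "n_rand"))
    xlab <- "z / sqrt(N)"
  }
  ggplot2::ggplot(tibble::tibble(z = z), ggplot2::aes(x = .data$z)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = xlab, y = "motif classes")
}

#' Two-node motif abundance plot
#'
#' Observed versus null-mean abundances per colored pair motif, the classic
#' paired-bar view of the smallest motifs.
#'
#' @param table a [significance_table()] result for `k = 2`
#' @param color_names color alphabet for labels (defaults to the table's)
#' @return A ggplot object.
#' @export
plot_pair_abundance <- function(table, color_names = NULL) {
  stopifnot(inherits(table, "motif_significance"), attr(table, "k") == 2)
  if (is.null(color_names)) color_names <- attr(table, "color_levels")
  df <- tibble::as_tibble(table)
  df$label <- format_motif(df$key, color_names)
  long <- tidyr::pivot_longer(df[, c("label", "n_obs", "null_mean")],
                              c("n_obs", "null_mean"),
                              names_to = "which", values_to = "count")
  long$which <- ifelse(long$which == "n_obs", "observed", "randomized")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$count,
                                     fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(observed = "black",
                                          randomized = "grey60")) +
    ggplot2::labs(x = NULL, y = "count", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}
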