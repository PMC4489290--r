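#' Plot the node degree distribution
#'
#' @param net An interactome tibble (or a `ppi_network_stats` object).
#' @return A ggplot: node count per degree on log-scaled axes, the usual
#'   view for heavy-tailed interactome degree distributions.
#' @export
plot_degree_distribution <- function(net) {
  dh <- if (inherits(net, "ppi_network_stats")) net$degree_histogram
        else network_stats(net)$degree_histogram
  ggplot2::ggplot(dh, ggplot2::aes(x = .data$degree, y = .data$count)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Degree", y = "Number of proteins",
                  title = "Node degree distribution") +
    ggplot2::theme_minimal()
}

#' Plot the interaction-weight distribution
#'
#' @param net A weighted interactome (or a `ppi_network_stats` object).
#' @return A ggplot: histogram of posterior interaction weights on the
#'   fixed 20-bin grid over \[0, 1\].
#' @export
plot_weight_distribution <- function(net) {
  wh <- if (inherits(net, "ppi_network_stats")) net$weight_histogram
        else weight_histogram(net)
  ggplot2::ggplot(wh, ggplot2::aes(x = (.data$bin_low + .data$bin_high) / 2,
                                   y = .data$count)) +
    ggplot2::geom_col(width = wh$bin_high[1] - wh$bin_low[1]) +
    ggplot2::labs(x = "Interaction weight", y = "Number of PPIs",
                  title = "PPI weight distribution") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' For an interactome, plots the weight distribution when weights are
#' present and the degree distribution otherwise. For a method-score
#' object, plots per-method likelihood ratios.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ppi_interactome <- function(object, ...) {
  if (any(!is.na(object$weight))) plot_weight_distribution(object)
  else plot_degree_distribution(object)
}

#' @rdname autoplot.ppi_interactome
#' @export
autoplot.ppi_method_scores <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$group, .data$lr),
                                   y = .data$lr)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Likelihood ratio",
                  title = "Detection-method reliability") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ppi_interactome
#' @export
autoplot.ppi_network_stats <- function(object, ...) {
  plot_degree_distribution(object)
}
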