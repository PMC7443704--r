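#' Plot the partner discovery curve of a sampling run
#'
#' Cumulative unique downstream partners against draws; the flattening of
#' this curve is what the saturation stopping rule formalises.
#'
#' @param state a [sample_to_saturation()] result.
#' @return a ggplot.
#' @export
plot_discovery_curve <- function(state) {
  curve <- discovery_curve(state)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$draw, y = .data$unique_partners)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "postsynapses sampled", y = "unique partners",
      subtitle = sprintf("stopped: %s at %.0f%% of the pool",
        state$stopped, 100 * state$fraction_sampled)
    ) +
    ggplot2::theme_minimal()
}

#' Plot observed versus expected claw inputs
#'
#' Bars show observed per-class claw inputs; points show the bouton-share
#' null expectation with ±2 Monte Carlo standard errors of the replicate
#' distribution.
#'
#' @param report an [enrichment_report()] result.
#' @param by `"class"` or `"valence"`.
#' @param expected an [expected_inputs()] result (needed for the error bars
#'   when `by = "class"`; optional).
#' @return a ggplot.
#' @export
plot_enrichment <- function(report, by = c("class", "valence"), expected = NULL) {
  by <- match.arg(by)
  d <- if (by == "class") {
    dplyr::rename(report$by_class, label = "class_label")
  } else {
    dplyr::rename(report$by_valence, label = "valence")
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$label)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed), fill = "grey70") +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected), size = 2) +
    ggplot2::labs(x = NULL, y = "claw inputs",
      subtitle = "bars: observed; points: bouton-share null expectation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (by == "class" && !is.null(expected)) {
    sdr <- apply(expected$replicates, 2, stats::sd)
    eb <- tibble(label = expected$summary$class_label,
      ymin = expected$summary$expected - 2 * sdr,
      ymax = expected$summary$expected + 2 * sdr)
    p <- p + ggplot2::geom_errorbar(
      data = eb, ggplot2::aes(ymin = .data$ymin, ymax = .data$ymax),
      width = 0.2)
  }
  p
}

#' Heatmap of an adjacency table
#'
#' @param adj a [build_adjacency()] table.
#' @param drop_zero hide all-zero rows/columns.
#' @return a ggplot.
#' @export
plot_adjacency_heatmap <- function(adj, drop_zero = TRUE) {
  d <- as_tibble(adj)
  if (drop_zero) {
    keep_s <- unique(d$source[d$n > 0])
    keep_t <- unique(d$target[d$n > 0])
    d <- d[d$source %in% keep_s & d$target %in% keep_t, ]
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$target, y = .data$source,
      fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "target", y = "source", fill = "synapses") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a typing dendrogram with its cut height
#'
#' @param typing a [cluster_types()] result.
#' @param ... passed to [plot()].
#' @export
plot_typing <- function(typing, ...) {
  plot(typing$hclust, hang = -1, xlab = "", sub = "", ...)
  graphics::abline(h = typing$cut_height, lty = 2, col = "firebrick")
  invisible(typing)
}
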