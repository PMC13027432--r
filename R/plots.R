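#' Plot the per-enzyme PTM density distribution
#'
#' Histogram of PTM density across the cohort with the median marked —
#' typically strongly right-skewed, with most enzymes sparsely modified and
#' a small heavily modified tail.
#'
#' @param metrics per-enzyme metrics table with `ptm_density`.
#' @param bins number of histogram bins.
#' @return a ggplot object.
#' @export
plot_density_distribution <- function(metrics, bins = 30) {
  med <- stats::median(metrics$ptm_density)
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$ptm_density)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = med, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "PTM density (sites per residue)", y = "enzymes",
                  title = "PTM density across the cohort",
                  subtitle = sprintf("median = %.3f", med)) +
    ggplot2::theme_minimal()
}

#' @rdname silhouette_scan
#' @param object a `ptm_silhouette_scan`.
#' @param ... unused.
#' @method autoplot ptm_silhouette_scan
#' @export
autoplot.ptm_silhouette_scan <- function(object, ...) {
  sel <- attr(object, "selected_k")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$silhouette)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = sel, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::scale_x_continuous(breaks = object$k) +
    ggplot2::labs(x = "k", y = "mean silhouette width",
                  title = sprintf("Silhouette scan (%s), selected k = %d",
                                  attr(object, "method"), sel)) +
    ggplot2::theme_minimal()
}

#' Plot a PCA projection colored by cluster
#'
#' @param scores tibble from [pca_project()].
#' @param clustering optional `ptm_clustering` whose labels color the points.
#' @return a ggplot object.
#' @export
plot_pca <- function(scores, clustering = NULL) {
  ev <- attr(scores, "explained_variance")
  df <- scores
  if (!is.null(clustering)) {
    df <- dplyr::left_join(df, clustering$labels, by = "accession") |>
      dplyr::mutate(cluster = factor(.data$cluster))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  p <- if (!is.null(clustering)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$cluster), alpha = 0.7)
  } else {
    p + ggplot2::geom_point(alpha = 0.7)
  }
  p +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ev[2]),
      title = "PCA projection of the enzyme feature matrix") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
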