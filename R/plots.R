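# ggplot2 displays for the main result types.

#' Plot an allele-frequency spectrum
#'
#' @param afs Result of [allele_frequency_spectrum()].
#' @return A ggplot: SNP count per allele-frequency bin, with the modal
#'   bin highlighted.
#' @export
plot_afs <- function(afs) {
  ggplot2::ggplot(afs$spectrum,
                  ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = 1 / nrow(afs$spectrum), fill = "grey40") +
    ggplot2::geom_vline(xintercept = afs$modal_bin$bin_mid,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Alternate allele frequency", y = "SNPs",
                  title = "SNP allele-frequency spectrum") +
    ggplot2::theme_minimal()
}

#' Plot a WGD cluster-size spectrum
#'
#' @param wgd Result of [wgd_cluster_spectrum()].
#' @return A ggplot: number of clusters per cluster size, faceted by
#'   identity level.
#' @export
plot_cluster_spectrum <- function(wgd) {
  ggplot2::ggplot(wgd$spectrum,
                  ggplot2::aes(x = factor(.data$cluster_size),
                               y = .data$n_clusters)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~identity_level, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Cluster size", y = "Clusters",
                  title = "Proteome cluster-size spectrum") +
    ggplot2::theme_minimal()
}

#' Plot the dN distribution with the fast-evolving cutoff
#'
#' @param results dN/dS result tibble (column `ka`).
#' @param fraction Top fraction highlighted (default 0.10).
#' @return A ggplot histogram of Ka with the top-fraction cutoff marked.
#' @export
plot_dnds <- function(results, fraction = 0.10) {
  defined <- results[!is.na(results$ka), ]
  cutoff <- quantile(defined$ka, 1 - fraction)
  ggplot2::ggplot(defined, ggplot2::aes(x = .data$ka)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "Ka (dN)", y = "Ortholog pairs",
                  title = "Pairwise dN distribution") +
    ggplot2::theme_minimal()
}

#' Plot hub centrality
#'
#' @param hubs Result of [hub_detection()].
#' @return A ggplot: degree vs betweenness per node, hubs highlighted.
#' @export
plot_hubs <- function(hubs) {
  ggplot2::ggplot(hubs$nodes,
                  ggplot2::aes(x = .data$degree, y = .data$betweenness,
                               colour = .data$hub)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Degree", y = "Betweenness",
                  title = "Co-expression network centrality") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a co-expression graph
#'
#' @param object A `coexpression_graph`.
#' @param ... Unused.
#' @return A ggplot of the node degree distribution.
#' @method autoplot coexpression_graph
#' @export
autoplot.coexpression_graph <- function(object, ...) {
  deg <- igraph::degree(object$graph)
  ggplot2::ggplot(tibble(degree = deg), ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "Degree", y = "Genes",
                  title = "Co-expression degree distribution") +
    ggplot2::theme_minimal()
}
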