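# broom-style tidiers for fitted/derived objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a co-expression graph
#'
#' @param x A `coexpression_graph`.
#' @param ... Unused.
#' @return Edge tibble: `from`, `to`, `r`, `weight`.
#' @method tidy coexpression_graph
#' @export
tidy.coexpression_graph <- function(x, ...) {
  x$edges
}

#' One-row summary of a co-expression graph
#'
#' @param x A `coexpression_graph`.
#' @param ... Unused.
#' @return Tibble with `n_genes`, `n_edges`, `density`,
#'   `n_components`, `min_abs_corr`.
#' @method glance coexpression_graph
#' @export
glance.coexpression_graph <- function(x, ...) {
  n <- nrow(x$nodes)
  tibble(n_genes = n, n_edges = nrow(x$edges),
         density = if (n > 1) nrow(x$edges) / choose(n, 2) else NA_real_,
         n_components = igraph::count_components(x$graph),
         min_abs_corr = x$min_abs_corr)
}
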