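# Differential-expression filtering and co-expression network hub
# analysis (degree + betweenness centrality).

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up BH adjustment with monotonicity enforcement,
#' order-preserving with the input.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    gs_abort("p-values must lie in (0, 1].", "bad_pvalue")
  }
  p.adjust(p, method = "BH")
}

#' Filter DE statistics into up- and down-regulated sets
#'
#' A gene is differentially expressed when its FDR-adjusted p-value is
#' below `alpha` and its absolute log2 fold change is at least
#' `min_abs_lfc`. When the `p_adj` column is absent it is computed from
#' `p_raw` with [bh_adjust()].
#'
#' @param stats Data frame with columns `gene_id`, `log2fc`, and `p_adj`
#'   and/or `p_raw`.
#' @param alpha Adjusted-p threshold, strict (default 0.05).
#' @param min_abs_lfc Absolute log2-fold-change threshold, inclusive
#'   (default 1).
#' @return List with `up` and `down` (character vectors of gene ids) and
#'   `stats` (input tibble plus `p_adj` and `de` columns:
#'   `"up"` / `"down"` / `NA`).
#' @export
de_filter <- function(stats, alpha = 0.05, min_abs_lfc = 1.0) {
  stats <- as_tibble(stats)
  if (!"p_adj" %in% names(stats)) {
    if (!"p_raw" %in% names(stats)) {
      gs_abort("Need a `p_adj` or `p_raw` column.", "missing_pvalue")
    }
    stats$p_adj <- bh_adjust(stats$p_raw)
  }
  stats <- stats %>%
    mutate(de = dplyr::case_when(
      .data$p_adj < alpha & .data$log2fc >= min_abs_lfc ~ "up",
      .data$p_adj < alpha & .data$log2fc <= -min_abs_lfc ~ "down",
      TRUE ~ NA_character_))
  list(up = stats$gene_id[!is.na(stats$de) & stats$de == "up"],
       down = stats$gene_id[!is.na(stats$de) & stats$de == "down"],
       stats = stats)
}

#' Build a co-expression graph from an expression matrix
#'
#' Computes Pearson correlations between genes on log2(x + 1)-transformed
#' values and connects gene pairs whose absolute correlation reaches
#' `min_abs_corr`; edge weight is |r|. Zero-variance genes are excluded
#' with a warning.
#'
#' @param expr Numeric matrix (genes x samples, gene rownames) or data
#'   frame with a `gene_id` column plus sample columns.
#' @param min_abs_corr Absolute-correlation edge threshold.
#' @return A `coexpression_graph` object: list with `graph` (igraph),
#'   `nodes` (tibble `gene_id`), `edges` (tibble `from`, `to`, `r`,
#'   `weight`).
#' @export
build_coexpression_graph <- function(expr, min_abs_corr) {
  if (is.data.frame(expr)) {
    m <- as.matrix(expr[, setdiff(names(expr), "gene_id")])
    rownames(m) <- expr$gene_id
  } else {
    m <- as.matrix(expr)
  }
  if (ncol(m) < 3) {
    gs_abort("Need at least 3 samples per gene.", "too_few_samples")
  }
  if (any(m < 0)) gs_abort("Expression values must be non-negative.",
                           "bad_input")
  lm2 <- log2(m + 1)
  v <- apply(lm2, 1, sd)
  if (any(v == 0)) {
    gs_warn(paste0(sum(v == 0), " zero-variance gene(s) excluded."),
            "zero_variance")
    lm2 <- lm2[v > 0, , drop = FALSE]
  }
  r <- cor(t(lm2))
  diag(r) <- 0
  idx <- which(abs(r) >= min_abs_corr & upper.tri(r), arr.ind = TRUE)
  rv <- r[idx]
  edges <- tibble(from = rownames(r)[idx[, 1]],
                  to = colnames(r)[idx[, 2]],
                  r = rv,
                  weight = abs(rv))
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "weight")], directed = FALSE,
    vertices = rownames(r))
  structure(list(graph = g, nodes = tibble(gene_id = rownames(r)),
                 edges = edges, min_abs_corr = min_abs_corr),
            class = "coexpression_graph")
}

#' @export
print.coexpression_graph <- function(x, ...) {
  cat("<coexpression_graph> ", nrow(x$nodes), " genes, ", nrow(x$edges),
      " edges (|r| >= ", x$min_abs_corr, ")\n", sep = "")
  invisible(x)
}

as_igraph_graph <- function(graph) {
  if (inherits(graph, "coexpression_graph")) graph$graph
  else if (inherits(graph, "igraph")) graph
  else gs_abort("Expected a coexpression_graph or igraph object.",
                "bad_input")
}

#' Detect network hubs by degree and betweenness centrality
#'
#' Computes each node's degree (adjacent-neighbour count) and unweighted
#' shortest-path betweenness (Brandes' algorithm, endpoints excluded,
#' components handled independently) and flags as hubs the nodes that lie
#' in BOTH the top `ceiling(top_fraction * n)` by degree and by
#' betweenness (boundary ties included, so the result does not depend on
#' node order). Set `rule = "union"` for either-list membership.
#'
#' @param graph A `coexpression_graph` or igraph object.
#' @param top_fraction Fraction of nodes forming each top list
#'   (default 0.10).
#' @param rule `"intersection"` (default) or `"union"` of the two top
#'   lists.
#' @return List with `nodes` (tibble `gene_id`, `degree`, `betweenness`,
#'   `top_degree`, `top_betweenness`, `hub`) and `hubs` (character
#'   vector).
#' @export
hub_detection <- function(graph, top_fraction = 0.10,
                          rule = c("intersection", "union")) {
  rule <- match.arg(rule)
  g <- as_igraph_graph(graph)
  n <- igraph::vcount(g)
  if (n == 0) gs_abort("Empty graph.", "empty_graph")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = NA, normalized = FALSE)
  k <- ceiling(top_fraction * n)
  top_cut <- function(x) sort(x, decreasing = TRUE)[k]
  top_deg <- deg >= top_cut(deg)
  top_btw <- btw >= top_cut(btw)
  hub <- if (rule == "intersection") top_deg & top_btw else
    top_deg | top_btw
  nodes <- tibble(gene_id = names(deg), degree = unname(deg),
                  betweenness = unname(btw),
                  top_degree = unname(top_deg),
                  top_betweenness = unname(top_btw),
                  hub = unname(hub)) %>%
    arrange(desc(.data$degree), desc(.data$betweenness))
  list(nodes = nodes, hubs = nodes$gene_id[nodes$hub])
}

#' Fisher enrichment of DE genes in co-expression modules
#'
#' For each module, a one-sided Fisher exact test of DE-set membership in
#' the module against the background of all module-assigned genes.
#'
#' @param modules Data frame (`gene_id`, `module`).
#' @param de_genes Character vector of DE gene ids (e.g. the up-regulated
#'   set of one contrast).
#' @param alpha Significance threshold (default 0.05).
#' @return Tibble: `module`, `k` (DE genes in module), `module_size`,
#'   `n_de` (DE genes in background), `n_background`, `p_value`,
#'   `significant`.
#' @export
module_de_enrichment <- function(modules, de_genes, alpha = 0.05) {
  modules <- as_tibble(modules) %>% distinct()
  background <- unique(modules$gene_id)
  de_bg <- intersect(de_genes, background)
  N <- length(background)
  res <- map(unique(modules$module), function(mod) {
    members <- modules$gene_id[modules$module == mod]
    if (length(members) == 0) {
      gs_warn(paste0("Module ", mod, " is empty; skipped."), "empty_module")
      return(NULL)
    }
    k <- length(intersect(members, de_bg))
    p <- phyper(k - 1, m = length(de_bg), n = N - length(de_bg),
                k = length(members), lower.tail = FALSE)
    tibble(module = mod, k = k, module_size = length(members),
           n_de = length(de_bg), n_background = N,
           p_value = p, significant = p < alpha)
  })
  bind_rows(res) %>% arrange(.data$p_value)
}
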