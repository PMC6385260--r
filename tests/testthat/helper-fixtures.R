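# Programmatic fixtures shared across test files.

# Random locus configurations for the merge-rule tests: each locus lives in
# its own 10 kbp window so loci cannot interact, and contains 0-3 ab initio
# models and 0-1 homology model with random intervals and completeness.
random_locus_models <- function(n_loci, seed) {
  set.seed(seed)
  a_rows <- list(); h_rows <- list()
  for (l in seq_len(n_loci)) {
    base <- (l - 1) * 10000 + 1
    strand <- sample(c("+", "-"), 1)
    contig <- paste0("c", ((l - 1) %% 3) + 1)
    n_a <- sample(0:3, 1)
    n_h <- sample(0:1, 1, prob = c(0.2, 0.8))
    if (n_a > 0) {
      for (k in seq_len(n_a)) {
        s <- base + sample(0:4000, 1)
        e <- s + sample(200:2500, 1)
        a_rows[[length(a_rows) + 1]] <- tibble::tibble(
          gene_id = sprintf("A%03d_%d", l, k), contig = contig,
          strand = strand, start = s, end = e, source = "abinitio",
          completeness = round(runif(1, 0.4, 1), 2))
      }
    }
    if (n_h > 0) {
      s <- base + sample(0:3000, 1)
      e <- s + sample(500:5000, 1)
      h_rows[[length(h_rows) + 1]] <- tibble::tibble(
        gene_id = sprintf("H%03d", l), contig = contig, strand = strand,
        start = s, end = e, source = "homology",
        completeness = round(runif(1, 0.4, 1), 2))
    }
  }
  list(abinitio = dplyr::bind_rows(a_rows), homology = dplyr::bind_rows(h_rows))
}

# A small annotated universe for enrichment tests.
make_annotation_universe <- function(n_genes = 1000, n_terms = 30, seed = 1) {
  set.seed(seed)
  genes <- sprintf("u%04d", seq_len(n_genes))
  anns <- lapply(seq_len(n_terms), function(t) {
    size <- sample(50:200, 1)
    tibble::tibble(gene_id = sample(genes, size),
                   term = sprintf("GO:%07d", t))
  })
  list(genes = genes, annotations = dplyr::bind_rows(anns))
}

adj_from_igraph <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}
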