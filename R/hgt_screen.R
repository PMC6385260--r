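# Phylogenomic screen for lineage-specific horizontal gene transfer and
# gene-transfer-agent (GTA) hallmark scoring of candidate bacterial gene
# clusters.

order_hits <- function(hits, by = c("bitscore", "identity")) {
  by <- match.arg(by)
  if (by == "bitscore") {
    hits[order(-hits$bitscore, hits$subject_id), ]
  } else {
    hits[order(-hits$identity, hits$subject_id), ]
  }
}

#' Prefilter HGT queries by the taxonomy of their top hit
#'
#' Queries whose best database hit (highest bitscore; ties broken by
#' subject id) is a coral or any other metazoan are removed from the HGT
#' candidate pool; queries with no hits at all are likewise dropped.
#'
#' @param hits Homology hit tibble (see [read_hits()]); may cover many
#'   queries.
#' @return Tibble with one row per query: `query_id`, `top_subject_id`,
#'   `top_is_metazoan`, `candidate` (logical).
#' @export
prefilter_queries <- function(hits) {
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) {
    return(tibble(query_id = character(), top_subject_id = character(),
                  top_is_metazoan = logical(), candidate = logical()))
  }
  hits %>%
    group_by(.data$query_id) %>%
    arrange(desc(.data$bitscore), .data$subject_id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    transmute(query_id = .data$query_id,
              top_subject_id = .data$subject_id,
              top_is_metazoan = .data$is_metazoan,
              candidate = !.data$is_metazoan)
}

#' Select representative subjects for tree building
#'
#' Builds two representative sets from one query's hits and returns their
#' union. Set 1 scans hits by descending bitscore, accepting hits
#' first-come-first-served while the hit's phylum has fewer than
#' `per_phylum_cap` accepted members. Set 2 restricts to hits with
#' alignment length at least `min_align_len`, re-sorts by descending
#' identity, and applies the same per-phylum scan. Ties are broken by
#' subject id; the union preserves first-seen order.
#'
#' @param hits Hit tibble for a single query.
#' @param per_phylum_cap Maximum representatives per phylum in each set
#'   (default 6).
#' @param min_align_len Alignment-length floor for the identity-sorted set
#'   (default 200 aa).
#' @return The selected hit rows, deduplicated by subject id, in selection
#'   order.
#' @export
select_representatives <- function(hits, per_phylum_cap = 6,
                                   min_align_len = 200) {
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) gs_abort("No hits supplied.", "empty_input")
  if (length(unique(hits$query_id)) > 1) {
    gs_abort("`hits` must belong to a single query.", "bad_input")
  }
  fcfs <- function(h) {
    sel <- logical(nrow(h))
    counts <- list()
    for (i in seq_len(nrow(h))) {
      p <- h$phylum[i]
      k <- counts[[p]] %||% 0L
      if (k < per_phylum_cap) {
        sel[i] <- TRUE
        counts[[p]] <- k + 1L
      }
    }
    h[sel, ]
  }
  set1 <- fcfs(order_hits(hits, "bitscore"))
  long <- hits[hits$align_len >= min_align_len, , drop = FALSE]
  set2 <- if (nrow(long) > 0) fcfs(order_hits(long, "identity")) else long
  combined <- bind_rows(set1, set2)
  combined[!duplicated(combined$subject_id), ]
}

# Leaves of the subtree rooted at `node` of a rooted phylo tree.
subtree_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, subtree_tips, tree = tree))
}

#' Classify the provenance of a query gene from its phylogeny
#'
#' Roots the gene tree (midpoint by default, or on a supplied outgroup)
#' and inspects the smallest clade containing the query and at least one
#' other leaf: if all non-query leaves of that clade are non-metazoan
#' the gene is called `non_metazoan`; if all are metazoan, `metazoan`;
#' otherwise `ambiguous`. The supporting clade is returned so calls can be
#' audited.
#'
#' @param tree An `ape::phylo` tree or a newick string.
#' @param query Tip label of the query gene.
#' @param taxonomy Data frame with columns `id` and `is_metazoan` covering
#'   all non-query leaves.
#' @param outgroup Optional tip label; when given, the tree is rooted on
#'   it instead of at the midpoint.
#' @return One-row tibble: `query_id`, `call` (`non_metazoan` /
#'   `metazoan` / `ambiguous`), `clade_leaves` (comma-separated support),
#'   `n_clade_metazoan`, `n_clade_nonmetazoan`.
#' @export
classify_provenance <- function(tree, query, taxonomy, outgroup = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!query %in% tree$tip.label) {
    gs_abort(paste0("Query '", query, "' is not a leaf of the tree."),
             "query_absent")
  }
  if (length(tree$tip.label) < 3) {
    gs_abort("Tree must have at least 3 leaves.", "bad_input")
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  tree <- if (!is.null(outgroup)) {
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  } else {
    phangorn::midpoint(tree)
  }
  taxonomy <- as_tibble(taxonomy)
  tax <- setNames(as.logical(taxonomy$is_metazoan), taxonomy$id)
  n_tip <- length(tree$tip.label)
  qnode <- which(tree$tip.label == query)
  parent_of <- function(node) {
    p <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(p) == 0) NA_integer_ else p
  }
  # sister-clade composition: the smallest ancestor clade holding the query
  # plus at least one other leaf decides the call
  node <- qnode
  clade <- character(0)
  repeat {
    node <- parent_of(node)
    if (is.na(node)) break
    clade <- setdiff(subtree_tips(tree, node), query)
    if (length(clade) >= 1) break
  }
  if (length(clade) == 0) {
    clade <- setdiff(tree$tip.label, query)
  }
  met <- tax[clade]
  if (any(is.na(met))) {
    gs_abort("Taxonomy missing for some clade leaves.", "bad_input")
  }
  call <- if (all(!met)) "non_metazoan" else if (all(met)) "metazoan"
          else "ambiguous"
  tibble(query_id = query, call = call,
         clade_leaves = paste(clade, collapse = ","),
         n_clade_metazoan = sum(met),
         n_clade_nonmetazoan = sum(!met))
}

#' Score GTA hallmarks of a candidate gene cluster
#'
#' Scores four hallmarks of a gene-transfer-agent mediated insertion:
#' (1) the cluster span falls within the DNA packaging size range of GTAs
#' (4-14 kbp by default); (2) every candidate gene is intronless (single
#' exon); (3) the candidates are physically contiguous, with no
#' non-candidate gene interleaved; (4) the nearest non-candidate gene on
#' each side exists and is of metazoan provenance.
#'
#' @param candidate_ids Gene ids of the candidate cluster.
#' @param genes Exon-level gene-model tibble for the whole contig.
#' @param provenance Data frame (`gene_id`, `call`) giving the provenance
#'   call of at least the non-candidate genes on the contig.
#' @param span_range Length-2 numeric, inclusive span window in bp
#'   (default `c(4000, 14000)`).
#' @return One-row tibble: `contig`, `span_bp`, the four logical criteria
#'   (`span_in_range`, `intronless`, `contiguous`, `flanks_metazoan`),
#'   `n_criteria_passed`, and the flanking gene ids (NA when absent).
#' @export
gta_hallmarks <- function(candidate_ids, genes, provenance,
                          span_range = c(4000, 14000)) {
  genes <- validate_models(as_tibble(genes), "annotation")
  spans <- gene_spans(genes) %>% arrange(.data$start)
  cand <- spans %>% filter(.data$gene_id %in% candidate_ids)
  if (nrow(cand) == 0) gs_abort("No candidate genes found.", "bad_input")
  if (length(unique(cand$contig)) > 1) {
    gs_abort("Candidate genes span multiple contigs.", "multi_contig")
  }
  ctg <- cand$contig[1]
  on_contig <- spans %>% filter(.data$contig == ctg)
  span_bp <- max(cand$end) - min(cand$start) + 1
  crit_span <- span_bp >= span_range[1] && span_bp <= span_range[2]
  exon_counts <- genes %>%
    filter(.data$gene_id %in% candidate_ids) %>%
    count(.data$gene_id)
  crit_intronless <- all(exon_counts$n == 1)
  idx <- which(on_contig$gene_id %in% candidate_ids)
  crit_contig <- length(idx) == nrow(cand) &&
    all(diff(sort(idx)) == 1)
  prov <- as_tibble(provenance)
  call_of <- setNames(prov$call, prov$gene_id)
  left_idx <- min(idx) - 1
  right_idx <- max(idx) + 1
  left_id <- if (left_idx >= 1) on_contig$gene_id[left_idx] else NA_character_
  right_id <- if (right_idx <= nrow(on_contig))
    on_contig$gene_id[right_idx] else NA_character_
  flank_met <- function(id) {
    !is.na(id) && !is.na(call_of[id]) && call_of[id] == "metazoan"
  }
  crit_flanks <- flank_met(left_id) && flank_met(right_id)
  tibble(contig = ctg, span_bp = span_bp,
         span_in_range = crit_span, intronless = crit_intronless,
         contiguous = crit_contig, flanks_metazoan = crit_flanks,
         n_criteria_passed = sum(crit_span, crit_intronless, crit_contig,
                                 crit_flanks),
         flank_left = left_id, flank_right = right_id)
}

#' Expression check for HGT candidate genes
#'
#' @param gene_ids Candidate gene ids.
#' @param counts Expression matrix: either a numeric matrix with gene
#'   rownames or a data frame with a `gene_id` column plus sample columns.
#' @return Tibble `gene_id`, `mean_count`, `expressed` (mean > 0).
#' @export
hgt_expression_lookup <- function(gene_ids, counts) {
  if (is.data.frame(counts)) {
    m <- as.matrix(counts[, setdiff(names(counts), "gene_id")])
    rownames(m) <- counts$gene_id
  } else {
    m <- as.matrix(counts)
  }
  missing <- setdiff(gene_ids, rownames(m))
  if (length(missing) > 0) {
    gs_abort(paste0("Genes absent from the count matrix: ",
                    paste(missing, collapse = ", ")), "missing_id")
  }
  means <- rowMeans(m[gene_ids, , drop = FALSE])
  tibble(gene_id = gene_ids, mean_count = unname(means),
         expressed = unname(means) > 0)
}

#' Run the full lineage-specific HGT screen
#'
#' Chains the screen end to end: taxonomic prefilter on top hits,
#' per-phylum representative selection, global-alignment distances and a
#' neighbor-joining gene tree per candidate, provenance classification
#' from the tree, grouping of contiguous non-metazoan genes into clusters,
#' and GTA hallmark scoring of each cluster.
#'
#' @param proteome Data frame (`id`, `seq`) of query proteins.
#' @param hits Homology hit tibble covering the queries.
#' @param subject_seqs Data frame (`id`, `seq`) with the subject proteins
#'   referenced by the hits.
#' @param genes Exon-level gene-model tibble (gene ids match query ids).
#' @param per_phylum_cap,min_align_len Passed to
#'   [select_representatives()].
#' @param span_range Passed to [gta_hallmarks()].
#' @return List with `calls` (per-gene provenance tibble) and `clusters`
#'   (one hallmark row per contiguous non-metazoan cluster, with a
#'   `gene_ids` column).
#' @export
screen_hgt <- function(proteome, hits, subject_seqs, genes,
                       per_phylum_cap = 6, min_align_len = 200,
                       span_range = c(4000, 14000)) {
  proteome <- as_tibble(proteome)
  hits <- as_tibble(hits)
  subject_seqs <- as_tibble(subject_seqs)
  pre <- prefilter_queries(hits)
  calls <- tibble(gene_id = proteome$id) %>%
    left_join(pre, by = c(gene_id = "query_id")) %>%
    mutate(call = dplyr::case_when(
      is.na(.data$candidate) ~ "ambiguous",      # no hits at all
      !.data$candidate ~ "metazoan",             # metazoan top hit
      TRUE ~ NA_character_))
  todo <- calls$gene_id[is.na(calls$call)]
  for (q in todo) {
    qh <- hits %>% filter(.data$query_id == q)
    reps <- select_representatives(qh, per_phylum_cap = per_phylum_cap,
                                   min_align_len = min_align_len)
    ids <- c(q, reps$subject_id)
    seqs <- c(proteome$seq[proteome$id == q],
              subject_seqs$seq[match(reps$subject_id, subject_seqs$id)])
    if (length(ids) < 3) {
      calls$call[calls$gene_id == q] <- "ambiguous"
      next
    }
    d <- identity_dist_matrix(seqs, ids, alphabet = "protein")
    tree <- nj_tree(d)
    tree$edge.length[tree$edge.length < 0] <- 0
    taxonomy <- reps %>%
      transmute(id = .data$subject_id, is_metazoan = .data$is_metazoan)
    calls$call[calls$gene_id == q] <-
      classify_provenance(tree, q, taxonomy)$call
  }
  calls <- calls %>% select("gene_id", "call")
  spans <- gene_spans(validate_models(genes, "annotation")) %>%
    left_join(calls, by = "gene_id") %>%
    arrange(.data$contig, .data$start)
  clusters <- list()
  for (ctg in unique(spans$contig)) {
    s <- spans %>% filter(.data$contig == ctg)
    is_hgt <- !is.na(s$call) & s$call == "non_metazoan"
    r <- rle(is_hgt)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      ids <- s$gene_id[starts[k]:ends[k]]
      hall <- gta_hallmarks(ids, genes, calls %>% rename(call = "call"),
                            span_range = span_range)
      hall$gene_ids <- paste(ids, collapse = ",")
      clusters[[length(clusters) + 1]] <- hall
    }
  }
  list(calls = calls,
       clusters = if (length(clusters) > 0) bind_rows(clusters) else
         tibble())
}
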