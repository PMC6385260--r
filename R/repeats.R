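# Repeat-library curation and repeat/SCOR landscape analytics.

#' Deduplicate a repeat family library
#'
#' Clusters family consensus sequences at `identity_cutoff` (Cd-hit style,
#' via [greedy_cluster()]) and keeps one representative — the longest
#' consensus — per cluster.
#'
#' @param families Data frame with columns `family_id`, `consensus`
#'   (nucleotide string) and optionally `classification`.
#' @param identity_cutoff Clustering identity threshold (default 0.85).
#' @return The retained subset of `families`, one row per cluster.
#' @export
dedupe_repeat_families <- function(families, identity_cutoff = 0.85) {
  families <- as_tibble(families)
  if (nrow(families) == 0) return(families)
  seqs <- tibble(id = families$family_id, seq = families$consensus)
  cl <- greedy_cluster(seqs, identity_cutoff = identity_cutoff,
                       min_coverage = 0, alphabet = "dna")
  # representatives are the cluster founders, i.e. the longest member
  # (ties by id) because greedy_cluster processes by descending length
  families %>% filter(.data$family_id %in% unique(cl$representative))
}

#' Drop unknown repeat families that match known proteins
#'
#' Families classified "unknown" whose consensus hit a protein database are
#' presumed to be fragments of real genes and are discarded; classified
#' families are always retained.
#'
#' @param families Repeat family tibble with columns `family_id`,
#'   `classification`.
#' @param protein_hits Character vector of family ids with a protein hit.
#' @return The retained subset of `families`.
#' @export
filter_unknown_families <- function(families, protein_hits) {
  families <- as_tibble(families)
  stray <- setdiff(protein_hits, families$family_id)
  if (length(stray) > 0) {
    gs_warn(paste0("Ignoring protein hits for unknown family ids: ",
                   paste(stray, collapse = ", ")), "unknown_ids")
  }
  families %>%
    filter(!(.data$classification == "unknown" &
               .data$family_id %in% protein_hits))
}

#' Repeat-masked fraction of the genome
#'
#' Computes the union of repeat-hit intervals per contig (overlaps counted
#' once) and divides by the assembly length.
#'
#' @param hits Repeat hit tibble (`family_id`, `contig`, `start`, `end`).
#' @param assembly_length Total assembly length in bp.
#' @param contig_lengths Optional named vector of contig lengths; when
#'   supplied, hits beyond a contig end raise an error.
#' @return List with `masked_bases` (bp), `fraction`, and
#'   `fraction_percent` (rounded to the nearest integer percent for
#'   summary display).
#' @export
repeat_genome_fraction <- function(hits, assembly_length,
                                   contig_lengths = NULL) {
  if (assembly_length <= 0) {
    gs_abort("`assembly_length` must be positive.", "bad_input")
  }
  hits <- as_tibble(hits)
  if (!is.null(contig_lengths) && nrow(hits) > 0) {
    lim <- contig_lengths[hits$contig]
    if (any(is.na(lim)) || any(hits$end > lim)) {
      gs_abort("Repeat hit extends beyond its contig.", "bad_coordinates")
    }
  }
  masked <- 0
  if (nrow(hits) > 0) {
    gr <- GenomicRanges::GRanges(hits$contig,
                                 IRanges::IRanges(hits$start, hits$end))
    masked <- sum(GenomicRanges::width(GenomicRanges::reduce(gr)))
  }
  frac <- masked / assembly_length
  list(masked_bases = masked, fraction = frac,
       fraction_percent = round(100 * frac))
}

#' Assign repeat hits to genomic compartments
#'
#' Labels each repeat hit by the compartment its midpoint falls in: intron
#' (between two exons of a gene), exon, UTR (only when UTR features are
#' provided; otherwise UTR space counts as exon), or intergenic. Also
#' reports per-family, per-compartment counts and the number of distinct
#' genes carrying at least one intronic hit.
#'
#' @param hits Repeat hit tibble (`family_id`, `contig`, `start`, `end`).
#' @param genes Exon-level gene-model tibble.
#' @param utrs Optional tibble (`contig`, `start`, `end`) of UTR features.
#' @return List with `hits` (input plus `compartment` column),
#'   `counts` (tibble `family_id`, `compartment`, `n`) and
#'   `genes_with_intronic_hits` (integer).
#' @export
annotate_compartments <- function(hits, genes, utrs = NULL) {
  hits <- as_tibble(hits)
  genes <- as_tibble(genes)
  if (nrow(hits) == 0) {
    return(list(hits = mutate(hits, compartment = character(0)),
                counts = tibble(family_id = character(),
                                compartment = character(), n = integer()),
                genes_with_intronic_hits = 0L))
  }
  mid <- floor((hits$start + hits$end) / 2)
  mid_gr <- GenomicRanges::GRanges(hits$contig, IRanges::IRanges(mid, mid))
  compartment <- rep("intergenic", nrow(hits))
  intron_gene <- rep(NA_character_, nrow(hits))

  spans <- gene_spans(validate_models(genes, "annotation"))
  exon_gr <- GenomicRanges::GRanges(genes$contig,
                                    IRanges::IRanges(genes$start, genes$end))
  span_gr <- GenomicRanges::GRanges(spans$contig,
                                    IRanges::IRanges(spans$start, spans$end))
  # hits on contigs without genes legitimately share no seqlevels
  in_span <- suppressWarnings(
    GenomicRanges::findOverlaps(mid_gr, span_gr, ignore.strand = TRUE))
  in_exon <- unique(S4Vectors::queryHits(suppressWarnings(
    GenomicRanges::findOverlaps(mid_gr, exon_gr, ignore.strand = TRUE))))
  genic <- unique(S4Vectors::queryHits(in_span))
  compartment[genic] <- "intron"
  compartment[in_exon] <- "exon"
  # record one host gene per intronic hit (first span containing it)
  intronic <- setdiff(genic, in_exon)
  first_span <- tapply(S4Vectors::subjectHits(in_span),
                       S4Vectors::queryHits(in_span), min)
  intron_gene[intronic] <-
    spans$gene_id[first_span[as.character(intronic)]]
  if (!is.null(utrs) && nrow(as_tibble(utrs)) > 0) {
    utrs <- as_tibble(utrs)
    utr_gr <- GenomicRanges::GRanges(utrs$contig,
                                     IRanges::IRanges(utrs$start, utrs$end))
    in_utr <- unique(S4Vectors::queryHits(suppressWarnings(
      GenomicRanges::findOverlaps(mid_gr, utr_gr, ignore.strand = TRUE))))
    compartment[in_utr] <- "utr"
  }
  out <- mutate(hits, compartment = compartment)
  counts <- out %>% count(.data$family_id, .data$compartment, name = "n")
  list(hits = out, counts = counts,
       genes_with_intronic_hits =
         length(unique(intron_gene[compartment == "intron" &
                                     !is.na(intron_gene)])))
}

#' Correlation between SCOR prevalence and intron length
#'
#' Spearman rank correlation (mid-rank ties) between per-gene total intron
#' length and per-gene SCOR hit count, with a two-sided p-value.
#'
#' @param gene_stats Data frame with columns `total_intron_length` (bp)
#'   and `scor_hit_count`.
#' @return One-row tibble with `rho`, `p_value`, `n_genes`.
#' @export
scor_intron_correlation <- function(gene_stats) {
  gene_stats <- as_tibble(gene_stats)
  x <- gene_stats$total_intron_length
  y <- gene_stats$scor_hit_count
  if (length(x) < 3) gs_abort("Need at least 3 genes.", "bad_input")
  if (sd(x) == 0 || sd(y) == 0) {
    gs_abort("Constant input: correlation undefined.", "degenerate")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = FALSE))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value,
         n_genes = length(x))
}
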