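# Assembly-level diagnostics: genome size from mapped coverage, the SNP
# allele-frequency diploidy spectrum, the haplotig self-similarity scan,
# and the cluster-size spectrum test for whole-genome duplication.

#' Estimate genome size from mapped bases and mean coverage
#'
#' The classic back-of-envelope estimator: total mapped read bases divided
#' by mean per-base coverage, truncated to an integer base-pair count.
#'
#' @param total_mapped_bases Sum of all mapped read bases (bp).
#' @param mean_coverage Mean per-base coverage (x), must be positive.
#' @return Genome size estimate in bp (integer-valued double,
#'   `floor(total/coverage)`).
#' @export
estimate_genome_size <- function(total_mapped_bases, mean_coverage) {
  if (!is.numeric(mean_coverage) || length(mean_coverage) != 1 ||
      is.na(mean_coverage) || mean_coverage <= 0) {
    gs_abort("`mean_coverage` must be a positive number.", "bad_coverage")
  }
  if (!is.numeric(total_mapped_bases) || total_mapped_bases < 0) {
    gs_abort("`total_mapped_bases` must be non-negative.", "bad_input")
  }
  floor(total_mapped_bases / mean_coverage)
}

#' Allele-frequency spectrum of biallelic SNPs
#'
#' Computes the alternate-allele frequency of every SNP
#' (`alt / (ref + alt)`) and bins it over \[0, 1\]. In a clean diploid
#' assembly of a single genotype the spectrum peaks at 0.5; a mode near 1
#' indicates haploid contamination or collapsed repeats.
#'
#' @param snps Data frame with columns `ref_count`, `alt_count`.
#' @param bins Number of equal-width bins over \[0, 1\] (default 50).
#'   Bins are half-open `[lo, hi)` except the final closed bin.
#' @return List with `spectrum` (tibble: `bin_lo`, `bin_mid`, `bin_hi`,
#'   `count`), `modal_bin` (one-row tibble for the fullest bin; ties go to
#'   the lower bin) and `n_snps`.
#' @export
allele_frequency_spectrum <- function(snps, bins = 50) {
  snps <- as_tibble(snps)
  if (nrow(snps) == 0) gs_abort("No SNPs supplied.", "empty_input")
  if (bins < 2) gs_abort("`bins` must be at least 2.", "bad_input")
  tot <- snps$ref_count + snps$alt_count
  if (any(tot <= 0) || any(snps$ref_count < 0) || any(snps$alt_count < 0)) {
    gs_abort("SNP counts must be non-negative with positive totals.",
             "bad_input")
  }
  freq <- snps$alt_count / tot
  idx <- pmin(floor(freq * bins) + 1L, bins)
  counts <- tabulate(idx, nbins = bins)
  spectrum <- tibble(
    bin_lo = (seq_len(bins) - 1) / bins,
    bin_mid = (seq_len(bins) - 0.5) / bins,
    bin_hi = seq_len(bins) / bins,
    count = counts
  )
  modal <- spectrum[which.max(spectrum$count), ]
  list(spectrum = spectrum, modal_bin = modal, n_snps = nrow(snps))
}

#' Scan self-alignment hits for residual haplotigs
#'
#' Filters a contig-vs-contig alignment table to hits above an identity
#' threshold on distinct contigs; long surviving hits flag alternate
#' haplotypes that were not purged from the primary assembly.
#'
#' @param hits Data frame with columns `contig_a`, `contig_b`, `identity`
#'   (percent) and `length` (bp).
#' @param min_identity Identity threshold in percent; hits strictly above
#'   it are kept (default 99).
#' @return List with `hits` (retained rows sorted by length descending)
#'   and `max_length` (bp; 0 when nothing is retained).
#' @export
haplotig_scan <- function(hits, min_identity = 99) {
  if (min_identity <= 0 || min_identity > 100) {
    gs_abort("`min_identity` must be in (0, 100].", "bad_input")
  }
  hits <- as_tibble(hits)
  kept <- hits %>%
    filter(.data$identity > min_identity, .data$contig_a != .data$contig_b) %>%
    arrange(desc(.data$length))
  list(hits = kept,
       max_length = if (nrow(kept) == 0) 0L else max(kept$length))
}

#' Cluster-size spectrum test for whole-genome duplication
#'
#' Clusters the full proteome against itself at each identity level
#' (requiring a minimum aligned coverage) and tabulates cluster sizes. A
#' genome that underwent recent WGD shows a dominant cluster size of 2;
#' a dominant size of 1 argues against WGD.
#'
#' @param proteome Data frame with columns `id`, `seq` (amino acids).
#' @param identity_levels Identity fractions to test
#'   (default `c(0.9, 0.7, 0.5)`).
#' @param min_coverage Minimum aligned coverage of the shorter sequence
#'   (default 0.7).
#' @return List with `spectrum` (tibble: `identity_level`, `cluster_size`,
#'   `n_clusters`) and `dominant` (tibble: `identity_level`,
#'   `dominant_size`; ties broken toward the smaller size).
#' @export
wgd_cluster_spectrum <- function(proteome,
                                 identity_levels = c(0.9, 0.7, 0.5),
                                 min_coverage = 0.7) {
  proteome <- as_tibble(proteome)
  if (nrow(proteome) == 0) gs_abort("Empty proteome.", "empty_input")
  if (any(identity_levels <= 0 | identity_levels > 1)) {
    gs_abort("Identity levels must lie in (0, 1].", "bad_input")
  }
  spectra <- map(identity_levels, function(level) {
    cl <- greedy_cluster(proteome, identity_cutoff = level,
                         min_coverage = min_coverage, alphabet = "protein")
    sizes <- cl %>% count(.data$cluster, name = "size")
    sizes %>%
      count(.data$size, name = "n_clusters") %>%
      mutate(identity_level = level, cluster_size = .data$size) %>%
      select("identity_level", "cluster_size", "n_clusters")
  })
  spectrum <- bind_rows(spectra)
  dominant <- spectrum %>%
    group_by(.data$identity_level) %>%
    arrange(desc(.data$n_clusters), .data$cluster_size, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    transmute(identity_level = .data$identity_level,
              dominant_size = .data$cluster_size)
  list(spectrum = spectrum, dominant = dominant)
}
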