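# Reconciliation of ab initio and homology-based gene models, gene-model
# filtering, and gene-family expansion / Venn-partition statistics.
#
# Gene models are exon-level tibbles: one row per exon with columns
# `gene_id`, `contig`, `strand`, `start`, `end` (1-based inclusive),
# `source` ("abinitio" or "homology") and `completeness` (fraction or NA).

gene_spans <- function(models) {
  models %>%
    group_by(.data$gene_id) %>%
    summarise(contig = first(.data$contig), strand = first(.data$strand),
              start = min(.data$start), end = max(.data$end),
              source = first(.data$source),
              completeness = if ("completeness" %in% names(models))
                first(.data$completeness) else NA_real_,
              .groups = "drop")
}

validate_models <- function(models, source) {
  models <- as_tibble(models)
  need <- c("gene_id", "contig", "strand", "start", "end")
  if (!all(need %in% names(models))) {
    gs_abort(paste0("Gene models need columns: ", paste(need, collapse = ", ")),
             "bad_input")
  }
  if (any(models$start > models$end)) {
    gs_abort("Exon start must not exceed end.", "bad_input")
  }
  bad <- models %>%
    group_by(.data$gene_id) %>%
    summarise(multi = dplyr::n_distinct(.data$contig) > 1 ||
                dplyr::n_distinct(.data$strand) > 1, .groups = "drop")
  if (any(bad$multi)) {
    gs_abort("All exons of a gene must share one contig and strand.",
             "bad_input")
  }
  if (!"source" %in% names(models)) models$source <- source
  if (!"completeness" %in% names(models)) models$completeness <- NA_real_
  models
}

spans_overlap <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

#' Map homology gene models onto overlapping ab initio models
#'
#' Two models overlap when they lie on the same contig and strand and their
#' exon-span (gene-extent) intervals intersect in at least 1 bp. This
#' bipartite mapping is the substrate for the merge rules of
#' [reconcile_gene_models()].
#'
#' @param abinitio,homology Exon-level gene-model tibbles.
#' @return Tibble with one row per overlapping pair: `homology_id`,
#'   `abinitio_id`, sorted by homology id then ab initio start.
#' @export
locus_overlap_graph <- function(abinitio, homology) {
  abinitio <- validate_models(abinitio, "abinitio")
  homology <- validate_models(homology, "homology")
  if (length(intersect(unique(abinitio$gene_id),
                       unique(homology$gene_id))) > 0) {
    gs_abort("Gene ids must not be duplicated across the two model sets.",
             "duplicate_ids")
  }
  a <- gene_spans(abinitio)
  h <- gene_spans(homology)
  if (nrow(a) == 0 || nrow(h) == 0) {
    return(tibble(homology_id = character(), abinitio_id = character()))
  }
  a_gr <- GenomicRanges::GRanges(a$contig, IRanges::IRanges(a$start, a$end),
                                 strand = a$strand)
  h_gr <- GenomicRanges::GRanges(h$contig, IRanges::IRanges(h$start, h$end),
                                 strand = h$strand)
  # the two model sets may legitimately live on disjoint contig sets
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(h_gr, a_gr, ignore.strand = FALSE))
  tibble(homology_id = h$gene_id[S4Vectors::queryHits(ov)],
         abinitio_id = a$gene_id[S4Vectors::subjectHits(ov)],
         abinitio_start = a$start[S4Vectors::subjectHits(ov)]) %>%
    arrange(.data$homology_id, .data$abinitio_start) %>%
    select("homology_id", "abinitio_id")
}

#' Reconcile ab initio and homology-based gene models
#'
#' Merges two gene-model sets with priority given to the ab initio
#' predictions. For each homology model H, in order along the genome:
#' \itemize{
#'   \item rule "a": if two or more mutually non-overlapping ab initio
#'     models overlap H (H spans what the ab initio predictor split into
#'     fragments), H is emitted and those ab initio models are consumed;
#'   \item rule "b": if exactly one ab initio model A shares the locus,
#'     H is emitted only when its completeness exceeds A's by more than
#'     `min_completeness_gain`, otherwise A is kept;
#'   \item rule "c": a homology model overlapping no ab initio model is
#'     added as-is.
#' }
#' Ab initio models never consumed by these rules are emitted unchanged.
#' Loci where several mutually overlapping ab initio models hit one H are
#' resolved in favour of the ab initio models (H dropped), consistent with
#' ab initio priority.
#'
#' @param abinitio,homology Exon-level gene-model tibbles.
#' @param min_completeness_gain Completeness advantage (absolute fraction)
#'   a homology model needs to displace a 1:1 ab initio model
#'   (default 0.05).
#' @return List with `models` (exon tibble of the merged set) and
#'   `provenance` (tibble: `gene_id`, `source`, `action` in
#'   emitted/consumed/replaced, `rule`, `partner`).
#' @export
reconcile_gene_models <- function(abinitio, homology,
                                  min_completeness_gain = 0.05) {
  abinitio <- validate_models(abinitio, "abinitio")
  homology <- validate_models(homology, "homology")
  graph <- locus_overlap_graph(abinitio, homology)
  a_spans <- gene_spans(abinitio)
  h_spans <- gene_spans(homology) %>%
    arrange(.data$contig, .data$start, .data$gene_id)
  consumed <- character(0)   # ab initio ids used up by rules a/b
  log <- list()
  emit_h <- character(0)
  for (i in seq_len(nrow(h_spans))) {
    hid <- h_spans$gene_id[i]
    partners <- setdiff(graph$abinitio_id[graph$homology_id == hid], consumed)
    ps <- a_spans[match(partners, a_spans$gene_id), , drop = FALSE]
    has_disjoint_pair <- FALSE
    if (nrow(ps) >= 2) {
      for (p in seq_len(nrow(ps) - 1)) {
        for (q in seq((p + 1), nrow(ps))) {
          if (!spans_overlap(ps$start[p], ps$end[p], ps$start[q], ps$end[q])) {
            has_disjoint_pair <- TRUE
          }
        }
      }
    }
    if (nrow(ps) >= 2 && has_disjoint_pair) {
      emit_h <- c(emit_h, hid)
      consumed <- c(consumed, partners)
      log[[length(log) + 1]] <- tibble(
        gene_id = c(hid, partners), source = c("homology",
                                               rep("abinitio", length(partners))),
        action = c("emitted", rep("consumed", length(partners))),
        rule = "a", partner = c(NA_character_, rep(hid, length(partners))))
    } else if (nrow(ps) == 1) {
      aid <- ps$gene_id[1]
      ch <- h_spans$completeness[i]
      ca <- ps$completeness[1]
      if (is.na(ch) || is.na(ca)) {
        gs_abort(paste0("Completeness missing for 1:1 pair ", hid, " / ", aid),
                 "missing_completeness")
      }
      if (ch - ca > min_completeness_gain) {
        emit_h <- c(emit_h, hid)
        consumed <- c(consumed, aid)
        log[[length(log) + 1]] <- tibble(
          gene_id = c(hid, aid), source = c("homology", "abinitio"),
          action = c("emitted", "replaced"), rule = "b",
          partner = c(aid, hid))
      } else {
        log[[length(log) + 1]] <- tibble(
          gene_id = hid, source = "homology", action = "replaced",
          rule = "b", partner = aid)
      }
    } else if (nrow(ps) == 0) {
      emit_h <- c(emit_h, hid)
      log[[length(log) + 1]] <- tibble(
        gene_id = hid, source = "homology", action = "emitted",
        rule = "c", partner = NA_character_)
    } else {
      # >=2 partners, all mutually overlapping: ab initio priority, H dropped
      log[[length(log) + 1]] <- tibble(
        gene_id = hid, source = "homology", action = "consumed",
        rule = "ambiguous", partner = paste(partners, collapse = ","))
    }
  }
  kept_a <- setdiff(a_spans$gene_id, consumed)
  logged <- if (length(log) > 0) bind_rows(log) else
    tibble(gene_id = character(), source = character(), action = character(),
           rule = character(), partner = character())
  untouched <- setdiff(kept_a, logged$gene_id)
  if (length(untouched) > 0) {
    logged <- bind_rows(logged, tibble(
      gene_id = untouched, source = "abinitio", action = "emitted",
      rule = "untouched", partner = NA_character_))
  }
  models <- bind_rows(
    abinitio %>% filter(.data$gene_id %in% kept_a),
    homology %>% filter(.data$gene_id %in% emit_h)
  ) %>% arrange(.data$contig, .data$start, .data$gene_id)
  list(models = models, provenance = logged %>% arrange(.data$gene_id))
}

#' Completeness of a predicted protein against a reference homolog
#'
#' Globally aligns the model protein to its closest reference homolog and
#' reports the fraction of reference positions covered by (aligned to)
#' query residues.
#'
#' @param model_protein,reference_homolog Amino-acid strings.
#' @return Completeness fraction in \[0, 1\].
#' @export
compute_completeness <- function(model_protein, reference_homolog) {
  if (nchar(model_protein) == 0 || nchar(reference_homolog) == 0) {
    gs_abort("Sequences must be non-empty.", "empty_sequence")
  }
  rows <- align_pair(toupper(model_protein), toupper(reference_homolog),
                     alphabet = "protein")
  ca <- strsplit(rows$a, "")[[1]]
  cb <- strsplit(rows$b, "")[[1]]
  covered <- sum(ca != "-" & cb != "-")
  covered / nchar(reference_homolog)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_vector <- function(cds) {
  codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  codons <- codons[!codons %in% STOP_CODONS]
  all_codons <- setdiff(
    apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                      c("T", "C", "A", "G")), 1, paste, collapse = ""),
    STOP_CODONS)
  counts <- table(factor(codons, levels = all_codons))
  as.numeric(counts) / max(sum(counts), 1)
}

#' Filter gene models by coding-sequence sanity and repeat content
#'
#' Discards models with (i) an in-frame internal stop codon, (ii) codon
#' usage atypical relative to the genome-wide codon-frequency vector
#' (Pearson correlation below `atypicality_cutoff`), or (iii) at least
#' `max_repeat_overlap` of their CDS covered by repeat-library hits. CDS
#' whose length is not divisible by 3 are discarded as malformed.
#'
#' @param models Exon-level gene-model tibble.
#' @param cds Data frame with columns `gene_id`, `cds` (ACGT strings).
#' @param repeat_overlap Optional data frame (`gene_id`,
#'   `overlap_fraction`); genes absent from it are taken as repeat-free.
#' @param atypicality_cutoff Minimum Pearson correlation with the global
#'   codon-frequency vector (default 0.5).
#' @param max_repeat_overlap CDS repeat-overlap fraction at or above which
#'   a model is discarded (default 0.5).
#' @return List with `kept` (exon tibble) and `discarded` (tibble:
#'   `gene_id`, `reason`).
#' @export
filter_gene_models <- function(models, cds, repeat_overlap = NULL,
                               atypicality_cutoff = 0.5,
                               max_repeat_overlap = 0.5) {
  models <- as_tibble(models)
  cds <- as_tibble(cds)
  ids <- unique(models$gene_id)
  if (!all(ids %in% cds$gene_id)) {
    gs_abort("Every gene model needs a CDS entry.", "bad_input")
  }
  cds <- cds[match(ids, cds$gene_id), ]
  cds$cds <- toupper(cds$cds)
  rep_frac <- setNames(rep(0, length(ids)), ids)
  if (!is.null(repeat_overlap)) {
    ro <- as_tibble(repeat_overlap)
    rep_frac[ro$gene_id[ro$gene_id %in% ids]] <-
      ro$overlap_fraction[ro$gene_id %in% ids]
  }
  malformed <- nchar(cds$cds) %% 3 != 0
  has_stop <- map_lgl(seq_along(ids), function(i) {
    if (malformed[i]) return(FALSE)
    s <- cds$cds[i]
    codons <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
    any(codons[-length(codons)] %in% STOP_CODONS)
  })
  # genome-wide codon usage from all well-formed, stop-free models
  usable <- !malformed & !has_stop
  global_vec <- codon_vector(paste(cds$cds[usable], collapse = ""))
  atypical <- map_lgl(seq_along(ids), function(i) {
    if (!usable[i]) return(FALSE)
    r <- suppressWarnings(cor(codon_vector(cds$cds[i]), global_vec))
    !is.na(r) && r < atypicality_cutoff
  })
  repeat_hit <- rep_frac[ids] >= max_repeat_overlap
  reason <- dplyr::case_when(
    malformed ~ "malformed_cds",
    has_stop ~ "in_frame_stop",
    atypical ~ "atypical_codon_usage",
    repeat_hit ~ "repeat_overlap",
    TRUE ~ NA_character_
  )
  discarded <- tibble(gene_id = ids, reason = reason) %>%
    filter(!is.na(.data$reason))
  list(kept = models %>% filter(!.data$gene_id %in% discarded$gene_id),
       discarded = discarded)
}

#' Gene-family fold change between two species
#'
#' Integer (floored) ratio of family sizes, the statistic used to rank the
#' most expanded gene families between a focal and a reference species.
#'
#' @param families Orthogroup count tibble (`family_id` plus per-species
#'   count columns).
#' @param species_a,species_b Column names; fold = floor(count_a / count_b).
#' @return Tibble `family_id`, `count_a`, `count_b`, `fold`, sorted by
#'   fold descending.
#' @export
family_fold_change <- function(families, species_a, species_b) {
  families <- as_tibble(families)
  if (!all(c(species_a, species_b) %in% names(families))) {
    gs_abort("Both species must be columns of `families`.", "bad_input")
  }
  ca <- families[[species_a]]
  cb <- families[[species_b]]
  if (any(cb == 0)) {
    gs_abort("Fold change undefined where the reference count is 0.",
             "undefined_fold")
  }
  tibble(family_id = families$family_id, count_a = ca, count_b = cb,
         fold = floor(ca / cb)) %>%
    arrange(desc(.data$fold), .data$family_id)
}

#' Partition gene families into lineage gains, losses and shared sets
#'
#' Venn-style partition of orthogroup presence across named clades. A
#' family is a focal-lineage gain when present only in the focal clade; a
#' loss when absent from the focal clade but present in at least two of the
#' other named groups (so the family predates the split); shared when
#' present in the focal clade and at least one other group.
#'
#' @param families Orthogroup count tibble (`family_id` + species columns).
#' @param partition Named list of disjoint, non-empty character vectors of
#'   species column names; the focal clade is named by `focal`.
#' @param focal Name of the focal element of `partition` (default the
#'   first).
#' @return List with `summary` (tibble `category`, `n` over gain / loss /
#'   shared / other) and `families` (`family_id`, `category`; families with
#'   no presence in any partition species are excluded).
#' @export
partition_families <- function(families, partition,
                               focal = names(partition)[1]) {
  families <- as_tibble(families)
  if (is.null(names(partition)) || any(names(partition) == "")) {
    gs_abort("`partition` must be a named list.", "bad_input")
  }
  sp <- unlist(partition)
  if (anyDuplicated(sp)) {
    gs_abort("Partition clades must be disjoint.", "bad_input")
  }
  if (any(lengths(partition) == 0)) {
    gs_abort("Partition clades must be non-empty.", "bad_input")
  }
  if (!all(sp %in% names(families))) {
    gs_abort("Every partition species must be a column of `families`.",
             "species_mismatch")
  }
  present <- map(partition, function(cols) {
    rowSums(as.matrix(families[, cols, drop = FALSE]) > 0) > 0
  })
  focal_present <- present[[focal]]
  others <- present[setdiff(names(partition), focal)]
  n_other_present <- Reduce(`+`, map(others, as.integer))
  any_present <- focal_present | n_other_present > 0
  category <- dplyr::case_when(
    focal_present & n_other_present == 0 ~ "gain",
    focal_present & n_other_present >= 1 ~ "shared",
    !focal_present & n_other_present >= 2 ~ "loss",
    !focal_present & n_other_present == 1 ~ "other",
    TRUE ~ NA_character_
  )
  fam <- tibble(family_id = families$family_id, category = category) %>%
    filter(!is.na(.data$category))
  summary <- fam %>%
    count(.data$category, name = "n") %>%
    tidyr::complete(category = c("gain", "loss", "shared", "other"),
                    fill = list(n = 0L)) %>%
    arrange(match(.data$category, c("gain", "loss", "shared", "other")))
  list(summary = summary, families = fam)
}
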