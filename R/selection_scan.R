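# Pairwise dN (Ka) computation over single-copy ortholog pairs with the
# Nei-Gojobori (1986) counting method, top-fraction fast-evolving ranking,
# Fisher exact term enrichment, and the fast-evolving x DE intersection.

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE  # codon -> amino acid, "*" stop

translate_cds <- function(cds) {
  cds <- toupper(cds)
  codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  paste(GENETIC_CODE_TABLE[codons], collapse = "")
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Replaces each amino-acid column of a two-row protein alignment by its
#' source codon (protein gaps become `---`), guided by the unaligned CDS of
#' each row. Each CDS must translate exactly to its ungapped protein row
#' (standard genetic code; a terminal stop codon is tolerated).
#'
#' @param protein_aln Two-row alignment tibble (`id`, `seq`, gapped amino
#'   acids).
#' @param cds Data frame (`id`, `cds`) with the nucleotide CDS of both
#'   rows.
#' @return Codon alignment tibble (`id`, `seq`), width 3x the protein
#'   alignment width.
#' @export
backtranslate_alignment <- function(protein_aln, cds) {
  protein_aln <- as_tibble(protein_aln)
  cds <- as_tibble(cds)
  if (nrow(protein_aln) != 2) {
    gs_abort("Expected a two-row protein alignment.", "bad_input")
  }
  rows <- map_chr(seq_len(2), function(i) {
    id <- protein_aln$id[i]
    prot_gapped <- toupper(protein_aln$seq[i])
    this_cds <- toupper(cds$cds[match(id, cds$id)])
    if (is.na(this_cds)) gs_abort(paste0("No CDS for ", id), "bad_input")
    if (nchar(this_cds) %% 3 != 0) {
      gs_abort(paste0("CDS length of ", id, " is not divisible by 3."),
               "bad_cds")
    }
    prot <- gsub("[-.]", "", prot_gapped)
    trans <- translate_cds(this_cds)
    if (endsWith(trans, "*")) trans <- substr(trans, 1, nchar(trans) - 1)
    if (nchar(trans) != nchar(prot)) {
      gs_abort(paste0("CDS of ", id, " translates to ", nchar(trans),
                      " aa but the protein row has ", nchar(prot), "."),
               "translation_mismatch")
    }
    mism <- which(strsplit(trans, "")[[1]] != strsplit(prot, "")[[1]])
    if (length(mism) > 0) {
      gs_abort(paste0("CDS of ", id, " disagrees with its protein row at ",
                      "position ", mism[1], "."), "translation_mismatch")
    }
    codons <- substring(this_cds,
                        seq(1, by = 3, length.out = nchar(prot)),
                        seq(3, by = 3, length.out = nchar(prot)))
    out <- character(nchar(prot_gapped))
    is_gap <- strsplit(prot_gapped, "")[[1]] %in% c("-", ".")
    out[is_gap] <- "---"
    out[!is_gap] <- codons
    paste(out, collapse = "")
  })
  tibble(id = protein_aln$id, seq = rows)
}

split_codons <- function(s) {
  substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
}

#' Remove codon columns containing gaps
#'
#' Drops every codon column in which either row carries a gap, leaving a
#' gap-free codon alignment. Gaps must occupy whole-codon units (as
#' produced by [backtranslate_alignment()]); partial-codon gaps raise an
#' error rather than being repaired.
#'
#' @param codon_aln Two-row codon alignment tibble (`id`, `seq`).
#' @return Gap-free codon alignment tibble.
#' @export
strip_gap_codons <- function(codon_aln) {
  codon_aln <- as_tibble(codon_aln)
  if (any(nchar(codon_aln$seq) %% 3 != 0)) {
    gs_abort("Codon alignment length must be divisible by 3.", "bad_input")
  }
  rows <- map(codon_aln$seq, split_codons)
  ok <- map(rows, function(cod) {
    has_gap <- grepl("[-.]", cod)
    whole <- cod %in% c("---", "...")
    if (any(has_gap & !whole)) {
      gs_abort("Gap does not occupy a whole codon.", "partial_codon_gap")
    }
    has_gap
  })
  drop <- Reduce(`|`, ok)
  tibble(id = codon_aln$id,
         seq = map_chr(rows, ~ paste(.x[!drop], collapse = "")))
}

# --- NG86 machinery --------------------------------------------------------

NT <- c("A", "C", "G", "T")

# Synonymous site count of one codon: per position, the fraction of the
# three possible single-nucleotide changes that preserve the amino acid.
# Changes creating a stop codon count as non-synonymous.
ng86_sites <- function(codon) {
  aa <- GENETIC_CODE_TABLE[codon]
  s <- 0
  chars <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    for (alt in setdiff(NT, chars[pos])) {
      mutant <- chars
      mutant[pos] <- alt
      if (GENETIC_CODE_TABLE[paste(mutant, collapse = "")] == aa) {
        s <- s + 1 / 3
      }
    }
  }
  c(S = s, N = 3 - s)
}

# Pathway-averaged synonymous/non-synonymous difference counts between two
# codons. Pathways through stop codons are excluded (all pathways are used
# if every one is blocked).
ng86_diffs <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  if (length(pos) == 0) return(c(Sd = 0, Nd = 0))
  paths <- combinat_perms(pos)
  tallies <- list()
  for (p in seq_len(nrow(paths))) {
    cur <- a
    sd <- 0; nd <- 0; blocked <- FALSE
    for (step in paths[p, ]) {
      nxt <- cur
      nxt[step] <- b[step]
      aa1 <- GENETIC_CODE_TABLE[paste(cur, collapse = "")]
      aa2 <- GENETIC_CODE_TABLE[paste(nxt, collapse = "")]
      if (aa2 == "*") blocked <- TRUE
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    tallies[[p]] <- c(sd = sd, nd = nd, blocked = blocked)
  }
  tl <- do.call(rbind, tallies)
  use <- tl[, "blocked"] == 0
  if (!any(use)) use <- rep(TRUE, nrow(tl))
  c(Sd = mean(tl[use, "sd"]), Nd = mean(tl[use, "nd"]))
}

combinat_perms <- function(x) {
  if (length(x) == 1) return(matrix(x, 1, 1))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- combinat_perms(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

jc_correct <- function(p) {
  if (p >= 3 / 4) return(NA_real_)
  -(3 / 4) * log(1 - (4 / 3) * p)
}

#' Nei-Gojobori (1986) dN and dS for one codon alignment
#'
#' Counting estimator of the non-synonymous (Ka, dN) and synonymous
#' (Ks, dS) substitution rates: per-codon synonymous/non-synonymous site
#' counts averaged over the two sequences, pathway-averaged substitution
#' counting for multi-hit codons (pathways through stop codons excluded),
#' and a Jukes-Cantor multiple-hit correction per class. Ks (or Ka) is
#' flagged undefined when the corresponding proportion reaches 3/4, where
#' the correction diverges.
#'
#' @param aln Gap-free two-row codon alignment tibble (`id`, `seq`).
#' @return One-row tibble: `ka`, `ks`, `ka_ks`, `syn_sites`,
#'   `nonsyn_sites`, `syn_diffs`, `nonsyn_diffs`, `n_codons`,
#'   `ka_defined`, `ks_defined`.
#' @export
ng86_dnds <- function(aln) {
  aln <- as_tibble(aln)
  if (nrow(aln) != 2) gs_abort("Expected two sequences.", "bad_input")
  s1 <- toupper(aln$seq[1]); s2 <- toupper(aln$seq[2])
  if (nchar(s1) != nchar(s2) || nchar(s1) %% 3 != 0 || nchar(s1) == 0) {
    gs_abort("Sequences must be equal length, non-empty, divisible by 3.",
             "bad_input")
  }
  if (grepl("[^ACGT]", s1) || grepl("[^ACGT]", s2)) {
    gs_abort("Codon alignment must be gap-free ACGT.", "bad_input")
  }
  cod1 <- split_codons(s1); cod2 <- split_codons(s2)
  if (any(GENETIC_CODE_TABLE[cod1] == "*") ||
      any(GENETIC_CODE_TABLE[cod2] == "*")) {
    gs_abort("Internal stop codon in codon alignment.", "internal_stop")
  }
  sites1 <- vapply(cod1, ng86_sites, numeric(2))
  sites2 <- vapply(cod2, ng86_sites, numeric(2))
  S <- (sum(sites1["S", ]) + sum(sites2["S", ])) / 2
  N <- (sum(sites1["N", ]) + sum(sites2["N", ])) / 2
  diffs <- vapply(seq_along(cod1),
                  function(i) ng86_diffs(cod1[i], cod2[i]), numeric(2))
  Sd <- sum(diffs["Sd", ]); Nd <- sum(diffs["Nd", ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  ks <- jc_correct(ps)
  ka <- jc_correct(pn)
  tibble(ka = ka, ks = ks,
         ka_ks = if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else
           NA_real_,
         syn_sites = S, nonsyn_sites = N,
         syn_diffs = Sd, nonsyn_diffs = Nd,
         n_codons = length(cod1),
         ka_defined = !is.na(ka), ks_defined = !is.na(ks))
}

#' Compute dN/dS for a table of ortholog pairs
#'
#' Convenience wrapper: aligns each protein pair globally, back-translates
#' with the CDS, strips gapped codon columns, and applies [ng86_dnds()].
#'
#' @param pairs Data frame with columns `pair_id`, `id_a`, `id_b`.
#' @param proteins Data frame (`id`, `seq`) of amino-acid sequences.
#' @param cds Data frame (`id`, `cds`) of nucleotide CDS.
#' @return Tibble with one row per pair: `pair_id` plus the [ng86_dnds()]
#'   columns.
#' @export
pairwise_dnds <- function(pairs, proteins, cds) {
  pairs <- as_tibble(pairs)
  proteins <- as_tibble(proteins)
  out <- map(seq_len(nrow(pairs)), function(i) {
    ida <- pairs$id_a[i]; idb <- pairs$id_b[i]
    pa <- proteins$seq[match(ida, proteins$id)]
    pb <- proteins$seq[match(idb, proteins$id)]
    rows <- align_pair(toupper(pa), toupper(pb), alphabet = "protein")
    paln <- tibble(id = c(ida, idb), seq = c(rows$a, rows$b))
    codon <- backtranslate_alignment(paln, cds)
    codon <- strip_gap_codons(codon)
    res <- ng86_dnds(codon)
    res$pair_id <- pairs$pair_id[i]
    res
  })
  bind_rows(out) %>% select("pair_id", dplyr::everything())
}

round_half_up <- function(x) floor(x + 0.5)

#' Select the fastest-evolving fraction of ortholog pairs by dN
#'
#' Ranks pairs by Ka (dN) descending and returns the top
#' `round(fraction * n)` (round half up; ties at the cutoff broken by pair
#' id ascending). Pairs with undefined Ka are excluded from ranking and
#' counted.
#'
#' @param results Data frame with columns `pair_id` and `ka` (NA allowed).
#' @param fraction Fraction of pairs to keep (default 0.10).
#' @return List with `test_set` (tibble `pair_id`, `ka`, Ka descending),
#'   `size`, `n_ranked`, `n_excluded_undefined`.
#' @export
rank_fast_evolving <- function(results, fraction = 0.10) {
  results <- as_tibble(results)
  if (nrow(results) == 0) gs_abort("No dN results supplied.", "empty_input")
  if (fraction <= 0 || fraction >= 1) {
    gs_abort("`fraction` must be in (0, 1).", "bad_input")
  }
  defined <- results %>% filter(!is.na(.data$ka))
  n <- nrow(defined)
  if (n == 0) gs_abort("No pair has a defined Ka.", "empty_input")
  size <- round_half_up(fraction * n)
  ranked <- defined %>% arrange(desc(.data$ka), .data$pair_id)
  list(test_set = ranked[seq_len(size), c("pair_id", "ka")],
       size = size, n_ranked = n,
       n_excluded_undefined = nrow(results) - n)
}

#' Fisher exact over-representation test of annotation terms
#'
#' One-sided hypergeometric (Fisher exact) test of each term's
#' over-representation in a test gene set against a disjoint reference
#' set, with no multiple-testing correction (single-test p-values), the
#' convention of classic GO enrichment of a fast-evolving gene set against
#' the remaining orthologs.
#'
#' @param test_annotations Data frame (`gene_id`, `term`) for the test
#'   set.
#' @param reference_annotations Data frame (`gene_id`, `term`) for the
#'   reference set (disjoint gene ids).
#' @param alpha Significance level on the raw p-value (default 0.05).
#' @param alternative `"greater"` (over-representation, default) or
#'   `"two.sided"`.
#' @return Tibble: `term`, `k` (test genes with term), `K` (test size),
#'   `n` (reference genes with term), `N` (reference size), `p_value`,
#'   `significant`.
#' @export
fisher_enrichment <- function(test_annotations, reference_annotations,
                              alpha = 0.05,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  test_annotations <- distinct(as_tibble(test_annotations))
  reference_annotations <- distinct(as_tibble(reference_annotations))
  K <- dplyr::n_distinct(test_annotations$gene_id)
  N <- dplyr::n_distinct(reference_annotations$gene_id)
  terms <- union(test_annotations$term, reference_annotations$term)
  res <- map(terms, function(tm) {
    k <- sum(test_annotations$term == tm)
    n <- sum(reference_annotations$term == tm)
    if (k + n == 0) {
      gs_warn(paste0("Term ", tm, " absent from both sets; skipped."),
              "empty_term")
      return(NULL)
    }
    p <- if (alternative == "greater") {
      phyper(k - 1, m = k + n, n = (K + N) - (k + n), k = K,
             lower.tail = FALSE)
    } else {
      stats::fisher.test(matrix(c(k, K - k, n, N - n), 2),
                         alternative = "two.sided")$p.value
    }
    tibble(term = tm, k = k, K = K, n = n, N = N, p_value = p,
           significant = p < alpha)
  })
  bind_rows(res) %>% arrange(.data$p_value)
}

#' Intersect the fast-evolving set with DE gene sets
#'
#' Counts, per contrast, how many fast-evolving genes are up- and
#' down-regulated, plus the union across contrasts.
#'
#' @param fast_set Character vector of fast-evolving gene ids.
#' @param de_sets Data frame with columns `contrast`, `gene_id`,
#'   `direction` (`"up"` or `"down"`).
#' @return List with `per_contrast` (tibble `contrast`, `n_up`, `n_down`,
#'   `n_total`) and `union_n` (distinct fast-evolving DE genes across all
#'   contrasts).
#' @export
intersect_fast_de <- function(fast_set, de_sets) {
  de_sets <- as_tibble(de_sets)
  inter <- de_sets %>% filter(.data$gene_id %in% fast_set)
  per_contrast <- de_sets %>%
    distinct(.data$contrast) %>%
    left_join(
      inter %>%
        group_by(.data$contrast) %>%
        summarise(n_up = sum(.data$direction == "up"),
                  n_down = sum(.data$direction == "down"),
                  .groups = "drop"),
      by = "contrast") %>%
    mutate(n_up = tidyr::replace_na(.data$n_up, 0L),
           n_down = tidyr::replace_na(.data$n_down, 0L),
           n_total = .data$n_up + .data$n_down)
  list(per_contrast = per_contrast,
       union_n = dplyr::n_distinct(inter$gene_id))
}
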