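# Synthetic-data generators with planted ground truth: a small diploid-like
# genome with structured genes, perturbed ab initio / homology model sets,
# repeat placements, a planted intronless bacterial gene cluster with
# metazoan flanks, taxonomy-annotated homology hit tables, heterozygous SNP
# tables, and negative-binomial expression with planted DE genes and
# module hubs.
#
# One integer seed drives a named pseudo-random stream per generator, so
# adding a generator never perturbs the others.

STREAM_OFFSETS <- c(genome = 101L, hits = 211L, snps = 307L,
                    expression = 401L)

gs_seed <- function(seed, stream) {
  set.seed((as.integer(seed) %% 2000000L) * 1000L + STREAM_OFFSETS[[stream]])
}

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))
AA20 <- setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*")

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

random_cds <- function(n_codons) {
  paste(c("ATG", sample(SENSE_CODONS, n_codons - 1, replace = TRUE)),
        collapse = "")
}

mutate_protein <- function(seq, frac) {
  chars <- strsplit(seq, "")[[1]]
  k <- round(frac * length(chars))
  if (k > 0) {
    pos <- sample(length(chars), k)
    chars[pos] <- map_chr(chars[pos],
                          function(a) sample(setdiff(AA20, a), 1))
  }
  paste(chars, collapse = "")
}

#' Build a synthetic-genome specification
#'
#' Bundles every tunable parameter of the generators with defaults chosen
#' to emulate the study conditions at desk scale: a multi-contig
#' gene-bearing genome, a planted intronless 4-gene bacterial cluster
#' spanning roughly 4-14 kbp with metazoan flanking genes, heterozygous
#' SNPs with allele frequency centred on 0.5, repeat copies split between
#' introns and intergenic DNA, and a 21-library (3 treatments x 2
#' timepoints x 3 replicates, plus 3 time-zero controls)
#' negative-binomial expression design with planted DE genes and one
#' planted hub per co-expression module.
#'
#' @param seed Integer seed (mandatory); drives one named random stream
#'   per generator.
#' @param n_contigs,contig_length,genes_per_contig Genome dimensions.
#' @param exon_count_range,exon_length_range,intron_length_range,
#'   intergenic_gap_range Gene-structure parameters (bp).
#' @param hgt List: `n_genes` (default 4), `codon_range` (codons per
#'   cluster gene), `gap_range` (bp between cluster genes), `contig`
#'   (host contig index). Set `n_genes = 0` to plant no transfer.
#' @param repeats List: `n_families`, `length_range` (bp),
#'   `intron_copies`, `intergenic_copies`.
#' @param snps List: `n_snps`, `depth`, `het_freq`, `haploid_fraction`.
#' @param expression List: `n_background`, `n_modules`, `module_size`,
#'   `n_de`, `de_lfc`, `dispersion`, `base_range` (log2 mean counts),
#'   `hub_loading`, `member_loading`, `member_extra_sd`.
#' @param wgd Duplicate every gene's protein verbatim (synthetic
#'   whole-genome duplication) in the returned proteome?
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed,
                           n_contigs = 2,
                           contig_length = 60000,
                           genes_per_contig = 10,
                           exon_count_range = c(1, 5),
                           exon_length_range = c(150, 450),
                           intron_length_range = c(200, 1200),
                           intergenic_gap_range = c(400, 1500),
                           hgt = list(),
                           repeats = list(),
                           snps = list(),
                           expression = list(),
                           wgd = FALSE) {
  if (missing(seed)) gs_abort("`seed` is mandatory.", "bad_input")
  hgt <- utils::modifyList(
    list(n_genes = 4, codon_range = c(300, 380), gap_range = c(150, 300),
         contig = 1), hgt)
  repeats <- utils::modifyList(
    list(n_families = 6, length_range = c(150, 600),
         intron_copies = 100, intergenic_copies = 150), repeats)
  snps <- utils::modifyList(
    list(n_snps = 5000, depth = 30, het_freq = 0.5, haploid_fraction = 0),
    snps)
  expression <- utils::modifyList(
    list(n_background = 100, n_modules = 4, module_size = 25,
         n_de = 20, de_lfc = 3, dispersion = 0.05, base_range = c(5, 9),
         module_base_range = c(8, 10), hub_loading = 2,
         member_loading = 1, member_extra_sd = 0.45),
    expression)
  structure(list(seed = as.integer(seed), n_contigs = n_contigs,
                 contig_length = contig_length,
                 genes_per_contig = genes_per_contig,
                 exon_count_range = exon_count_range,
                 exon_length_range = exon_length_range,
                 intron_length_range = intron_length_range,
                 intergenic_gap_range = intergenic_gap_range,
                 hgt = hgt, repeats = repeats, snps = snps,
                 expression = expression, wgd = wgd),
            class = "synthetic_spec")
}

#' Serialize / restore a synthetic-genome specification
#'
#' @param spec A `synthetic_spec`.
#' @param path JSON file path.
#' @return `path` (write) or the restored spec (read).
#' @export
write_synthetic_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "synthetic_spec")
}

r_int <- function(n, range) {
  if (range[1] >= range[2]) return(rep(range[1], n))
  sample(seq(range[1], range[2]), n, replace = TRUE)
}

# Lay out one gene starting at `cursor`: returns exon table, CDS, end.
plan_gene <- function(gene_id, contig, cursor, n_exons, exon_lens,
                      intron_lens, strand) {
  cds_len <- sum(exon_lens)
  # force CDS length to a codon multiple by padding the last exon
  pad <- (3 - cds_len %% 3) %% 3
  exon_lens[n_exons] <- exon_lens[n_exons] + pad
  starts <- integer(n_exons)
  ends <- integer(n_exons)
  pos <- cursor
  for (e in seq_len(n_exons)) {
    starts[e] <- pos
    ends[e] <- pos + exon_lens[e] - 1
    pos <- ends[e] + 1
    if (e < n_exons) pos <- pos + intron_lens[e]
  }
  list(exons = tibble(gene_id = gene_id, contig = contig, strand = strand,
                      start = starts, end = ends),
       cds_len = sum(exon_lens), end = ends[n_exons])
}

#' Generate a synthetic genome with planted ground truth
#'
#' Builds contig sequences carrying non-overlapping structured genes, a
#' planted intronless bacterial-like gene cluster flanked by host genes,
#' repeat-copy placements with known compartments, and two perturbed
#' gene-model sets (ab initio and homology) whose correct reconciliation
#' is known per locus.
#'
#' The ab initio / homology perturbations cover every merge rule: loci
#' where both predictors produce a full model (ab initio kept), where the
#' ab initio model is truncated (homology wins on completeness), where the
#' completeness gain is below threshold (ab initio kept), where the ab
#' initio predictor split the gene (homology spans the fragments), and
#' loci private to one predictor.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `contigs` (tibble `id`, `seq`), `genes` (true
#'   exon-level models), `cds`, `proteins`, `abinitio`, `homology`
#'   (perturbed model sets), `repeat_families`, `repeat_hits`, and
#'   `truth` (list: `hgt_genes`, `hgt_flanks`, `repeat_placements`,
#'   `reconciliation`, `duplicated_genes`).
#' @export
generate_genome <- function(spec) {
  gs_seed(spec$seed, "genome")
  contig_ids <- paste0("contig", seq_len(spec$n_contigs))
  gene_rows <- list()
  cds_list <- list()
  hgt_ids <- character(0)
  hgt_flanks <- c(NA_character_, NA_character_)
  contig_seqs <- character(spec$n_contigs)

  for (ci in seq_len(spec$n_contigs)) {
    contig <- contig_ids[ci]
    cursor <- sample(200:600, 1)
    n_genes <- spec$genes_per_contig
    plant_hgt <- spec$hgt$n_genes > 0 && ci == spec$hgt$contig
    hgt_after <- if (plant_hgt) max(2, floor(n_genes / 2)) else -1
    gi <- 0
    while (gi < n_genes) {
      gi <- gi + 1
      gid <- sprintf("g%02d_%03d", ci, gi)
      n_exons <- r_int(1, spec$exon_count_range)
      plan <- plan_gene(gid, contig, cursor, n_exons,
                        r_int(n_exons, spec$exon_length_range),
                        r_int(max(n_exons - 1, 1),
                              spec$intron_length_range),
                        sample(c("+", "-"), 1))
      if (plan$end > spec$contig_length - 1000) {
        gs_abort("Gene packing infeasible for the contig length.",
                 "infeasible_packing")
      }
      gene_rows[[length(gene_rows) + 1]] <- plan$exons
      cds_list[[gid]] <- random_cds(plan$cds_len / 3)
      cursor <- plan$end + r_int(1, spec$intergenic_gap_range)
      if (gi == hgt_after) {
        hgt_flanks[1] <- gid
        for (hj in seq_len(spec$hgt$n_genes)) {
          hid <- sprintf("hgt%02d", hj)
          n_codons <- r_int(1, spec$hgt$codon_range)
          plan <- plan_gene(hid, contig, cursor, 1, 3 * n_codons,
                            integer(0), "+")
          gene_rows[[length(gene_rows) + 1]] <- plan$exons
          cds_list[[hid]] <- random_cds(n_codons)
          hgt_ids <- c(hgt_ids, hid)
          cursor <- plan$end +
            (if (hj < spec$hgt$n_genes) r_int(1, spec$hgt$gap_range)
             else r_int(1, spec$intergenic_gap_range))
        }
        hgt_flanks[2] <- sprintf("g%02d_%03d", ci, gi + 1)
      }
    }
    contig_seqs[ci] <- random_dna(spec$contig_length)
  }
  genes <- bind_rows(gene_rows) %>%
    mutate(source = "true", completeness = 1)

  # splice each CDS into its exons on the forward strand of the contig
  # (strand only matters for model bookkeeping, not for the planted CDS)
  for (ci in seq_len(spec$n_contigs)) {
    chars <- strsplit(contig_seqs[ci], "")[[1]]
    cg <- genes %>% filter(.data$contig == contig_ids[ci])
    for (gid in unique(cg$gene_id)) {
      ex <- cg %>% filter(.data$gene_id == gid) %>% arrange(.data$start)
      cds_chars <- strsplit(cds_list[[gid]], "")[[1]]
      off <- 0
      for (e in seq_len(nrow(ex))) {
        w <- ex$end[e] - ex$start[e] + 1
        chars[ex$start[e]:ex$end[e]] <- cds_chars[off + seq_len(w)]
        off <- off + w
      }
    }
    contig_seqs[ci] <- paste(chars, collapse = "")
  }

  cds <- tibble(gene_id = names(cds_list),
                cds = unname(unlist(cds_list)))
  proteins <- tibble(id = cds$gene_id,
                     seq = map_chr(cds$cds, translate_cds))
  duplicated_genes <- character(0)
  if (isTRUE(spec$wgd)) {
    dup <- proteins %>% mutate(id = paste0(.data$id, "_dup"))
    duplicated_genes <- dup$id
    proteins <- bind_rows(proteins, dup)
  }

  # ---- perturbed prediction sets -----------------------------------------
  host_ids <- setdiff(unique(genes$gene_id), hgt_ids)
  scen_pool <- c(rep("both_full", 4), rep("h_better", 2),
                 rep("h_below_gain", 1), rep("split", 2),
                 rep("h_only", 1), rep("a_only", 1))
  scenarios <- sample(rep(scen_pool,
                          length.out = length(host_ids)))
  names(scenarios) <- host_ids
  ab_rows <- list(); ho_rows <- list(); recon <- list()
  for (gid in host_ids) {
    ex <- genes %>% filter(.data$gene_id == gid) %>% arrange(.data$start)
    sc <- scenarios[[gid]]
    aid <- paste0("a_", gid); hid <- paste0("h_", gid)
    add_a <- function(rows, id, comp) {
      mutate(rows, gene_id = id, source = "abinitio", completeness = comp)
    }
    add_h <- function(rows, id, comp) {
      mutate(rows, gene_id = id, source = "homology", completeness = comp)
    }
    if (sc == "both_full") {
      ab_rows[[gid]] <- add_a(ex, aid, 1)
      ho_rows[[gid]] <- add_h(ex, hid, 1)
      winner <- aid
    } else if (sc == "h_better") {
      keep <- seq_len(max(1, ceiling(nrow(ex) * 0.5)))
      ab_rows[[gid]] <- add_a(ex[keep, ], aid, 0.6)
      ho_rows[[gid]] <- add_h(ex, hid, 1)
      winner <- hid
    } else if (sc == "h_below_gain") {
      ab_rows[[gid]] <- add_a(ex, aid, 0.96)
      ho_rows[[gid]] <- add_h(ex, hid, 1)
      winner <- aid
    } else if (sc == "split") {
      if (nrow(ex) >= 2) {
        cut <- ceiling(nrow(ex) / 2)
        ab_rows[[gid]] <- bind_rows(
          add_a(ex[seq_len(cut), ], paste0(aid, ".1"), 0.5),
          add_a(ex[seq(cut + 1, nrow(ex)), ], paste0(aid, ".2"), 0.5))
      } else {
        w <- ex$end[1] - ex$start[1] + 1
        half <- floor(w / 2) - 10
        frag1 <- mutate(ex, end = .data$start + half)
        frag2 <- mutate(ex, start = .data$end - half)
        ab_rows[[gid]] <- bind_rows(add_a(frag1, paste0(aid, ".1"), 0.5),
                                    add_a(frag2, paste0(aid, ".2"), 0.5))
      }
      ho_rows[[gid]] <- add_h(ex, hid, 1)
      winner <- hid
    } else if (sc == "h_only") {
      ho_rows[[gid]] <- add_h(ex, hid, 1)
      winner <- hid
    } else { # a_only
      ab_rows[[gid]] <- add_a(ex, aid, 1)
      winner <- aid
    }
    recon[[gid]] <- tibble(true_gene = gid, scenario = sc,
                           expected_id = winner)
  }
  # HGT genes: ab initio predicts them cleanly (they are real genes)
  for (hid0 in hgt_ids) {
    ex <- genes %>% filter(.data$gene_id == hid0)
    ab_rows[[hid0]] <- mutate(ex, gene_id = paste0("a_", hid0),
                              source = "abinitio", completeness = 1)
    recon[[hid0]] <- tibble(true_gene = hid0, scenario = "a_only",
                            expected_id = paste0("a_", hid0))
  }

  # ---- repeat families and placements ------------------------------------
  rp <- spec$repeats
  fam_len <- r_int(rp$n_families, rp$length_range)
  fams <- tibble(
    family_id = sprintf("repfam%02d", seq_len(rp$n_families)),
    consensus = map_chr(fam_len, random_dna),
    classification = ifelse(seq_len(rp$n_families) %% 2 == 0,
                            "LTR", "unknown"),
    length = fam_len)
  spans <- gene_spans(genes)
  introns <- genes %>%
    group_by(.data$gene_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    summarise(contig = first(.data$contig),
              int_start = list(utils::head(.data$end, -1) + 1),
              int_end = list(utils::tail(.data$start, -1) - 1),
              .groups = "drop") %>%
    tidyr::unnest(c("int_start", "int_end")) %>%
    filter(.data$int_end - .data$int_start >= 50)
  gaps <- spans %>%
    group_by(.data$contig) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    summarise(gap_start = list(utils::head(.data$end, -1) + 1),
              gap_end = list(utils::tail(.data$start, -1) - 1),
              .groups = "drop") %>%
    tidyr::unnest(c("gap_start", "gap_end")) %>%
    filter(.data$gap_end - .data$gap_start >= 100)
  place_in <- function(intervals, n, compartment) {
    if (n == 0 || nrow(intervals) == 0) return(NULL)
    # weight by interval length, so long introns collect more copies
    w <- intervals[[2]] - intervals[[1]] + 1
    pick <- sample(nrow(intervals), n, replace = TRUE, prob = w)
    fam <- sample(nrow(fams), n, replace = TRUE)
    lo <- intervals[[1]][pick]; hi <- intervals[[2]][pick]
    start <- lo + floor(runif(n) * pmax(hi - lo - 20, 1))
    end <- pmin(start + fams$length[fam] - 1, hi)
    tibble(family_id = fams$family_id[fam],
           contig = intervals$contig[pick],
           start = start, end = end, planted_compartment = compartment)
  }
  empty_placements <- tibble(family_id = character(), contig = character(),
                             start = integer(), end = integer(),
                             planted_compartment = character())
  placements <- bind_rows(
    empty_placements,
    place_in(introns %>% select("int_start", "int_end", "contig"),
             rp$intron_copies, "intron"),
    place_in(gaps %>% select("gap_start", "gap_end", "contig"),
             rp$intergenic_copies, "intergenic"))
  repeat_hits <- placements %>%
    select("family_id", "contig", "start", "end")

  list(contigs = tibble(id = contig_ids, seq = contig_seqs),
       genes = genes, cds = cds, proteins = proteins,
       abinitio = bind_rows(ab_rows), homology = bind_rows(ho_rows),
       repeat_families = fams, repeat_hits = repeat_hits,
       truth = list(hgt_genes = hgt_ids, hgt_flanks = hgt_flanks,
                    repeat_placements = placements,
                    reconciliation = bind_rows(recon),
                    duplicated_genes = duplicated_genes))
}

hit_row <- function(query_id, subject_id, qlen, divergence, phylum,
                    is_metazoan, is_coral) {
  tibble(query_id = query_id, subject_id = subject_id,
         identity = round(100 * (1 - divergence), 1),
         align_len = qlen, mismatches = round(qlen * divergence),
         gap_open = 0L, qstart = 1L, qend = qlen, sstart = 1L, send = qlen,
         evalue = 1e-30, bitscore = round(2 * qlen * (1 - divergence), 1),
         phylum = phylum, is_metazoan = is_metazoan, is_coral = is_coral)
}

#' Generate a taxonomy-annotated homology hit table
#'
#' Emulates the output of a protein search against a combined
#' reference + coral database: host genes receive metazoan-topped hit
#' lists (with weaker bacterial hits below), while planted HGT genes
#' receive bacterial-topped lists spread over three phyla — more than the
#' per-phylum representative cap in the leading phylum — with weak
#' metazoan hits below. Subject sequences are mutated copies of the query
#' at the implied divergence so that alignment distances and gene trees
#' reproduce the planted provenance.
#'
#' @param spec A [synthetic_spec()].
#' @param genome Output of [generate_genome()] (uses `proteins` and
#'   `truth$hgt_genes`).
#' @return List with `hits` (hit tibble) and `subject_seqs`
#'   (tibble `id`, `seq`).
#' @export
generate_hits <- function(spec, genome) {
  gs_seed(spec$seed, "hits")
  proteins <- genome$proteins
  hgt_ids <- genome$truth$hgt_genes
  rows <- list(); subj <- list()
  add_subject <- function(query, tag, div) {
    sid <- paste0(query, "_", tag)
    subj[[sid]] <<- mutate_protein(proteins$seq[proteins$id == query], div)
    sid
  }
  for (q in setdiff(proteins$id, genome$truth$duplicated_genes)) {
    qlen <- nchar(proteins$seq[proteins$id == q])
    if (q %in% hgt_ids) {
      plan <- bind_rows(
        tibble(tag = sprintf("bacP%d", 1:8),
               div = seq(0.05, 0.19, length.out = 8),
               phylum = "Proteobacteria", met = FALSE, cor = FALSE),
        tibble(tag = sprintf("bacB%d", 1:3), div = c(0.24, 0.26, 0.28),
               phylum = "Bacteroidetes", met = FALSE, cor = FALSE),
        tibble(tag = sprintf("bacF%d", 1:3), div = c(0.30, 0.32, 0.34),
               phylum = "Firmicutes", met = FALSE, cor = FALSE),
        tibble(tag = sprintf("met%d", 1:2), div = c(0.44, 0.47),
               phylum = "Cnidaria", met = TRUE, cor = TRUE))
    } else {
      plan <- bind_rows(
        tibble(tag = sprintf("cor%d", 1:3), div = c(0.06, 0.10, 0.14),
               phylum = "Cnidaria", met = TRUE, cor = TRUE),
        tibble(tag = sprintf("chor%d", 1:2), div = c(0.20, 0.24),
               phylum = "Chordata", met = TRUE, cor = FALSE),
        tibble(tag = sprintf("bac%d", 1:2), div = c(0.45, 0.48),
               phylum = "Proteobacteria", met = FALSE, cor = FALSE))
    }
    for (i in seq_len(nrow(plan))) {
      sid <- add_subject(q, plan$tag[i], plan$div[i])
      rows[[length(rows) + 1]] <-
        hit_row(q, sid, qlen, plan$div[i], plan$phylum[i],
                plan$met[i], plan$cor[i])
    }
  }
  list(hits = bind_rows(rows),
       subject_seqs = tibble(id = names(subj), seq = unname(unlist(subj))))
}

#' Generate a biallelic SNP table
#'
#' Heterozygous sites draw their alternate-allele count from
#' binomial(depth, `het_freq`); an optional haploid-contamination
#' fraction of sites is drawn at alternate frequency 1 for negative
#' controls.
#'
#' @param spec A [synthetic_spec()].
#' @return Tibble `contig`, `pos`, `ref_count`, `alt_count`.
#' @export
generate_snps <- function(spec) {
  gs_seed(spec$seed, "snps")
  sp <- spec$snps
  n <- sp$n_snps
  if (n == 0) {
    return(tibble(contig = character(), pos = integer(),
                  ref_count = integer(), alt_count = integer()))
  }
  if (sp$depth < 10) gs_abort("`depth` must be >= 10.", "bad_input")
  hap <- runif(n) < sp$haploid_fraction
  alt <- integer(n)
  alt[!hap] <- rbinom(sum(!hap), sp$depth, sp$het_freq)
  alt[hap] <- sp$depth
  # guard: a site with no observed alternate allele is not a SNP
  redraw <- which(alt == 0)
  while (length(redraw) > 0) {
    alt[redraw] <- rbinom(length(redraw), sp$depth, sp$het_freq)
    redraw <- redraw[alt[redraw] == 0]
  }
  tibble(contig = paste0("contig", sample(spec$n_contigs, n, replace = TRUE)),
         pos = sample(spec$contig_length, n, replace = TRUE),
         ref_count = sp$depth - alt, alt_count = alt)
}

#' Generate synthetic expression data with planted DE genes and hubs
#'
#' Simulates the 21-library stress-response design (3 treatments x 2
#' timepoints x 3 replicates plus 3 time-zero ambient controls).
#' Counts are negative binomial around gene-wise log2 means. Module genes
#' load on their module's planted hub gene, which carries the strongest
#' signal, so correlation-threshold graphs recover the hub as the module
#' centre. Planted DE genes are shifted by `de_lfc` log2 units (half up,
#' half down) in the high-temperature samples. Per-gene DE statistics are
#' computed with a simple two-group Welch t-test on log2(count + 1) —
#' fixture machinery standing in for a full negative-binomial model, so
#' the downstream filters are exercisable end to end.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `counts` (matrix, genes x samples), `samples`
#'   (tibble `sample_id`, `treatment`, `time`, `rep`), `de_stats`
#'   (tibble `contrast`, `gene_id`, `log2fc`, `p_raw`, `p_adj`), and
#'   `truth` (list: `de_genes` tibble, `modules` tibble, `hubs`).
#' @export
generate_expression <- function(spec) {
  gs_seed(spec$seed, "expression")
  ex <- spec$expression
  samples <- bind_rows(
    tibble(treatment = "ATAC", time = 0, rep = 1:3),
    tidyr::expand_grid(treatment = c("ATAC", "ATHC", "HTAC"),
                       time = c(1, 6), rep = 1:3)) %>%
    mutate(sample_id = paste0(.data$treatment, "_", .data$time, "_r",
                              .data$rep))
  n_samp <- nrow(samples)
  n_mod_genes <- ex$n_modules * ex$module_size
  n_genes <- ex$n_background + n_mod_genes
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  base <- runif(n_genes, ex$base_range[1], ex$base_range[2])
  log2mu <- matrix(rep(base, n_samp), nrow = n_genes)
  rownames(log2mu) <- gene_ids

  modules <- tibble(gene_id = character(), module = character())
  hubs <- character(0)
  if (ex$n_modules > 0) {
    for (m in seq_len(ex$n_modules)) {
      idx <- ex$n_background + (m - 1) * ex$module_size +
        seq_len(ex$module_size)
      hub_i <- idx[1]
      member_i <- idx[-1]
      # module genes sit at high expression so count noise stays small
      # relative to the shared signal
      base[idx] <- runif(length(idx), ex$module_base_range[1],
                         ex$module_base_range[2])
      log2mu[idx, ] <- matrix(rep(base[idx], n_samp), nrow = length(idx))
      # unit-variance factor: module signal strength does not wobble with
      # the luck of the sample draw
      z <- as.numeric(scale(rnorm(n_samp)))
      log2mu[hub_i, ] <- log2mu[hub_i, ] + ex$hub_loading * z
      for (g in member_i) {
        log2mu[g, ] <- log2mu[g, ] + ex$member_loading * z +
          rnorm(n_samp, sd = ex$member_extra_sd)
      }
      modules <- bind_rows(modules,
                           tibble(gene_id = gene_ids[idx],
                                  module = paste0("M", m)))
      hubs <- c(hubs, gene_ids[hub_i])
    }
  }

  de_truth <- tibble(gene_id = character(), lfc = numeric(),
                     direction = character())
  if (ex$n_de > 0) {
    de_idx <- seq_len(min(ex$n_de, ex$n_background))
    dirs <- rep(c(1, -1), length.out = length(de_idx))
    # planted DE genes sit at quantifiable expression so the shift is
    # detectable in both directions
    base[de_idx] <- runif(length(de_idx), ex$module_base_range[1],
                          ex$module_base_range[2])
    log2mu[de_idx, ] <- matrix(rep(base[de_idx], n_samp),
                               nrow = length(de_idx))
    hot <- samples$treatment == "HTAC"
    for (j in seq_along(de_idx)) {
      log2mu[de_idx[j], hot] <- log2mu[de_idx[j], hot] +
        dirs[j] * ex$de_lfc
    }
    de_truth <- tibble(gene_id = gene_ids[de_idx],
                       lfc = dirs * ex$de_lfc,
                       direction = ifelse(dirs > 0, "up", "down"))
  }

  mu <- 2^log2mu
  counts <- matrix(rnbinom(n_genes * n_samp, mu = mu,
                           size = 1 / ex$dispersion),
                   nrow = n_genes,
                   dimnames = list(gene_ids, samples$sample_id))

  contrasts <- tibble(
    contrast = c("ATHC_1_vs_ATAC_1", "ATHC_6_vs_ATAC_6",
                 "HTAC_1_vs_ATAC_1", "HTAC_6_vs_ATAC_6"),
    trt = c("ATHC", "ATHC", "HTAC", "HTAC"),
    time = c(1, 6, 1, 6))
  de_stats <- map(seq_len(nrow(contrasts)), function(i) {
    g1 <- samples$sample_id[samples$treatment == contrasts$trt[i] &
                              samples$time == contrasts$time[i]]
    g0 <- samples$sample_id[samples$treatment == "ATAC" &
                              samples$time == contrasts$time[i]]
    l1 <- log2(counts[, g1, drop = FALSE] + 1)
    l0 <- log2(counts[, g0, drop = FALSE] + 1)
    lfc <- rowMeans(l1) - rowMeans(l0)
    p <- vapply(seq_len(n_genes), function(g) {
      if (sd(l1[g, ]) == 0 && sd(l0[g, ]) == 0) return(1)
      tryCatch(t.test(l1[g, ], l0[g, ], var.equal = TRUE)$p.value,
               error = function(e) 1)
    }, numeric(1))
    tibble(contrast = contrasts$contrast[i], gene_id = gene_ids,
           log2fc = lfc, p_raw = p, p_adj = bh_adjust(p))
  }) %>% bind_rows()

  list(counts = counts, samples = samples, de_stats = de_stats,
       truth = list(de_genes = de_truth, modules = modules, hubs = hubs))
}
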