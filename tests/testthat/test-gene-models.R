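mk_model <- function(id, contig, strand, exons, source = "abinitio",
                     completeness = 1) {
  tibble::tibble(gene_id = id, contig = contig, strand = strand,
                 start = vapply(exons, `[`, 0, 1),
                 end = vapply(exons, `[`, 0, 2),
                 source = source, completeness = completeness)
}

test_that("locus overlap mapping equals the all-pairs interval oracle", {
  a1 <- mk_model("a1", "c1", "+", list(c(100, 500)))
  a2 <- mk_model("a2", "c1", "+", list(c(900, 1200)))
  h1 <- mk_model("h1", "c1", "+", list(c(50, 1300)), "homology")
  g <- locus_overlap_graph(dplyr::bind_rows(a1, a2), h1)
  expect_equal(g$abinitio_id, c("a1", "a2"))

  h2 <- mk_model("h2", "c2", "+", list(c(50, 1300)), "homology")
  expect_equal(nrow(locus_overlap_graph(a1, h2)), 0)

  expect_error(
    locus_overlap_graph(a1, mk_model("a1", "c1", "+", list(c(1, 2)),
                                     "homology")),
    class = "genomescape_error_duplicate_ids")

  # 200 random models vs O(n^2) brute force
  set.seed(37)
  rand_models <- function(prefix, n, source) {
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      s <- sample.int(20000, 1)
      mk_model(paste0(prefix, i), sample(c("c1", "c2"), 1),
               sample(c("+", "-"), 1), list(c(s, s + sample.int(3000, 1))),
               source)
    }))
  }
  A <- rand_models("A", 100, "abinitio")
  H <- rand_models("H", 100, "homology")
  got <- locus_overlap_graph(A, H)
  brute <- list()
  for (i in seq_len(nrow(H))) for (j in seq_len(nrow(A))) {
    if (H$contig[i] == A$contig[j] && H$strand[i] == A$strand[j] &&
        H$start[i] <= A$end[j] && A$start[j] <= H$end[i]) {
      brute[[length(brute) + 1]] <- c(H$gene_id[i], A$gene_id[j])
    }
  }
  want <- do.call(rbind, brute)
  expect_setequal(paste(got$homology_id, got$abinitio_id),
                  paste(want[, 1], want[, 2]))
})

test_that("merge rules follow ab initio priority with completeness override", {
  # rule a: homology model spanning two disjoint ab initio fragments wins
  a <- dplyr::bind_rows(mk_model("a1", "c1", "+", list(c(100, 400))),
                        mk_model("a2", "c1", "+", list(c(600, 900))))
  h <- mk_model("h1", "c1", "+", list(c(50, 950)), "homology")
  r <- reconcile_gene_models(a, h)
  expect_setequal(unique(r$models$gene_id), "h1")
  expect_equal(r$provenance$rule[r$provenance$gene_id == "h1"], "a")

  # rule b boundary: gain of 0.04 is not enough
  a2 <- mk_model("a1", "c1", "+", list(c(100, 400)), completeness = 0.86)
  h2 <- mk_model("h1", "c1", "+", list(c(90, 410)), "homology",
                 completeness = 0.90)
  r2 <- reconcile_gene_models(a2, h2)
  expect_setequal(unique(r2$models$gene_id), "a1")

  # and a gain of 0.06 is
  h3 <- dplyr::mutate(h2, completeness = 0.92)
  r3 <- reconcile_gene_models(a2, h3)
  expect_setequal(unique(r3$models$gene_id), "h1")

  expect_error(
    reconcile_gene_models(dplyr::mutate(a2, completeness = NA_real_), h2),
    class = "genomescape_error_missing_completeness")
})

test_that("merge equals the literal rule oracle on random locus configurations", {
  for (seed in c(101, 202, 303)) {
    cfg <- random_locus_models(120, seed)
    got <- reconcile_gene_models(cfg$abinitio, cfg$homology)
    want <- oracle_reconcile(cfg$abinitio, cfg$homology)
    expect_equal(sort(unique(got$models$gene_id)), want)

    # conservation: every input model appears exactly once in the log
    all_ids <- c(cfg$abinitio$gene_id, cfg$homology$gene_id)
    expect_setequal(got$provenance$gene_id, all_ids)
    expect_equal(anyDuplicated(got$provenance$gene_id), 0L)

    # invariance to input row order
    got2 <- reconcile_gene_models(
      cfg$abinitio[sample(nrow(cfg$abinitio)), ],
      cfg$homology[sample(nrow(cfg$homology)), ])
    expect_setequal(unique(got2$models$gene_id),
                    unique(got$models$gene_id))
  }
})

test_that("completeness measures reference coverage by the query", {
  set.seed(43)
  ref <- rand_prot(200)
  expect_equal(compute_completeness(ref, ref), 1)
  half <- substr(ref, 1, 100)
  expect_lt(abs(compute_completeness(half, ref) - 0.5), 0.01)
  for (f in seq(0.2, 0.9, 0.1)) {
    trunc <- substr(ref, 1, round(f * 200))
    expect_lt(abs(compute_completeness(trunc, ref) - f), 0.02)
  }
  expect_error(compute_completeness("", ref),
               class = "genomescape_error_empty_sequence")
})

test_that("gene-model filtering discards stops, repeats and atypical codon usage", {
  set.seed(47)
  # 100 genes drawn from one skewed codon-preference profile, 10 planted
  # with a transposon-like inverted preference ordering
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  u <- stats::runif(length(sense))^2
  profile <- u / sum(u)
  typical <- function(n) paste(c("ATG", sample(sense, n, TRUE, profile)),
                               collapse = "")
  biased <- function(n) paste(c("ATG", sample(sense, n, TRUE,
                                              rev(profile))),
                              collapse = "")
  ids <- sprintf("g%03d", 1:100)
  cds <- tibble::tibble(
    gene_id = ids,
    cds = c(vapply(1:90, function(i) typical(400), ""),
            vapply(1:10, function(i) biased(400), "")))
  models <- tibble::tibble(gene_id = ids, contig = "c1", strand = "+",
                           start = seq(1, by = 2000, length.out = 100),
                           end = seq(1203, by = 2000, length.out = 100),
                           source = "abinitio", completeness = 1)
  out <- filter_gene_models(models, cds)
  expect_setequal(out$discarded$gene_id, ids[91:100])
  expect_true(all(out$discarded$reason == "atypical_codon_usage"))

  # in-frame stop
  cds2 <- dplyr::bind_rows(cds[1:20, ],
                           tibble::tibble(gene_id = "stopgene",
                                          cds = "ATGTAAGGGCCC"))
  models2 <- dplyr::bind_rows(
    models[1:20, ],
    tibble::tibble(gene_id = "stopgene", contig = "c1", strand = "+",
                   start = 200000, end = 200011, source = "abinitio",
                   completeness = 1))
  out2 <- filter_gene_models(models2, cds2)
  expect_true("stopgene" %in% out2$discarded$gene_id)
  expect_equal(out2$discarded$reason[out2$discarded$gene_id == "stopgene"],
               "in_frame_stop")

  # repeat overlap
  out3 <- filter_gene_models(
    models[1:20, ], cds[1:20, ],
    repeat_overlap = tibble::tibble(gene_id = c("g001", "g002"),
                                    overlap_fraction = c(0.8, 0.3)))
  expect_equal(out3$discarded$gene_id, "g001")
})

test_that("family fold change reproduces the published expansion arithmetic", {
  fams <- tibble::tibble(family_id = c("OG0000159", "OG0000016",
                                       "OG0000127", "OGx"),
                         mcap = c(110, 286, 102, 5),
                         adig = c(2, 6, 2, 5))
  fc <- family_fold_change(fams, "mcap", "adig")
  expect_equal(fc$fold[fc$family_id == "OG0000159"], 55)
  expect_equal(fc$fold[fc$family_id == "OG0000016"], 47)  # floor of 47.67
  expect_equal(fc$fold[fc$family_id == "OG0000127"], 51)
  expect_equal(fc$fold[fc$family_id == "OGx"], 1)
  expect_error(family_fold_change(
    tibble::tibble(family_id = "f", a = 1, b = 0), "a", "b"),
    class = "genomescape_error_undefined_fold")
  # fold >= 1 iff count_a >= count_b
  set.seed(53)
  fams2 <- tibble::tibble(family_id = sprintf("f%02d", 1:50),
                          a = sample.int(20, 50, TRUE),
                          b = sample.int(20, 50, TRUE))
  fc2 <- family_fold_change(fams2, "a", "b")
  expect_equal(fc2$fold >= 1, fc2$count_a >= fc2$count_b)
})

test_that("family partition reproduces manual Venn enumeration", {
  partition <- list(focal = c("mc1", "mc2"), acro = c("ad1", "ad2"),
                    out = c("nv"))
  # all present everywhere: no gains or losses
  all_in <- tibble::tibble(family_id = c("f1", "f2"), mc1 = 1, mc2 = 1,
                           ad1 = 1, ad2 = 1, nv = 1)
  p0 <- partition_families(all_in, partition)
  expect_equal(p0$summary$n[p0$summary$category == "gain"], 0L)
  expect_equal(p0$summary$n[p0$summary$category == "loss"], 0L)

  # hand-assigned 8-family presence table
  toy <- tibble::tibble(
    family_id = sprintf("f%d", 1:8),
    mc1 = c(1, 0, 1, 0, 1, 0, 0, 1),
    mc2 = c(1, 0, 0, 0, 0, 0, 1, 0),
    ad1 = c(0, 1, 1, 0, 0, 1, 0, 0),
    ad2 = c(0, 1, 0, 0, 0, 0, 0, 0),
    nv  = c(0, 1, 0, 1, 1, 0, 0, 0))
  # manual: f1 gain; f2 loss (absent focal, present acro+out);
  # f3 shared; f4 other (out only); f5 shared; f6 other (acro only);
  # f7 gain; f8 gain
  p <- partition_families(toy, partition)
  want <- c(gain = 3L, loss = 1L, shared = 2L, other = 2L)
  got <- setNames(p$summary$n, p$summary$category)
  expect_equal(got[names(want)], want)
  # disjoint cells sum to all families with any presence
  expect_equal(sum(p$summary$n), 8L)

  expect_error(partition_families(toy, list(focal = "mc1", bad = "zz")),
               class = "genomescape_error_species_mismatch")
})
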