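SENSE <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
rand_cds <- function(n) paste(sample(SENSE, n, TRUE), collapse = "")
translate1 <- function(cds) {
  cod <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  paste(Biostrings::GENETIC_CODE[cod], collapse = "")
}

test_that("back-translation mirrors the protein alignment codon by codon", {
  # gap-free pair: width is 3x the protein width
  set.seed(97)
  c1 <- rand_cds(20); c2 <- rand_cds(20)
  paln <- tibble::tibble(id = c("a", "b"),
                         seq = c(translate1(c1), translate1(c2)))
  cod <- backtranslate_alignment(paln, tibble::tibble(id = c("a", "b"),
                                                      cds = c(c1, c2)))
  expect_equal(nchar(cod$seq), c(60, 60))
  expect_equal(cod$seq[1], c1)

  # protein gap becomes a codon gap
  paln2 <- tibble::tibble(id = c("a", "b"), seq = c("M-K", "MRK"))
  cds2 <- tibble::tibble(id = c("a", "b"),
                         cds = c("ATGAAA", "ATGCGCAAG"))
  cod2 <- backtranslate_alignment(paln2, cds2)
  expect_equal(cod2$seq[1], "ATG---AAA")
  expect_equal(cod2$seq[2], "ATGCGCAAG")

  # translation mismatch raises a positioned error
  expect_error(
    backtranslate_alignment(paln2,
                            tibble::tibble(id = c("a", "b"),
                                           cds = c("ATGGGG", "ATGCGCAAG"))),
    class = "genomescape_error_translation_mismatch")

  # round trip: translating the back-translated rows recovers the protein
  for (i in 1:25) {
    n <- sample(5:40, 1)
    ca <- rand_cds(n)
    pa <- translate1(ca)
    gaps <- sort(sample(nchar(pa) + 1, sample(0:3, 1)))
    gapped <- pa
    for (g in rev(gaps)) {
      gapped <- paste0(substr(gapped, 1, g - 1), "-",
                       substr(gapped, g, nchar(gapped)))
    }
    other <- rand_cds(nchar(gapped))
    paln3 <- tibble::tibble(id = c("a", "b"),
                            seq = c(gapped, translate1(other)))
    cod3 <- backtranslate_alignment(
      paln3, tibble::tibble(id = c("a", "b"), cds = c(ca, other)))
    back <- gsub("-", "", cod3$seq[1])
    expect_equal(translate1(back), pa)
  }
})

test_that("gap-codon stripping equals the codon-column filter oracle", {
  clean <- tibble::tibble(id = c("a", "b"),
                          seq = c("ATGAAACCC", "ATGAAGCCA"))
  expect_equal(strip_gap_codons(clean), clean)

  one_gap <- tibble::tibble(id = c("a", "b"),
                            seq = c("ATG---AAA", "ATGCGCAAG"))
  got <- strip_gap_codons(one_gap)
  expect_equal(got$seq, c("ATGAAA", "ATGAAG"))

  expect_error(strip_gap_codons(tibble::tibble(
    id = c("a", "b"), seq = c("AT-AAA", "ATGAAA"))),
    class = "genomescape_error_partial_codon_gap")

  set.seed(101)
  for (i in 1:10) {
    n <- 12
    codons1 <- vapply(1:n, function(j) sample(SENSE, 1), "")
    codons2 <- vapply(1:n, function(j) sample(SENSE, 1), "")
    gap_cols <- runif(n) < 0.25
    side <- sample(1:2, n, TRUE)
    codons1[gap_cols & side == 1] <- "---"
    codons2[gap_cols & side == 2] <- "---"
    aln <- tibble::tibble(id = c("a", "b"),
                          seq = c(paste(codons1, collapse = ""),
                                  paste(codons2, collapse = "")))
    got <- strip_gap_codons(aln)
    keep <- !(codons1 == "---" | codons2 == "---")
    expect_equal(got$seq, c(paste(codons1[keep], collapse = ""),
                            paste(codons2[keep], collapse = "")))
  }
})

test_that("NG86 reproduces independently computed single-codon tallies", {
  pair <- function(a, b) tibble::tibble(id = c("x", "y"), seq = c(a, b))
  # identical sequences
  r0 <- ng86_dnds(pair("ATGAAA", "ATGAAA"))
  expect_equal(r0$ka, 0); expect_equal(r0$ks, 0)

  # frozen values computed with an independent NG86 implementation
  r1 <- ng86_dnds(pair("TTT", "TTA"))
  expect_equal(r1$ka, 0.571605, tolerance = 1e-6)
  expect_equal(r1$ks, 0)
  expect_equal(r1$syn_sites, 0.5)
  expect_equal(r1$nonsyn_sites, 2.5)

  r2 <- ng86_dnds(pair("TTTGGG", "TTAGGA"))
  expect_equal(r2$ka, 0.2635484, tolerance = 1e-6)
  expect_equal(r2$ks, 1.647918, tolerance = 1e-6)

  # two-hit codon with pathway averaging; dS undefined at p_s = 3/4
  r3 <- ng86_dnds(pair("CCT", "CAG"))
  expect_equal(r3$ka, 1.459433, tolerance = 1e-6)
  expect_false(r3$ks_defined)

  # synonymous-only divergence: Ka exactly zero
  r4 <- ng86_dnds(pair("TTGAGG", "TTGCGG"))
  expect_equal(r4$ka, 0)
  expect_equal(r4$ks, 1.207078, tolerance = 1e-6)

  expect_error(ng86_dnds(pair("TAAAAA", "TAAAAG")),
               class = "genomescape_error_internal_stop")
})

test_that("NG86 is symmetric and zero on synonymous-only divergence", {
  set.seed(103)
  for (i in 1:10) {
    a <- rand_cds(30); b <- mutate_seq(a, 0.1)
    # re-draw until stop-free
    while (grepl("TAA|TAG|TGA",
                 paste(substring(b, seq(1, 88, 3), seq(3, 90, 3)),
                       collapse = "|"))) b <- mutate_seq(a, 0.1)
    f <- ng86_dnds(tibble::tibble(id = c("x", "y"), seq = c(a, b)))
    r <- ng86_dnds(tibble::tibble(id = c("y", "x"), seq = c(b, a)))
    expect_equal(f$ka, r$ka)
    expect_equal(f$ks, r$ks)
  }
  # swap synonymous codons only
  a <- paste(rep("CTG", 20), collapse = "")   # Leu
  b <- paste(rep(c("CTG", "CTA"), 10), collapse = "")
  r <- ng86_dnds(tibble::tibble(id = c("x", "y"), seq = c(a, b)))
  expect_identical(r$ka, 0)
  expect_gt(r$ks, 0)
})

test_that("equal syn/nonsyn mutation pressure gives Ka/Ks near one", {
  # evolve one sequence by accepting random single-nucleotide changes
  # regardless of their effect: under NG86 this should give dN/dS ~ 1
  set.seed(107)
  ratios <- replicate(10, {
    a <- rand_cds(300)
    b <- a
    changed <- 0
    while (changed < 60) {
      pos <- sample(nchar(b), 1)
      nt <- sample(setdiff(c("A", "C", "G", "T"),
                           substr(b, pos, pos)), 1)
      cand <- paste0(substr(b, 1, pos - 1), nt,
                     substr(b, pos + 1, nchar(b)))
      cod <- substring(cand, seq(1, nchar(cand) - 2, 3),
                       seq(3, nchar(cand), 3))
      if (!any(Biostrings::GENETIC_CODE[cod] == "*")) {
        b <- cand; changed <- changed + 1
      }
    }
    r <- ng86_dnds(tibble::tibble(id = c("x", "y"), seq = c(a, b)))
    r$ka / r$ks
  })
  expect_lt(abs(mean(ratios) - 1), 0.25)
})

test_that("fast-evolving ranking sizes and ordering follow round-half-up", {
  set.seed(109)
  res <- tibble::tibble(pair_id = sprintf("p%05d", 1:12196),
                        ka = runif(12196, 0, 2))
  top <- rank_fast_evolving(res, 0.10)
  expect_equal(top$size, 1220)
  expect_equal(nrow(top$test_set), 1220)
  expect_true(all(diff(top$test_set$ka) <= 0))

  res10 <- tibble::tibble(pair_id = letters[1:10], ka = runif(10))
  top10 <- rank_fast_evolving(res10, 0.10)
  expect_equal(top10$test_set$pair_id, res10$pair_id[which.max(res10$ka)])

  # sort-and-slice oracle with NA exclusion
  res2 <- tibble::tibble(pair_id = sprintf("q%03d", 1:157),
                         ka = c(runif(150), rep(NA, 7)))
  got <- rank_fast_evolving(res2, 0.25)
  want <- res2[!is.na(res2$ka), ]
  want <- want[order(-want$ka, want$pair_id), ][1:floor(0.25 * 150 + 0.5), ]
  expect_equal(got$test_set$pair_id, want$pair_id)
  expect_equal(got$n_excluded_undefined, 7)

  # size formula across n
  for (n in c(1, 7, 10, 99, 1000, 99999)) {
    r <- tibble::tibble(pair_id = as.character(seq_len(n)), ka = runif(n))
    expect_equal(rank_fast_evolving(r, 0.1)$size, floor(0.1 * n + 0.5))
  }
  expect_error(rank_fast_evolving(res[0, ]),
               class = "genomescape_error_empty_input")
})

test_that("enrichment p-values equal the hypergeometric summation oracle", {
  test_ann <- tibble::tibble(
    gene_id = sprintf("t%02d", 1:10),
    term = c(rep("GO:1", 3), rep("GO:2", 7)))
  ref_ann <- tibble::tibble(
    gene_id = sprintf("r%02d", 1:50),
    term = c(rep("GO:1", 5), rep("GO:2", 45)))
  out <- fisher_enrichment(test_ann, ref_ann)
  expect_equal(out$p_value[out$term == "GO:1"],
               oracle_hyper_tail(3, 10, 5, 50), tolerance = 1e-12)
  expect_equal(out$p_value[out$term == "GO:2"],
               oracle_hyper_tail(7, 10, 45, 50), tolerance = 1e-12)

  # a term private to the whole test set is overwhelmingly significant
  t2 <- tibble::tibble(gene_id = sprintf("t%02d", 1:10), term = "GO:X")
  r2 <- tibble::tibble(gene_id = sprintf("r%02d", 1:50), term = "GO:Y")
  out2 <- fisher_enrichment(t2, r2)
  expect_lt(out2$p_value[out2$term == "GO:X"], 1e-6)
  expect_true(out2$significant[out2$term == "GO:X"])

  # p in (0,1] and monotone: more test hits with fixed margins
  p_at <- function(k) {
    ta <- tibble::tibble(gene_id = sprintf("t%02d", 1:20),
                         term = c(rep("GO:1", k), rep("GO:other", 20 - k)))
    ra <- tibble::tibble(gene_id = sprintf("r%02d", 1:80),
                         term = c(rep("GO:1", 10), rep("GO:other", 70)))
    out <- fisher_enrichment(ta, ra)
    out$p_value[out$term == "GO:1"]
  }
  ps <- vapply(1:8, p_at, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("fast-evolving x DE intersections match set algebra", {
  de <- tibble::tibble(
    contrast = rep(c("heat_1h", "heat_6h"), c(4, 5)),
    gene_id = c("g1", "g2", "g3", "g4", "g1", "g5", "g6", "g7", "g8"),
    direction = c("up", "up", "down", "down",
                  "up", "up", "up", "down", "down"))
  fast <- c("g1", "g3", "g6", "g9")
  out <- intersect_fast_de(fast, de)
  h1 <- out$per_contrast[out$per_contrast$contrast == "heat_1h", ]
  expect_equal(c(h1$n_up, h1$n_down), c(1L, 1L))
  h6 <- out$per_contrast[out$per_contrast$contrast == "heat_6h", ]
  expect_equal(c(h6$n_up, h6$n_down), c(2L, 0L))
  expect_equal(out$union_n, 3L)

  # disjoint sets: zeros
  out0 <- intersect_fast_de(c("zz"), de)
  expect_true(all(out0$per_contrast$n_total == 0))
  # fast == de: counts equal set sizes
  outA <- intersect_fast_de(unique(de$gene_id), de)
  expect_equal(sum(outA$per_contrast$n_total), nrow(de))
})
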