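test_that("pairwise identity matches the dynamic-programming oracle", {
  # identity case
  s <- rand_dna(30)
  expect_equal(pairwise_identity(s, s),
               tibble::tibble(identity = 1, coverage = 1))
  # a worst-case quartet against the exhaustive DP oracle
  expect_equal(pairwise_identity("ACGT", "TGCA")$identity,
               oracle_identity("ACGT", "TGCA"))
  # random pairs: the alignment engine must reach the oracle's optimal
  # score (co-optimal tracebacks can differ, so identity is checked with
  # slack while the score is exact)
  set.seed(11)
  for (i in 1:20) {
    a <- rand_dna(sample(10:40, 1))
    b <- rand_dna(sample(10:40, 1))
    aln <- Biostrings::pairwiseAlignment(
      a, b, type = "global",
      substitutionMatrix = {
        m <- diag(5); dimnames(m) <- list(c("A","C","G","T","N"),
                                          c("A","C","G","T","N")); m
      }, gapOpening = 0, gapExtension = 1)
    expect_equal(Biostrings::score(aln), oracle_global_align(a, b)$score)
    expect_lt(abs(pairwise_identity(a, b)$identity - oracle_identity(a, b)),
              0.15)
  }
  # equal-length lightly mutated pairs align uniquely: identity exact
  for (i in 1:10) {
    a <- rand_dna(60)
    b <- mutate_seq(a, 0.1)
    expect_equal(pairwise_identity(a, b)$identity, oracle_identity(a, b),
                 tolerance = 1e-12)
  }
})

test_that("identity of a half-mutated copy is near one half", {
  set.seed(7)
  a <- rand_dna(100)
  b <- mutate_seq(a, 0.5)
  # gap-free Hamming oracle: sequences are equal length, so the global
  # alignment should essentially be the direct one
  hamming <- mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  got <- pairwise_identity(a, b)$identity
  expect_gte(got, hamming - 1e-9)     # alignment can only improve on it
  expect_lt(abs(got - 0.5), 0.12)
})

test_that("self identity is perfect for any sequence", {
  set.seed(21)
  for (i in 1:10) {
    s <- if (i %% 2) rand_dna(sample(5:60, 1)) else rand_prot(sample(5:60, 1))
    expect_equal(pairwise_identity(s, s),
                 tibble::tibble(identity = 1, coverage = 1))
  }
})

test_that("pairwise identity rejects bad input with typed errors", {
  expect_error(pairwise_identity("ACGT", ""),
               class = "genomescape_error_empty_sequence")
  expect_error(pairwise_identity("ACGT", "MKLV", alphabet = "dna"),
               class = "genomescape_error_alphabet_mismatch")
})

test_that("greedy clustering groups identical and separates unrelated", {
  s3 <- tibble::tibble(id = c("x", "y", "z"),
                       seq = rep(strrep("ACGT", 10), 3))
  cl <- greedy_cluster(s3, identity_cutoff = 0.9, min_coverage = 0.9)
  expect_equal(length(unique(cl$cluster)), 1)
  expect_equal(nrow(cl), 3)

  set.seed(5)
  two <- tibble::tibble(id = c("p", "q"),
                        seq = c(rand_prot(50), rand_prot(50)))
  cl2 <- greedy_cluster(two, identity_cutoff = 0.9, min_coverage = 0.5)
  expect_equal(length(unique(cl2$cluster)), 2)
})

test_that("greedy clustering equals the first-qualifying-representative oracle", {
  set.seed(31)
  base <- rand_dna(60)
  seqs <- tibble::tibble(
    id = sprintf("s%02d", 1:10),
    seq = c(base,
            vapply(1:5, function(i) mutate_seq(base, runif(1, 0.05, 0.5)), ""),
            vapply(1:4, function(i) rand_dna(sample(40:80, 1)), "")))
  got <- greedy_cluster(seqs, identity_cutoff = 0.7, min_coverage = 0.5)
  want <- oracle_greedy_cluster(seqs, 0.7, 0.5)
  expect_equal(got, want)
})

test_that("greedy clustering yields a partition and exact-duplicate groups at 1.0", {
  set.seed(41)
  seqs <- tibble::tibble(id = sprintf("s%02d", 1:12),
                         seq = c(rep(rand_dna(40), 3),
                                 vapply(1:9, function(i) rand_dna(40), "")))
  cl <- greedy_cluster(seqs, identity_cutoff = 1, min_coverage = 1)
  # partition: every id exactly once
  expect_setequal(cl$id, seqs$id)
  expect_equal(anyDuplicated(cl$id), 0L)
  # only the three duplicates share a cluster
  sizes <- table(cl$cluster)
  expect_equal(sort(as.integer(sizes), decreasing = TRUE)[1], 3L)
  expect_true(all(sort(as.integer(sizes), decreasing = TRUE)[-1] == 1L))
})

test_that("alignment trimming matches the counting oracle and is idempotent", {
  # gap-free alignment untouched
  aln <- tibble::tibble(id = c("a", "b", "c"),
                        seq = c("MKLV", "MKIV", "MRLV"))
  expect_equal(trim_alignment(aln, 0.3, 0.5), aln)

  # a fully gapped column disappears
  aln2 <- tibble::tibble(id = letters[1:4],
                         seq = c("M-KL", "M-KI", "M-RL", "M-RV"))
  got2 <- trim_alignment(aln2, 0.5, 0.9)
  expect_equal(nchar(got2$seq[1]), 3)
  expect_equal(nrow(got2), 4)

  # random alignments vs the explicit per-column/per-row counting oracle
  set.seed(13)
  for (rep in 1:10) {
    mat <- matrix(sample(c("A", "C", "D", "E"), 600, TRUE), 10, 60)
    mat[matrix(runif(600) < 0.2, 10, 60)] <- "-"
    aln3 <- tibble::tibble(id = sprintf("t%02d", 1:10),
                           seq = apply(mat, 1, paste, collapse = ""))
    want <- oracle_trim(mat, 0.3, 0.5)
    got3 <- tryCatch(trim_alignment(aln3, 0.3, 0.5),
                     genomescape_error_degenerate_alignment = function(e) NULL)
    if (is.null(got3)) {
      expect_true(nrow(want) < 2 || ncol(want) == 0)
    } else {
      expect_equal(do.call(rbind, strsplit(got3$seq, "")),
                   unname(want), ignore_attr = TRUE)
      # idempotence
      expect_equal(trim_alignment(got3, 0.3, 0.5), got3)
    }
  }
})

test_that("concatenation filters short alignments and sums lengths", {
  mk <- function(w) tibble::tibble(id = c("A", "B", "C"),
                                   seq = vapply(1:3, function(i)
                                     rand_prot(w), ""))
  set.seed(3)
  out <- concatenate_alignments(list(mk(150), mk(150)), min_len = 120)
  expect_equal(nchar(out$seq[1]), 300)
  out2 <- concatenate_alignments(list(mk(119), mk(200)), min_len = 120)
  expect_equal(nchar(out2$seq[1]), 200)
  bad <- mk(150); bad$id <- c("A", "B", "D")
  expect_error(concatenate_alignments(list(mk(150), bad), 120),
               class = "genomescape_error_taxon_mismatch")
})

test_that("a 211-gene super-alignment reaches 54,795 columns", {
  # synthetic single-gene alignments whose retained lengths sum to the
  # published super-alignment size: 210 x 259 + 1 x 405 = 54,795
  set.seed(17)
  lens <- c(rep(259, 210), 405)
  taxa <- sprintf("sp%02d", 1:12)
  alns <- lapply(lens, function(w)
    tibble::tibble(id = taxa, seq = vapply(taxa, function(t)
      rand_prot(w), "")))
  short <- list(tibble::tibble(id = taxa, seq = vapply(taxa, function(t)
    rand_prot(80), "")))
  out <- concatenate_alignments(c(alns, short), min_len = 120)
  expect_equal(length(lens), 211)
  expect_equal(nchar(out$seq[1]), 54795)
  expect_equal(nrow(out), 12)
})

test_that("neighbor joining recovers additive distances and topologies", {
  # 4-taxon additive matrix: ((A,B),(C,D)) with known branch lengths
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  bl <- c(A = 1, B = 2, C = 3, D = 4); inner <- 5
  d["A", "B"] <- d["B", "A"] <- bl["A"] + bl["B"]
  for (x in c("A", "B")) for (y in c("C", "D")) {
    d[x, y] <- d[y, x] <- bl[x] + inner + bl[y]
  }
  d["C", "D"] <- d["D", "C"] <- bl["C"] + bl["D"]
  tr <- nj_tree(d)
  patristic <- cophenetic(tr)[rownames(d), colnames(d)]
  expect_lt(max(abs(patristic - d)), 1e-9)

  # 3 taxa: the unique unrooted topology
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  expect_equal(length(nj_tree(d3)$tip.label), 3)

  # rebuild a known 6-leaf tree from its patristic distances
  set.seed(9)
  for (i in 1:5) {
    true <- ape::rtree(6)
    rebuilt <- nj_tree(cophenetic(true))
    expect_equal(phangorn::RF.dist(ape::unroot(true), rebuilt), 0)
  }

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)),
               class = "genomescape_error_bad_input")
  dd <- matrix(runif(16), 4); diag(dd) <- 0
  expect_error(nj_tree(dd), class = "genomescape_error_bad_input")
})
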