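# Shared sequence, alignment and clustering primitives.
#
# Sequences travel as tidy tables with columns `id` and `seq` (one row per
# sequence); alignments are the same shape with equal-width gapped strings.
# Biostrings does the dynamic programming; everything layered on top
# (identity bookkeeping, greedy clustering, alignment trimming) is defined
# here so it can be checked against independent counting oracles.

DNA_LETTERS  <- c("A", "C", "G", "T", "N")
PROT_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")

#' Validate a sequence table
#'
#' Checks the invariants every sequence set must satisfy: unique non-empty
#' ids, non-empty sequences, residues drawn from the declared alphabet
#' (gaps allowed only when `gapped = TRUE`).
#'
#' @param seqs A data frame with columns `id` and `seq`.
#' @param alphabet `"dna"` (ACGTN) or `"protein"`.
#' @param gapped Allow `-` and `.` characters (aligned sequences)?
#' @return The input as a tibble, invisibly checked.
#' @export
validate_seqs <- function(seqs, alphabet = c("dna", "protein"),
                          gapped = FALSE) {
  alphabet <- match.arg(alphabet)
  seqs <- as_tibble(seqs)
  if (!all(c("id", "seq") %in% names(seqs))) {
    gs_abort("`seqs` must have columns `id` and `seq`.", "bad_input")
  }
  if (any(is.na(seqs$id)) || any(seqs$id == "")) {
    gs_abort("Sequence ids must be non-empty.", "bad_input")
  }
  if (anyDuplicated(seqs$id)) {
    gs_abort("Sequence ids must be unique within a set.", "bad_input")
  }
  if (any(is.na(seqs$seq)) || any(nchar(seqs$seq) == 0)) {
    gs_abort("Sequences must be non-empty.", "empty_sequence")
  }
  letters_ok <- switch(alphabet, dna = DNA_LETTERS, protein = PROT_LETTERS)
  if (gapped) letters_ok <- c(letters_ok, "-", ".")
  bad <- setdiff(unique(unlist(strsplit(toupper(seqs$seq), ""))), letters_ok)
  if (length(bad) > 0) {
    gs_abort(paste0("Residues outside the ", alphabet, " alphabet: ",
                    paste(bad, collapse = ", ")), "alphabet_mismatch")
  }
  seqs$seq <- toupper(seqs$seq)
  seqs
}

guess_alphabet <- function(x) {
  chars <- unique(unlist(strsplit(toupper(x), "")))
  if (all(chars %in% c(DNA_LETTERS, "-", "."))) "dna" else "protein"
}

identity_submat <- function(alphabet) {
  letters_ok <- switch(alphabet, dna = DNA_LETTERS, protein = PROT_LETTERS)
  m <- matrix(0, length(letters_ok), length(letters_ok),
              dimnames = list(letters_ok, letters_ok))
  diag(m) <- 1
  m
}

# Global alignment of two residue strings under match = 1, mismatch = 0,
# gap = -1 per position.  Returns the two gapped rows.
align_pair <- function(a, b, alphabet, type = "global") {
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = type,
    substitutionMatrix = identity_submat(alphabet),
    gapOpening = 0, gapExtension = 1)
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)))
}

#' Pairwise identity and coverage between two sequences
#'
#' Globally aligns two sequences (match = 1, mismatch = 0, gap = -1) and
#' reports the identity over aligned columns excluding terminal gaps, and
#' the fraction of the shorter sequence covered by the aligned span. This is
#' the deterministic identity backbone behind the Cd-hit-style greedy
#' clustering used throughout the package.
#'
#' @param a,b Residue strings (single sequences) over one alphabet.
#' @param mode `"global"` end-to-end alignment, or `"query_cover"`
#'   (ends-free overlap alignment, appropriate when one sequence is a
#'   fragment of the other).
#' @param alphabet `"dna"`, `"protein"`, or `NULL` to infer.
#' @return One-row tibble with columns `identity` and `coverage`, both in
#'   \[0, 1\].
#' @export
pairwise_identity <- function(a, b, mode = c("global", "query_cover"),
                              alphabet = NULL) {
  mode <- match.arg(mode)
  if (length(a) != 1 || length(b) != 1 || is.na(a) || is.na(b) ||
      nchar(a) == 0 || nchar(b) == 0) {
    gs_abort("Both sequences must be non-empty strings.", "empty_sequence")
  }
  a <- toupper(a); b <- toupper(b)
  if (is.null(alphabet)) {
    alphabet <- guess_alphabet(c(a, b))
  }
  ok <- switch(alphabet, dna = DNA_LETTERS, protein = PROT_LETTERS)
  if (!all(unlist(strsplit(c(a, b), "")) %in% ok)) {
    gs_abort("Sequences do not share the declared alphabet.",
             "alphabet_mismatch")
  }
  pairwise_identity_batch(a, b, mode = mode, alphabet = alphabet)
}

# Vectorized form: one query against many targets in a single alignment
# call, with the same identity/coverage definitions as pairwise_identity.
pairwise_identity_batch <- function(query, targets, mode = "global",
                                    alphabet = "protein") {
  type <- if (mode == "global") "global" else "overlap"
  aln <- Biostrings::pairwiseAlignment(
    pattern = targets, subject = query, type = type,
    substitutionMatrix = identity_submat(alphabet),
    gapOpening = 0, gapExtension = 1)
  pa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  qlen <- nchar(query)
  out <- map(seq_along(targets), function(j) {
    ca <- strsplit(pa[j], "")[[1]]
    cb <- strsplit(sa[j], "")[[1]]
    gap_a <- ca %in% c("-", ".")
    gap_b <- cb %in% c("-", ".")
    both <- which(!gap_a & !gap_b)
    if (length(both) == 0) return(c(identity = 0, coverage = 0))
    core <- seq(min(both), max(both))
    matches <- sum(ca[core] == cb[core] & !gap_a[core])
    shorter_len <- min(qlen, nchar(targets[j]))
    shorter_gap <- if (nchar(targets[j]) <= qlen) gap_a else gap_b
    covered <- sum(!shorter_gap[core])
    c(identity = matches / length(core),
      coverage = covered / shorter_len)
  })
  m <- do.call(rbind, out)
  tibble(identity = unname(m[, "identity"]),
         coverage = unname(m[, "coverage"]))
}

#' Greedy length-sorted sequence clustering
#'
#' A deterministic Cd-hit-style greedy-incremental clusterer: sequences are
#' sorted by descending length (ties broken by id), and each sequence joins
#' the first existing cluster whose representative it matches at
#' `identity_cutoff` identity or better with at least `min_coverage` of the
#' shorter sequence aligned; otherwise it founds a new cluster.
#'
#' @param seqs Data frame with columns `id`, `seq`.
#' @param identity_cutoff Identity threshold in (0, 1\].
#' @param min_coverage Minimum aligned coverage of the shorter sequence.
#' @param alphabet `"dna"`, `"protein"`, or `NULL` to infer.
#' @return Tibble with columns `id`, `cluster` (integer, founding order),
#'   `representative` (id of the cluster founder).
#' @export
greedy_cluster <- function(seqs, identity_cutoff, min_coverage = 0,
                           alphabet = NULL) {
  if (identity_cutoff <= 0 || identity_cutoff > 1) {
    gs_abort("`identity_cutoff` must be in (0, 1].", "bad_input")
  }
  seqs <- as_tibble(seqs)
  if (nrow(seqs) == 0) {
    return(tibble(id = character(), cluster = integer(),
                  representative = character()))
  }
  if (is.null(alphabet)) alphabet <- guess_alphabet(seqs$seq)
  seqs <- validate_seqs(seqs, alphabet)
  ord <- order(-nchar(seqs$seq), seqs$id)
  seqs <- seqs[ord, ]
  rep_id <- character(0)
  rep_seq <- character(0)
  assignment <- integer(nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    hit <- 0L
    if (length(rep_id) > 0) {
      m <- pairwise_identity_batch(seqs$seq[i], rep_seq,
                                   mode = "query_cover",
                                   alphabet = alphabet)
      ok <- which(m$identity >= identity_cutoff &
                    m$coverage >= min_coverage)
      if (length(ok) > 0) hit <- ok[1]
    }
    if (hit == 0L) {
      rep_id <- c(rep_id, seqs$id[i])
      rep_seq <- c(rep_seq, seqs$seq[i])
      hit <- length(rep_id)
    }
    assignment[i] <- hit
  }
  tibble(id = seqs$id, cluster = assignment,
         representative = rep_id[assignment])
}

# Pairwise (1 - identity) distance matrix over a sequence set, batched
# through vectorized global alignment; identity over aligned positions.
identity_dist_matrix <- function(seqs, ids = names(seqs),
                                 alphabet = "protein") {
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sub <- identity_submat(alphabet)
  for (i in seq_len(n - 1)) {
    rest <- seq(i + 1, n)
    aln <- Biostrings::pairwiseAlignment(
      pattern = seqs[rest], subject = seqs[i], type = "global",
      substitutionMatrix = sub, gapOpening = 0, gapExtension = 1)
    ident <- Biostrings::pid(aln, type = "PID2") / 100
    d[i, rest] <- d[rest, i] <- 1 - ident
  }
  d
}

missing_chars <- function(alphabet) {
  switch(alphabet, dna = c("-", ".", "N"), protein = c("-", ".", "X"))
}

aln_matrix <- function(aln) {
  widths <- nchar(aln$seq)
  if (length(unique(widths)) != 1) {
    gs_abort("Alignment rows must have equal length.", "bad_alignment")
  }
  do.call(rbind, strsplit(toupper(aln$seq), ""))
}

#' Trim an alignment by missing-data thresholds
#'
#' Drops columns whose missing-data fraction (gaps plus ambiguity
#' characters, `X` for protein and `N` for nucleotide) is at or above
#' `max_col_missing`, then drops rows whose missing fraction over the
#' retained columns is at or above `max_seq_missing`. The two passes are
#' repeated until the alignment is stable, so the result is idempotent.
#'
#' @param aln Data frame with columns `id`, `seq` (equal-width gapped rows).
#' @param max_col_missing Column missing-data threshold (default 0.3).
#' @param max_seq_missing Row missing-data threshold (default 0.5).
#' @param alphabet `"protein"` or `"dna"`.
#' @return Trimmed alignment tibble; errors with class
#'   `genomescape_error_degenerate_alignment` if fewer than 2 rows or no
#'   columns survive.
#' @export
trim_alignment <- function(aln, max_col_missing = 0.3, max_seq_missing = 0.5,
                           alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  aln <- as_tibble(aln)
  m <- aln_matrix(aln)
  ids <- aln$id
  miss <- missing_chars(alphabet)
  repeat {
    if (nrow(m) < 2 || ncol(m) == 0) break
    col_frac <- colMeans(matrix(m %in% miss, nrow = nrow(m)))
    keep_cols <- col_frac < max_col_missing
    m <- m[, keep_cols, drop = FALSE]
    if (ncol(m) == 0) break
    row_frac <- rowMeans(matrix(m %in% miss, nrow = nrow(m)))
    keep_rows <- row_frac < max_seq_missing
    if (all(keep_cols) && all(keep_rows)) break
    m <- m[keep_rows, , drop = FALSE]
    ids <- ids[keep_rows]
  }
  if (nrow(m) < 2 || ncol(m) == 0) {
    gs_abort("Trimming left a degenerate alignment (<2 rows or 0 columns).",
             "degenerate_alignment")
  }
  tibble(id = ids, seq = apply(m, 1, paste, collapse = ""))
}

#' Concatenate per-gene alignments into a super-alignment
#'
#' Excludes alignments shorter than `min_len` columns, requires all
#' remaining alignments to cover the identical taxon set, and concatenates
#' their columns in input order.
#'
#' @param alns List of alignment tibbles (`id`, `seq`).
#' @param min_len Minimum alignment length (columns) to retain; default 120,
#'   the conventional single-gene length floor for concatenated
#'   phylogenomic matrices.
#' @return One alignment tibble whose width is the sum of retained widths.
#' @export
concatenate_alignments <- function(alns, min_len = 120) {
  if (length(alns) == 0) gs_abort("No alignments supplied.", "bad_input")
  widths <- map_int(alns, ~ nchar(.x$seq[1]))
  keep <- which(widths >= min_len)
  if (length(keep) == 0) {
    gs_abort("No alignment reaches `min_len` columns.", "degenerate_alignment")
  }
  taxa <- sort(alns[[keep[1]]]$id)
  for (k in keep) {
    if (!identical(sort(alns[[k]]$id), taxa)) {
      gs_abort(paste0("Alignment ", k, " does not cover the shared taxon set."),
               "taxon_mismatch")
    }
  }
  order_ids <- alns[[keep[1]]]$id
  pieces <- map(keep, function(k) {
    aln <- alns[[k]]
    aln$seq[match(order_ids, aln$id)]
  })
  tibble(id = order_ids,
         seq = do.call(paste0, pieces))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via \pkg{ape}) on a symmetric pairwise
#' distance matrix; additive matrices are recovered exactly.
#'
#' @param dist Square symmetric numeric matrix, zero diagonal, n >= 3,
#'   with row/col names used as tip labels.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) != ncol(dist) || nrow(dist) < 3) {
    gs_abort("Distance matrix must be square with n >= 3.", "bad_input")
  }
  if (max(abs(dist - t(dist))) > 1e-8 || any(diag(dist) != 0)) {
    gs_abort("Distance matrix must be symmetric with a zero diagonal.",
             "bad_input")
  }
  if (is.null(rownames(dist))) {
    rownames(dist) <- colnames(dist) <- paste0("t", seq_len(nrow(dist)))
  }
  ape::nj(dist)
}
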