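# Independent oracles used to check the package implementations.
# Everything here is deliberately naive (plain DP, exhaustive path
# counting, direct summation) and shares no code with R/.

# --- Needleman-Wunsch DP, match = 1 / mismatch = 0 / gap = -1 --------------
oracle_global_align <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n)
  S[1, ] <- -(0:m)
  for (i in 1:n) {
    for (j in 1:m) {
      S[i + 1, j + 1] <- max(
        S[i, j] + as.integer(av[i] == bv[j]),
        S[i, j + 1] - 1,
        S[i + 1, j] - 1)
    }
  }
  # traceback (prefer diagonal for determinism)
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + as.integer(av[i] == bv[j])) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1
    }
  }
  list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""),
       score = S[n + 1, m + 1])
}

oracle_identity <- function(a, b) {
  al <- oracle_global_align(a, b)
  ca <- strsplit(al$a, "")[[1]]
  cb <- strsplit(al$b, "")[[1]]
  both <- which(ca != "-" & cb != "-")
  core <- seq(min(both), max(both))
  sum(ca[core] == cb[core] & ca[core] != "-") / length(core)
}

# --- exhaustive betweenness via all-pairs BFS path counting ----------------
# For every vertex v: sum over ordered pairs (s,t), s!=t!=v, of
# sigma_st(v)/sigma_st, halved for undirected graphs.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bfs <- function(s) {
    dist <- rep(Inf, n); sigma <- rep(0, n)
    dist[s] <- 0; sigma[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(adj[u, ] > 0)) {
          if (is.infinite(dist[v])) {
            dist[v] <- dist[u] + 1
            nxt <- c(nxt, v)
          }
          if (dist[v] == dist[u] + 1) sigma[v] <- sigma[v] + sigma[u]
        }
      }
      frontier <- unique(nxt)
    }
    list(dist = dist, sigma = sigma)
  }
  info <- lapply(seq_len(n), bfs)
  btw <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t || is.infinite(info[[s]]$dist[t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (info[[s]]$dist[v] + info[[v]]$dist[t] == info[[s]]$dist[t]) {
          btw[v] <- btw[v] +
            info[[s]]$sigma[v] * info[[v]]$sigma[t] / info[[s]]$sigma[t]
        }
      }
    }
  }
  btw / 2  # each unordered pair counted twice
}

# --- hypergeometric upper tail by direct summation -------------------------
oracle_hyper_tail <- function(k, K, n, N) {
  # P(X >= k), X = white draws when drawing K from an urn of (k+n) white
  # and (K+N)-(k+n) black balls
  white <- k + n
  black <- (K + N) - white
  kk <- k:min(K, white)
  sum(choose(white, kk) * choose(black, K - kk) / choose(white + black, K))
}

# --- hand-executed BH step-up ----------------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest rank down
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# --- alignment trimming by explicit counting (iterated to a fixpoint) ------
oracle_trim <- function(mat, max_col, max_row, miss = c("-", ".", "X")) {
  repeat {
    if (nrow(mat) < 2 || ncol(mat) == 0) break
    cf <- apply(mat, 2, function(col) mean(col %in% miss))
    m2 <- mat[, cf < max_col, drop = FALSE]
    if (ncol(m2) == 0) { mat <- m2; break }
    rf <- apply(m2, 1, function(row) mean(row %in% miss))
    m3 <- m2[rf < max_row, , drop = FALSE]
    if (identical(dim(m3), dim(mat)) && all(m3 == mat)) { mat <- m3; break }
    mat <- m3
  }
  mat
}

# --- greedy clustering following the declared rule literally ---------------
oracle_greedy_cluster <- function(seqs, cutoff, min_cov) {
  ord <- order(-nchar(seqs$seq), seqs$id)
  seqs <- seqs[ord, ]
  reps <- character(0)
  assign <- integer(nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    hit <- 0
    for (j in seq_along(reps)) {
      m <- pairwise_identity(seqs$seq[i], seqs$seq[match(reps[j], seqs$id)],
                             mode = "query_cover")
      if (m$identity >= cutoff && m$coverage >= min_cov) { hit <- j; break }
    }
    if (hit == 0) { reps <- c(reps, seqs$id[i]); hit <- length(reps) }
    assign[i] <- hit
  }
  tibble::tibble(id = seqs$id, cluster = assign,
                 representative = reps[assign])
}

# --- literal merge-rule application, per locus -----------------------------
# Takes gene-span tables (one row per model) and applies rules a/b/c exactly
# as written, enumerating homology models in genome order.
oracle_reconcile <- function(a_spans, h_spans, gain = 0.05) {
  overlaps <- function(r1, r2) {
    r1$contig == r2$contig & r1$strand == r2$strand &
      r1$start <= r2$end & r2$start <= r1$end
  }
  h_spans <- h_spans[order(h_spans$contig, h_spans$start, h_spans$gene_id), ]
  consumed <- character(0)
  emitted <- character(0)
  for (i in seq_len(nrow(h_spans))) {
    H <- h_spans[i, ]
    part <- a_spans[overlaps(a_spans, H[rep(1, nrow(a_spans)), ]), ]
    part <- part[!part$gene_id %in% consumed, ]
    if (nrow(part) >= 2) {
      disjoint <- FALSE
      for (p in seq_len(nrow(part) - 1)) for (q in seq(p + 1, nrow(part))) {
        if (!(part$start[p] <= part$end[q] && part$start[q] <= part$end[p]))
          disjoint <- TRUE
      }
      if (disjoint) {
        emitted <- c(emitted, H$gene_id)
        consumed <- c(consumed, part$gene_id)
      } # else ambiguous locus: ab initio kept, H dropped
    } else if (nrow(part) == 1) {
      if (H$completeness - part$completeness > gain) {
        emitted <- c(emitted, H$gene_id)
        consumed <- c(consumed, part$gene_id)
      }
    } else {
      emitted <- c(emitted, H$gene_id)
    }
  }
  sort(c(emitted, setdiff(a_spans$gene_id, consumed)))
}

# random sequence helpers ----------------------------------------------------
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
rand_prot <- function(n) {
  aa <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], character(0))
  paste(sample(aa, n, TRUE), collapse = "")
}
mutate_seq <- function(s, frac, alphabet = c("A", "C", "G", "T")) {
  ch <- strsplit(s, "")[[1]]
  k <- round(frac * length(ch))
  pos <- sample(length(ch), k)
  ch[pos] <- vapply(ch[pos],
                    function(x) sample(setdiff(alphabet, x), 1), "")
  paste(ch, collapse = "")
}
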