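# Independent brute-force oracles. Each recomputes its quantity from first
# principles, sharing no code path with the implementation it checks.

# Joint-histogram MI via explicit double loop. Bins are derived from the
# sort order (ties by original position), matching equal-frequency binning.
oracle_mi <- function(x, y, n_bins) {
  n <- length(x)
  bin_of <- function(v) {
    pos <- integer(n)
    pos[order(v)] <- seq_len(n)  # order() breaks ties by index
    ceiling(pos * n_bins / n)
  }
  bx <- bin_of(x); by <- bin_of(y)
  mi <- 0
  for (a in seq_len(n_bins)) {
    for (b in seq_len(n_bins)) {
      pab <- sum(bx == a & by == b) / n
      if (pab > 0) {
        mi <- mi + pab * log(pab / ((sum(bx == a) / n) * (sum(by == b) / n)))
      }
    }
  }
  mi
}

# BH step-up computed literally from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[ord[i]] <- min(1, min(p[ord][i:m] * m / (i:m)))
  }
  q
}

# Upper-tail hypergeometric P(X >= k) by enumerating all C(N, n) draws.
oracle_hyper_enum <- function(N, K, n, k) {
  draws <- combn(N, n)
  hits <- colSums(draws <= K)  # successes are items 1..K
  mean(hits >= k)
}

# DPI by exhaustive triplet enumeration against the input edge set.
oracle_dpi <- function(edges, tf_list, tolerance = 0) {
  get_mi <- function(a, b) {
    hit <- (edges$tf == a & edges$target == b) |
      (edges$tf == b & edges$target == a)
    if (!any(hit)) return(NA_real_)
    max(edges$mi[hit])
  }
  drop <- rep(FALSE, nrow(edges))
  tfs <- intersect(tf_list, unique(c(edges$tf, edges$target)))
  for (e in seq_len(nrow(edges))) {
    i <- edges$tf[e]; k <- edges$target[e]
    if (k %in% tf_list) next
    for (j in setdiff(tfs, i)) {
      m_ij <- get_mi(i, j); m_jk <- get_mi(j, k)
      if (!is.na(m_ij) && !is.na(m_jk) &&
          edges$mi[e] < (1 - tolerance) * min(m_ij, m_jk)) {
        drop[e] <- TRUE
      }
    }
  }
  edges[!drop, , drop = FALSE]
}

# GSEA enrichment score by a literal position-by-position running sum.
oracle_es <- function(genes, metric, gene_set, exponent) {
  N <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  denom <- sum(abs(metric[hit])^exponent)
  running <- 0; best <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      running <- running + if (denom > 0) abs(metric[i])^exponent / denom else 1 / nh
    } else {
      running <- running - 1 / (N - nh)
    }
    if (abs(running) > abs(best)) best <- running
  }
  best
}

# Lamb-style KS tag score by scanning every position of the rank list.
oracle_ks <- function(tags, instance) {
  n <- length(instance); t_n <- length(tags)
  V <- sort(match(tags, instance))
  a <- -Inf; b <- -Inf
  for (j in seq_len(t_n)) {
    a <- max(a, j / t_n - V[j] / n)
    b <- max(b, V[j] / n - (j - 1) / t_n)
  }
  if (a > b) a else -b
}

# Random expression fixture.
random_expr <- function(n_genes, n_samples, prefix = "G") {
  matrix(rnorm(n_genes * n_samples),
         nrow = n_genes,
         dimnames = list(sprintf("%s%03d", prefix, seq_len(n_genes)),
                         sprintf("S%03d", seq_len(n_samples))))
}
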