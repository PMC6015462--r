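#' Rank a differential expression result into a phenotype
#'
#' Genes sorted by descending logFC; ties are broken by lexicographic gene id
#' so the ordering is fully deterministic.
#'
#' @param de result of [moderated_t_test()] (or any data.frame with `gene`
#'   and `logFC`).
#' @return `ranked_phenotype`: data.frame with `gene`, `metric`, ordered.
#' @export
rank_phenotype <- function(de) {
  if (anyDuplicated(de$gene)) stopf("duplicate genes in DE result")
  ord <- order(-de$logFC, de$gene)
  out <- data.frame(gene = de$gene[ord], metric = de$logFC[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ranked_phenotype", "data.frame")
  out
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' GSEA running sum over the ranked list: a hit at position i increments by
#' `|metric_i|^exponent / sum_hits |metric|^exponent`, a miss decrements by
#' `1 / (N - |set|)`; the enrichment score is the signed maximum deviation
#' from zero, bounded in `[-1, 1]`.
#'
#' @param ranked a `ranked_phenotype`.
#' @param gene_set character vector; must intersect the ranked universe.
#' @param exponent weighting exponent (1 = metric-weighted, 0 = classic KS).
#' @return the enrichment score.
#' @export
enrichment_score <- function(ranked, gene_set, exponent = 1) {
  hit <- ranked$gene %in% gene_set
  if (!any(hit)) stopf("gene set is disjoint from the ranked universe")
  N <- nrow(ranked); nh <- sum(hit)
  w <- abs(ranked$metric)^exponent
  w[!hit] <- 0
  denom <- sum(w)
  steps <- if (denom == 0) {
    # all-zero metrics inside the set: fall back to unweighted hits
    ifelse(hit, 1 / nh, 0)
  } else {
    w / denom
  }
  if (nh < N) steps[!hit] <- -1 / (N - nh)
  running <- cumsum(steps)
  running[which.max(abs(running))]
}

#' Two-tail enrichment of a signed regulon
#'
#' Scores the positive-mode and negative-mode target subsets independently
#' in the ranked phenotype. `EsA` is the enrichment score of the positive
#' subset, `EsB` of the negative subset, and the differential score is
#' `dES = EsA - EsB`: strongly positive when the regulon is induced in the
#' disease phenotype, strongly negative when repressed. An empty subset has
#' its score defined as 0 (logged).
#'
#' @param regulon a `signed_regulon`.
#' @param ranked a `ranked_phenotype`.
#' @param exponent GSEA weighting exponent.
#' @return named numeric vector `c(EsA, EsB, dES)`.
#' @export
two_tail_es <- function(regulon, ranked, exponent = 1) {
  score_side <- function(targets, side) {
    present <- intersect(targets, ranked$gene)
    if (length(present) == 0L) {
      message(sprintf("empty %s-mode subset for %s: Es = 0", side, regulon$tf))
      return(0)
    }
    enrichment_score(ranked, present, exponent)
  }
  EsA <- score_side(names(regulon$pos), "positive")
  EsB <- score_side(names(regulon$neg), "negative")
  c(EsA = EsA, EsB = EsB, dES = EsA - EsB)
}

#' Permutation p-value for the differential enrichment score
#'
#' The null resamples gene labels: random disjoint subsets of the sizes of
#' the two mode subsets are drawn from the ranked universe and dES is
#' recomputed `n_perm` times; the two-sided p-value is
#' `(1 + #{|dES_null| >= |dES_obs|}) / (1 + n_perm)`.
#'
#' @inheritParams two_tail_es
#' @param n_perm permutation count (default 1000).
#' @param seed integer seed.
#' @return list with `p`, `dES`, `EsA`, `EsB`.
#' @export
permutation_test_dES <- function(regulon, ranked, n_perm = 1000L,
                                 exponent = 1, seed = NULL) {
  obs <- two_tail_es(regulon, ranked, exponent)
  n_pos <- length(intersect(names(regulon$pos), ranked$gene))
  n_neg <- length(intersect(names(regulon$neg), ranked$gene))
  null <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      draw <- sample(ranked$gene, n_pos + n_neg)
      fake <- signed_regulon(regulon$tf,
                             pos = stats::setNames(rep(1, n_pos),
                                                   draw[seq_len(n_pos)]),
                             neg = stats::setNames(rep(1, n_neg),
                                                   draw[seq_len(n_neg) + n_pos]))
      suppressMessages(two_tail_es(fake, ranked, exponent)[["dES"]])
    }, numeric(1))
  })
  p <- (1 + sum(abs(null) >= abs(obs[["dES"]]))) / (1 + n_perm)
  list(p = p, dES = obs[["dES"]], EsA = obs[["EsA"]], EsB = obs[["EsB"]])
}

#' Two-tail GSEA across MR candidates and studies
#'
#' For each candidate TF and each study, computes the two-tail enrichment of
#' its regulon in the logFC-ranked phenotype with a gene-label permutation
#' p-value, BH-adjusts across TFs within the study, and classifies states.
#'
#' @param regulons a `regulon_set` restricted to the TFs of interest.
#' @param de_list named list of [moderated_t_test()] results.
#' @param n_perm permutations per test (default 1000).
#' @param alpha FDR threshold for state calls (default 0.05).
#' @param exponent GSEA weighting exponent.
#' @param seed integer seed (per-test seeds are derived deterministically).
#' @return data.frame of `two_tail_record`s: `tf`, `study_id`, `EsA`, `EsB`,
#'   `dES`, `p`, `p_adj`, `state`.
#' @export
run_two_tail_gsea <- function(regulons, de_list, n_perm = 1000L, alpha = 0.05,
                              exponent = 1, seed = NULL) {
  if (is.null(names(de_list))) names(de_list) <- paste0("study", seq_along(de_list))
  recs <- list()
  idx <- 0L
  for (sid in names(de_list)) {
    ranked <- rank_phenotype(de_list[[sid]])
    rows <- lapply(regulons, function(r) {
      idx <<- idx + 1L
      res <- permutation_test_dES(r, ranked, n_perm = n_perm,
                                  exponent = exponent,
                                  seed = if (is.null(seed)) NULL else
                                    derive_seed(seed, idx))
      data.frame(tf = r$tf, study_id = sid, EsA = res$EsA, EsB = res$EsB,
                 dES = res$dES, p = res$p, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df$p_adj <- bh_adjust(df$p)
    recs[[sid]] <- df
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  classify_state(out, alpha = alpha)
}

#' Classify regulon activation states
#'
#' `p_adj <= alpha` with `dES > 0` is activated, with `dES < 0` repressed;
#' anything else is `ns`. A significant record with `dES == 0` carries no
#' direction and is classified `ns` with a warning.
#'
#' @param records data.frame with columns `dES` and `p_adj`.
#' @param alpha FDR threshold (default 0.05).
#' @return `records` with a `state` column.
#' @export
classify_state <- function(records, alpha = 0.05) {
  state <- rep("ns", nrow(records))
  sig <- records$p_adj <= alpha
  state[sig & records$dES > 0] <- "activated"
  state[sig & records$dES < 0] <- "repressed"
  if (any(sig & records$dES == 0)) {
    warnf("significant record with dES == 0: state undirected, set to ns")
  }
  records$state <- state
  records
}

#' Consensus activation state across studies
#'
#' Majority direction among a TF's significant per-study calls; `ns` when no
#' study is significant or the directions tie.
#'
#' @param records classified records from [run_two_tail_gsea()].
#' @return data.frame per TF: `tf`, `n_activated`, `n_repressed`, `state`.
#' @export
consensus_state <- function(records) {
  tfs <- sort(unique(records$tf))
  out <- do.call(rbind, lapply(tfs, function(tf) {
    r <- records[records$tf == tf, ]
    na <- sum(r$state == "activated")
    nr <- sum(r$state == "repressed")
    state <- if (na > nr) "activated" else if (nr > na) "repressed" else "ns"
    data.frame(tf = tf, n_activated = na, n_repressed = nr, state = state,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
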