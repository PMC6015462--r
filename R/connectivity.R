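#' Build an up/down query signature from MR-candidate targets
#'
#' Selects MR candidates whose two-tail GSEA p-value (unadjusted, the
#' connectivity-map input tier) is at most `gsea_p_cutoff`, takes the union
#' of their regulon targets, keeps the ones differentially expressed in the
#' study (`p_adj < de_alpha`), and tags them by the logFC metric: positive
#' logFC genes become up tags, negative logFC genes down tags, each ordered
#' by decreasing `|logFC|` and truncated at `max_tags`.
#'
#' @param gsea_records classified two-tail records for one study.
#' @param regulons `regulon_set` holding the candidates' regulons.
#' @param de the study's [moderated_t_test()] result.
#' @param gsea_p_cutoff candidate filter on the GSEA p (default 0.01).
#' @param de_alpha DE filter on the adjusted p (default 0.05).
#' @param max_tags per-direction cap on the tag lists (default 1000).
#' @return `tag_signature`: list with `up_tags`, `down_tags` (ordered ids).
#' @export
build_query_signature <- function(gsea_records, regulons, de,
                                  gsea_p_cutoff = 0.01, de_alpha = 0.05,
                                  max_tags = 1000L) {
  qual <- unique(gsea_records$tf[gsea_records$p <= gsea_p_cutoff])
  qual <- intersect(qual, names(regulons))
  targets <- unique(unlist(lapply(regulons[qual], regulon_targets),
                           use.names = FALSE))
  de_sub <- de[de$gene %in% targets & de$p_adj < de_alpha & de$logFC != 0, ]
  if (length(qual) == 0L || nrow(de_sub) == 0L) {
    stopf("no query signature: no candidate at GSEA p <= %g with DE targets",
          gsea_p_cutoff)
  }
  de_sub <- de_sub[order(-abs(de_sub$logFC), de_sub$gene), ]
  up <- de_sub$gene[de_sub$logFC > 0]
  down <- de_sub$gene[de_sub$logFC < 0]
  tag_signature(up_tags = head(up, max_tags), down_tags = head(down, max_tags))
}

#' Construct a tag-list signature
#' @param up_tags,down_tags ordered, disjoint gene id vectors (combined
#'   length >= 2).
#' @return object of class `tag_signature`.
#' @export
tag_signature <- function(up_tags = character(0), down_tags = character(0)) {
  if (length(intersect(up_tags, down_tags)) > 0L) {
    stopf("up and down tag lists overlap")
  }
  if (length(up_tags) + length(down_tags) < 2L) {
    stopf("a query signature needs at least 2 tags")
  }
  structure(list(up_tags = up_tags, down_tags = down_tags),
            class = "tag_signature")
}

#' Kolmogorov-Smirnov tag score against an instance rank list
#'
#' With `V(j)` the ascending ranks of the `t` tags in the instance list of
#' length `n`: `a = max_j [j/t - V(j)/n]`, `b = max_j [V(j)/n - (j-1)/t]`;
#' the score is `a` when `a > b`, else `-b`. Positive scores mean the tags
#' sit near the top (up-regulated by the treatment), negative near the
#' bottom.
#'
#' @param tags character vector of gene ids (subset of the universe).
#' @param instance_ranks ordered character vector: the instance's rank list
#'   (rank 1 = most up-regulated).
#' @return the signed KS statistic.
#' @export
ks_tag_score <- function(tags, instance_ranks) {
  t_n <- length(tags)
  if (t_n < 1L) stopf("need at least one tag")
  V <- match(tags, instance_ranks)
  if (anyNA(V)) {
    stopf("tag '%s' absent from the instance universe", tags[which(is.na(V))[1L]])
  }
  V <- sort(V)
  n <- length(instance_ranks)
  j <- seq_len(t_n)
  a <- max(j / t_n - V / n)
  b <- max(V / n - (j - 1) / t_n)
  if (a > b) a else -b
}

#' Raw connectivity of a query signature with one instance
#'
#' `ks_up` and `ks_down` are the tag scores of the up and down lists; when
#' they share a sign the instance is incoherent and the raw score is 0,
#' otherwise the score is `ks_up - ks_down` (in `[-2, 2]`). Positive scores
#' mark instances that mimic the query signature, negative ones that
#' reverse it.
#'
#' @param query a `tag_signature`.
#' @param instance_ranks ordered gene id vector for one instance.
#' @return raw connectivity score.
#' @export
instance_connectivity <- function(query, instance_ranks) {
  ks_up <- if (length(query$up_tags) > 0L) {
    ks_tag_score(query$up_tags, instance_ranks)
  } else 0
  ks_down <- if (length(query$down_tags) > 0L) {
    ks_tag_score(query$down_tags, instance_ranks)
  } else 0
  if (sign(ks_up) == sign(ks_down)) 0 else ks_up - ks_down
}

#' Scale raw connectivity scores to \[-1, 1\]
#'
#' Positive raw scores are divided by the maximum positive score, negative
#' ones by the magnitude of the minimum, zeros stay zero — the extreme
#' instances anchor +1 and -1.
#'
#' @param raw numeric vector of raw instance scores.
#' @return scaled scores.
#' @export
scale_scores <- function(raw) {
  out <- raw
  pos <- raw > 0; neg <- raw < 0
  if (any(pos)) out[pos] <- raw[pos] / max(raw[pos])
  if (any(neg)) out[neg] <- raw[neg] / abs(min(raw[neg]))
  out
}

#' Score every instance of a signature database against a query
#'
#' @param db a `signature_db`.
#' @param query a `tag_signature`.
#' @return data.frame `instance_id`, `compound`, `cell_line`, `raw`,
#'   `score` (scaled).
#' @export
score_signature_db <- function(db, query) {
  raw <- vapply(seq_len(nrow(db$ranks)), function(i) {
    instance_connectivity(query, db$ranks[i, ])
  }, numeric(1))
  out <- db$instances
  out$raw <- raw
  out$score <- scale_scores(raw)
  out
}

#' Per-compound connectivity summary with permutation p-values
#'
#' Groups scaled instance scores by compound and reports the mean score. The
#' permutation null for a compound with m instances is the mean score of a
#' random m-instance subset of the study's instances, resampled `n_perm`
#' times; `p = (1 + #{|null mean| >= |mean|}) / (1 + n_perm)`. Null draws
#' are shared across compounds with the same instance count, keeping the
#' summary deterministic under the seed.
#'
#' @param scored data.frame from [score_signature_db()].
#' @param n_perm permutation count (default 10000).
#' @param alpha significance level used to set the direction flag
#'   (default 0.05).
#' @param study_id label carried into the records.
#' @param seed integer seed.
#' @return data.frame per compound: `compound`, `study_id`, `n_instances`,
#'   `mean_score`, `p`, `direction` (`negative`, `positive` or `ns`).
#' @export
compound_summary <- function(scored, n_perm = 10000L, alpha = 0.05,
                             study_id = "study", seed = NULL) {
  means <- tapply(scored$score, scored$compound, mean)
  sizes <- tapply(scored$score, scored$compound, length)
  compounds <- sort(names(means))
  all_scores <- scored$score
  p <- stats::setNames(numeric(length(compounds)), compounds)
  with_local_seed(seed, {
    for (m in sort(unique(sizes))) {
      null_means <- vapply(seq_len(n_perm), function(i) {
        mean(all_scores[sample.int(length(all_scores), m)])
      }, numeric(1))
      for (comp in compounds[sizes[compounds] == m]) {
        p[comp] <- (1 + sum(abs(null_means) >= abs(means[[comp]]))) /
          (1 + n_perm)
      }
    }
  })
  direction <- rep("ns", length(compounds))
  sig <- p[compounds] <= alpha
  direction[sig & means[compounds] < 0] <- "negative"
  direction[sig & means[compounds] > 0] <- "positive"
  data.frame(compound = compounds, study_id = study_id,
             n_instances = as.integer(sizes[compounds]),
             mean_score = as.numeric(means[compounds]),
             p = as.numeric(p[compounds]), direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-study consensus drugs
#'
#' A compound is a consensus drug when it is significant (`p <= p_cutoff`)
#' with the same direction in at least `min_studies` studies. Negative
#' consensus (signature reversal) nominates therapeutic candidates, positive
#' consensus disease mimetics. Compounds significant in opposite directions
#' in different studies are excluded with a message.
#'
#' @param records row-bound [compound_summary()] tables across studies.
#' @param p_cutoff per-study significance cutoff (default 0.05).
#' @param min_studies consensus requirement (default 2).
#' @return list with character vectors `therapeutic` and `mimetic`
#'   (disjoint), plus `excluded` (direction conflicts).
#' @export
consensus_drugs <- function(records, p_cutoff = 0.05, min_studies = 2L) {
  sig <- records[records$p <= p_cutoff & records$direction != "ns", ]
  therapeutic <- character(0); mimetic <- character(0); excluded <- character(0)
  for (comp in sort(unique(sig$compound))) {
    r <- sig[sig$compound == comp, ]
    n_neg <- sum(r$direction == "negative")
    n_pos <- sum(r$direction == "positive")
    if (n_neg > 0L && n_pos > 0L) {
      excluded <- c(excluded, comp)
      message(sprintf("compound %s significant in opposite directions: excluded",
                      comp))
    } else if (n_neg >= min_studies) {
      therapeutic <- c(therapeutic, comp)
    } else if (n_pos >= min_studies) {
      mimetic <- c(mimetic, comp)
    }
  }
  list(therapeutic = therapeutic, mimetic = mimetic, excluded = excluded)
}
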