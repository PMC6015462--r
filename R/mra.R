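#' Hypergeometric regulon-DE overlap test
#'
#' Upper-tail hypergeometric test of the overlap between one regulon's
#' targets and a study's differentially expressed genes:
#' `p = P(X >= k)` with population `N = |universe|`, successes
#' `K = |regulon ∩ universe|`, draws `n = |DE ∩ universe|` and observed
#' overlap `k = |regulon ∩ DE ∩ universe|`. Genes outside the universe are
#' intersected away (counted in a message).
#'
#' @param regulon_targets character vector of a regulon's target ids.
#' @param de_set character vector of DE gene ids.
#' @param universe character vector: the testable gene space.
#' @param tf,study_id labels carried into the record.
#' @return one-row data.frame: `tf`, `study_id`, `regulon_size`, `de_count`,
#'   `overlap`, `universe_size`, `p_hyper`.
#' @export
hypergeom_overlap_test <- function(regulon_targets, de_set, universe,
                                   tf = NA_character_,
                                   study_id = NA_character_) {
  if (length(universe) == 0L) stopf("empty universe")
  out_reg <- length(setdiff(regulon_targets, universe))
  out_de <- length(setdiff(de_set, universe))
  if (out_reg + out_de > 0L) {
    message(sprintf("%d regulon and %d DE gene(s) outside the universe dropped",
                    out_reg, out_de))
  }
  reg <- intersect(regulon_targets, universe)
  de <- intersect(de_set, universe)
  N <- length(universe); K <- length(reg); n <- length(de)
  k <- length(intersect(reg, de))
  p <- phyper(k - 1L, m = K, n = N - K, k = n, lower.tail = FALSE)
  data.frame(tf = tf, study_id = study_id, regulon_size = K, de_count = n,
             overlap = k, universe_size = N, p_hyper = p,
             stringsAsFactors = FALSE)
}

#' Master regulator analysis across studies
#'
#' One hypergeometric overlap test per TF per study, against that study's
#' DE gene set. Within each study the universe is the intersection of the
#' network's gene space (all regulon targets plus TFs) with the study's
#' measured genes, and p-values are BH-adjusted across TFs.
#'
#' @param regulons a `regulon_set` (already filtered to the MRA tier).
#' @param de_list named list of [moderated_t_test()] results, one per study.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param de_alpha FDR threshold defining each study's DE set (default 0.05).
#' @return data.frame of MRA records with `p_adj` and `significant` added.
#' @export
run_mra <- function(regulons, de_list, alpha = 0.05, de_alpha = 0.05) {
  if (length(regulons) == 0L) stopf("no regulons to test")
  if (is.null(names(de_list))) names(de_list) <- paste0("study", seq_along(de_list))
  net_genes <- unique(c(names(regulons),
                        unlist(lapply(regulons, regulon_targets),
                               use.names = FALSE)))
  recs <- list()
  for (sid in names(de_list)) {
    de <- de_list[[sid]]
    universe <- intersect(net_genes, de$gene)
    if (length(universe) < 0.5 * length(net_genes)) {
      warnf("study %s shares < 50%% of the network's gene space", sid)
    }
    de_set <- de_gene_set(de, alpha = de_alpha)
    study_recs <- do.call(rbind, lapply(regulons, function(r) {
      hypergeom_overlap_test(regulon_targets(r), de_set, universe,
                             tf = r$tf, study_id = sid)
    }))
    study_recs$p_adj <- bh_adjust(study_recs$p_hyper)
    study_recs$significant <- study_recs$p_adj < alpha
    recs[[sid]] <- study_recs
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Cross-study consensus master regulator candidates
#'
#' A TF is an MR candidate when its regulon is significantly enriched with
#' DE genes in at least `min_studies` studies.
#'
#' @param records data.frame from [run_mra()].
#' @param min_studies consensus requirement (default 3).
#' @return data.frame per TF: per-study flags, `n_significant_studies`,
#'   `is_candidate`.
#' @export
consensus_mr <- function(records, min_studies = 3L) {
  if (min_studies < 1L) stopf("min_studies must be >= 1")
  studies <- sort(unique(records$study_id))
  tfs <- sort(unique(records$tf))
  flags <- matrix(FALSE, nrow = length(tfs), ncol = length(studies),
                  dimnames = list(tfs, studies))
  flags[cbind(match(records$tf, tfs), match(records$study_id, studies))] <-
    records$significant
  n_sig <- rowSums(flags)
  out <- data.frame(tf = tfs, as.data.frame(flags),
                    n_significant_studies = as.integer(n_sig),
                    is_candidate = n_sig >= min_studies,
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  out
}
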