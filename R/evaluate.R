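#' Regulon recovery statistics against a ground truth
#'
#' Per-TF precision, recall and F1 of the inferred target sets against the
#' planted network, plus the mode-assignment accuracy over the correctly
#' recovered edges.
#'
#' @param truth a `ground_truth` network.
#' @param regulons an inferred `regulon_set`.
#' @return list with `per_tf` (data.frame `tf`, `n_true`, `n_inferred`,
#'   `tp`, `precision`, `recall`, `f1`), `f1_median`, and `mode_accuracy`
#'   (fraction of true recovered edges whose assigned mode matches truth).
#' @export
regulon_recovery_stats <- function(truth, regulons) {
  per_tf <- do.call(rbind, lapply(truth$tf_ids, function(tf) {
    true_t <- truth$regulons[[tf]]$target
    inf_t <- if (tf %in% names(regulons)) {
      regulon_targets(regulons[[tf]])
    } else character(0)
    tp <- length(intersect(true_t, inf_t))
    prec <- if (length(inf_t) == 0L) 0 else tp / length(inf_t)
    rec <- if (length(true_t) == 0L) 0 else tp / length(true_t)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(tf = tf, n_true = length(true_t), n_inferred = length(inf_t),
               tp = tp, precision = prec, recall = rec, f1 = f1,
               stringsAsFactors = FALSE)
  }))
  rownames(per_tf) <- NULL
  match_flags <- unlist(lapply(truth$tf_ids, function(tf) {
    if (!(tf %in% names(regulons))) return(logical(0))
    reg <- regulons[[tf]]
    inferred_mode <- c(stats::setNames(rep(1L, length(reg$pos)), names(reg$pos)),
                       stats::setNames(rep(-1L, length(reg$neg)), names(reg$neg)))
    tr <- truth$regulons[[tf]]
    true_mode <- stats::setNames(tr$mode, tr$target)
    common <- intersect(names(inferred_mode), names(true_mode))
    unname(inferred_mode[common] == true_mode[common])
  }))
  list(per_tf = per_tf,
       f1_median = median(per_tf$f1),
       mode_accuracy = if (length(match_flags) == 0L) NA_real_ else
         mean(match_flags))
}
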