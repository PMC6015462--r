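#' Jaccard coefficient of two sets
#'
#' @param set_a,set_b character vectors; at least one must be non-empty.
#' @return `|a ∩ b| / |a ∪ b|` in `[0, 1]`.
#' @export
jaccard <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0L) stopf("Jaccard undefined for two empty sets")
  length(intersect(set_a, set_b)) / u
}

#' Cross-MR subnetwork
#'
#' Weighted graph over the state-significant master regulators: edge weight
#' is the Jaccard coefficient of the two regulons' target sets, edges with
#' weight above `min_jaccard` are kept (the default keeps every nonzero
#' overlap), node degree is the incident edge count.
#'
#' @param regulons `regulon_set` of the MRs to connect (>= 2).
#' @param states optional named character vector, TF -> activation state,
#'   carried onto the node table.
#' @param min_jaccard edge inclusion threshold (edge kept when weight >
#'   `min_jaccard`; default 0).
#' @return `mr_subnetwork`: list with `nodes` (tf, size, state, degree),
#'   `edges` (tf_a, tf_b, jaccard), `mean_degree`, `sd_degree`.
#' @export
build_mr_subnetwork <- function(regulons, states = NULL, min_jaccard = 0) {
  tfs <- names(regulons)
  if (length(tfs) < 2L) stopf("need at least 2 MRs to build a subnetwork")
  pairs <- utils::combn(tfs, 2L)
  w <- apply(pairs, 2L, function(pr) {
    jaccard(regulon_targets(regulons[[pr[1L]]]),
            regulon_targets(regulons[[pr[2L]]]))
  })
  keep <- w > min_jaccard
  edges <- data.frame(tf_a = pairs[1L, keep], tf_b = pairs[2L, keep],
                      jaccard = w[keep], stringsAsFactors = FALSE,
                      row.names = NULL)
  degree <- stats::setNames(integer(length(tfs)), tfs)
  for (tf in tfs) degree[tf] <- sum(edges$tf_a == tf) + sum(edges$tf_b == tf)
  nodes <- data.frame(
    tf = tfs,
    size = vapply(regulons, regulon_size, integer(1)),
    state = if (is.null(states)) NA_character_ else unname(states[tfs]),
    degree = as.integer(degree),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(nodes = nodes, edges = edges,
                 mean_degree = mean(degree),
                 sd_degree = sd(degree)),
            class = "mr_subnetwork")
}

#' @export
print.mr_subnetwork <- function(x, ...) {
  cat(sprintf("<mr_subnetwork> %d nodes, %d edges, degree %.2f +/- %.2f\n",
              nrow(x$nodes), nrow(x$edges), x$mean_degree,
              ifelse(is.na(x$sd_degree), 0, x$sd_degree)))
  invisible(x)
}

#' Pipeline funnel summary
#'
#' Tier counts mirroring the analysis funnel: TFs tested, regulons passing
#' the reporting tier (> `reporting_min` targets), regulons in the MRA tier,
#' MR candidates, state-significant MRs, and consensus drug counts.
#'
#' @param all_regulons unfiltered `regulon_set`.
#' @param mra_regulons MRA-tier `regulon_set`.
#' @param candidates character vector of MR candidate TFs.
#' @param state_significant character vector of state-significant TFs.
#' @param drugs result of [consensus_drugs()].
#' @param reporting_min reporting-tier threshold (default 25, `>` rule).
#' @return named list of counts.
#' @export
funnel_summary <- function(all_regulons, mra_regulons, candidates,
                           state_significant, drugs, reporting_min = 25L) {
  list(
    n_tfs = length(all_regulons),
    n_reporting_tier = length(filter_regulons(all_regulons,
                                              min_targets = reporting_min,
                                              rule = "gt")),
    n_mra_tier = length(mra_regulons),
    n_mr_candidates = length(candidates),
    n_state_significant = length(state_significant),
    n_therapeutic = length(drugs$therapeutic),
    n_mimetic = length(drugs$mimetic)
  )
}
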