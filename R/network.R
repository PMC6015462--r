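#' Permutation-derived mutual information threshold
#'
#' Builds a pooled null distribution by drawing random TF-target pairs,
#' permuting the samples of one member, and recomputing MI; the threshold is
#' the empirical `1 - p_cutoff` quantile of that null. Interactions below the
#' threshold are treated as noise by [infer_raw_network()].
#'
#' @param expr genes x samples expression matrix (see [read_expression_matrix()]).
#' @param tf_list character vector of TF gene ids.
#' @param n_perm number of null draws (default 1000).
#' @param p_cutoff tail probability defining the threshold (default 0.001).
#' @param n_bins bins for the MI estimator; default [default_bins()].
#' @param seed integer seed; the null is deterministic given the seed.
#' @return numeric MI threshold (nats).
#' @export
permutation_threshold <- function(expr, tf_list, n_perm = 1000L,
                                  p_cutoff = 0.001, n_bins = NULL,
                                  seed = NULL) {
  expr <- validate_expression_matrix(expr)
  tf_list <- intersect(tf_list, rownames(expr))
  if (length(tf_list) == 0L) stopf("no TF ids present in the expression matrix")
  if (n_perm < 100L) warnf("n_perm < 100: threshold quantile is unstable")
  n <- ncol(expr)
  if (is.null(n_bins)) n_bins <- default_bins(n)
  targets <- rownames(expr)
  with_local_seed(seed, {
    tf_draw <- sample(tf_list, n_perm, replace = TRUE)
    tg_draw <- sample(targets, n_perm, replace = TRUE)
    null_mi <- vapply(seq_len(n_perm), function(i) {
      x <- expr[tf_draw[i], ]
      y <- expr[tg_draw[i], sample.int(n)]
      estimate_mi(x, y, n_bins)
    }, numeric(1))
    unname(quantile(null_mi, probs = 1 - p_cutoff, type = 1))
  })
}

#' Raw TF-target candidate network
#'
#' All TF x gene pairs (self pairs excluded) whose mutual information reaches
#' the threshold. TF-TF pairs are retained: the DPI pruning step needs them.
#'
#' @inheritParams permutation_threshold
#' @param threshold minimum MI (nats) for an edge.
#' @return data.frame with columns `tf`, `target`, `mi`.
#' @export
infer_raw_network <- function(expr, tf_list, threshold, n_bins = NULL) {
  expr <- validate_expression_matrix(expr)
  dropped <- setdiff(tf_list, rownames(expr))
  if (length(dropped) > 0L) {
    message(sprintf("dropping %d TF ids absent from the expression matrix",
                    length(dropped)))
  }
  tf_list <- intersect(tf_list, rownames(expr))
  if (length(tf_list) == 0L) stopf("empty TF list")
  if (is.null(n_bins)) n_bins <- default_bins(ncol(expr))
  mi <- mi_rows(expr[tf_list, , drop = FALSE], expr, n_bins)
  hits <- which(mi >= threshold, arr.ind = TRUE)
  edges <- data.frame(
    tf = tf_list[hits[, 1L]],
    target = rownames(expr)[hits[, 2L]],
    mi = mi[hits],
    stringsAsFactors = FALSE
  )
  edges <- edges[edges$tf != edges$target, , drop = FALSE]
  edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Bootstrap consensus network
#'
#' Resamples the cohort's samples with replacement `n_boot` times, recomputes
#' the raw network on every resample, and keeps edges whose support fraction
#' reaches `consensus`. With `consensus = 0` the result is the union of the
#' bootstrap networks. The `mi` column reports the full-data MI.
#'
#' Resampling with replacement duplicates sample pairs, which genuinely
#' inflates the MI of independent gene pairs (a duplicated `(x, y)` point is
#' real dependence in the resampled data), so a threshold calibrated on the
#' full cohort is too low inside a bootstrap. When `p_cutoff` is supplied,
#' each bootstrap therefore recalibrates its own null: `n_null` random
#' TF-target pairs are drawn, the target's samples are permuted in the
#' original sample space and only then resampled with the bootstrap's index
#' vector — preserving the duplicate structure — and the bootstrap's
#' effective threshold is the larger of `threshold` and the
#' `1 - p_cutoff` null quantile. With `p_cutoff = NULL` the fixed
#' `threshold` is used as-is.
#'
#' @inheritParams infer_raw_network
#' @param n_boot number of bootstrap resamples (default 100).
#' @param consensus minimum support fraction in (0, 1]; default 0.95.
#' @param p_cutoff tail probability for the per-bootstrap null recalibration
#'   (use the value that produced `threshold`); `NULL` disables it.
#' @param n_null null draws per bootstrap (default 1000).
#' @param seed integer seed.
#' @return data.frame with columns `tf`, `target`, `mi`, `bootstrap_support`.
#' @export
bootstrap_consensus <- function(expr, tf_list, threshold, n_boot = 100L,
                                consensus = 0.95, n_bins = NULL,
                                p_cutoff = NULL, n_null = 1000L,
                                seed = NULL) {
  expr <- validate_expression_matrix(expr)
  tf_list <- intersect(tf_list, rownames(expr))
  if (length(tf_list) == 0L) stopf("empty TF list")
  if (n_boot < 1L) stopf("n_boot must be >= 1")
  n <- ncol(expr)
  if (is.null(n_bins)) n_bins <- default_bins(n)
  counts <- matrix(0L, nrow = length(tf_list), ncol = nrow(expr),
                   dimnames = list(tf_list, rownames(expr)))
  with_local_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      thr_b <- threshold
      if (!is.null(p_cutoff)) {
        thr_b <- max(threshold,
                     boot_null_threshold(expr, tf_list, idx, n_null,
                                         p_cutoff, n_bins))
      }
      mi_b <- mi_rows(expr[tf_list, idx, drop = FALSE],
                      expr[, idx, drop = FALSE], n_bins)
      counts <- counts + (mi_b >= thr_b)
    }
  })
  support <- counts / n_boot
  keep <- which(support >= max(consensus, .Machine$double.eps) &
                  support > 0, arr.ind = TRUE)
  mi_full <- mi_rows(expr[tf_list, , drop = FALSE], expr, n_bins)
  edges <- data.frame(
    tf = tf_list[keep[, 1L]],
    target = rownames(expr)[keep[, 2L]],
    mi = mi_full[keep],
    bootstrap_support = support[keep],
    stringsAsFactors = FALSE
  )
  edges <- edges[edges$tf != edges$target, , drop = FALSE]
  edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

# Null MI quantile matching one bootstrap's duplicate structure: random
# TF-target pairs, the target permuted in original sample space, both then
# resampled with the bootstrap index vector. Uses the caller's RNG stream.
boot_null_threshold <- function(expr, tf_list, idx, n_null, p_cutoff, n_bins) {
  n <- ncol(expr)
  tf_draw <- sample(tf_list, n_null, replace = TRUE)
  tg_draw <- sample(rownames(expr), n_null, replace = TRUE)
  bins_a <- matrix(0L, nrow = n_null, ncol = n)
  bins_b <- matrix(0L, nrow = n_null, ncol = n)
  for (i in seq_len(n_null)) {
    bins_a[i, ] <- equalfreq_bins(expr[tf_draw[i], idx], n_bins)
    perm <- sample.int(n)
    bins_b[i, ] <- equalfreq_bins(expr[tg_draw[i], perm[idx]], n_bins)
  }
  null_mi <- .mi_pairs_binned(bins_a, bins_b, as.integer(n_bins))
  unname(quantile(null_mi, probs = 1 - p_cutoff, type = 1))
}

#' Data processing inequality pruning
#'
#' For every closed triplet (TF_i, TF_j, target_k) with edges (i,j), (j,k)
#' and (i,k) all present, the TF-target edge (i,k) is removed when
#' `mi(i,k) < (1 - tolerance) * min(mi(i,j), mi(j,k))` — the weakest edge of
#' a fully connected triplet is read as an indirect interaction. Removal is
#' decided against the pre-pruning edge set in a single pass, so the result
#' is order-independent; equality keeps the edge; only TF-target edges are
#' removable (TF-TF edges participate but survive).
#'
#' @param edges data.frame with columns `tf`, `target`, `mi`.
#' @param tf_list character vector of TF ids (distinguishes TF-TF edges).
#' @param tolerance DPI tolerance in `[0, 1]`; 0 is the strict ("null
#'   tolerance") rule.
#' @return the pruned subset of `edges`.
#' @export
apply_dpi <- function(edges, tf_list, tolerance = 0) {
  if (tolerance < 0) stopf("tolerance must be >= 0")
  if (nrow(edges) == 0L) return(edges)
  tfs <- intersect(tf_list, unique(c(edges$tf, edges$target)))
  genes <- sort(unique(c(edges$tf, edges$target)))
  # MI adjacency over the pre-pruning edge set (NA = edge absent); TF-TF
  # edges are symmetrised since the MI estimator is symmetric.
  A <- matrix(NA_real_, nrow = length(tfs), ncol = length(genes),
              dimnames = list(tfs, genes))
  in_tf <- edges$tf %in% tfs
  A[cbind(match(edges$tf[in_tf], tfs), match(edges$target[in_tf], genes))] <-
    edges$mi[in_tf]
  for (i in tfs) for (j in tfs) {
    if (!is.na(A[i, j]) && i != j) {
      A[j, i] <- if (is.na(A[j, i])) A[i, j] else max(A[j, i], A[i, j])
    }
  }
  removable <- !(genes %in% tfs)
  drop_key <- character(0)
  for (i in tfs) for (j in tfs) {
    if (i == j || is.na(A[i, j])) next
    bound <- (1 - tolerance) * pmin(A[i, j], A[j, ])
    bad <- which(!is.na(A[i, ]) & !is.na(A[j, ]) & removable &
                   A[i, ] < bound)
    if (length(bad) > 0L) {
      drop_key <- c(drop_key, paste(i, genes[bad], sep = "\r"))
    }
  }
  keep <- !(paste(edges$tf, edges$target, sep = "\r") %in% drop_key)
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign regulation modes and assemble signed regulons
#'
#' The mode of action of every TF-target edge is the sign of the Pearson
#' correlation between the two expression profiles in the reference cohort.
#' An exact zero correlation (a measure-zero event) is assigned the positive
#' mode with a warning so the output stays deterministic. TF-TF edges are
#' dropped at this stage: regulatory units are TF-to-target sets.
#'
#' @inheritParams apply_dpi
#' @param expr reference genes x samples matrix.
#' @return a `regulon_set`: named list of `signed_regulon` objects, each with
#'   elements `tf`, `pos` and `neg` (named numeric vectors of MI weights).
#' @export
assign_modes <- function(expr, edges, tf_list) {
  expr <- validate_expression_matrix(expr)
  edges <- edges[!(edges$target %in% tf_list), , drop = FALSE]
  genes <- unique(c(edges$tf, edges$target))
  zero_var <- genes[apply(expr[genes, , drop = FALSE], 1L, sd) == 0]
  if (length(zero_var) > 0L) {
    stopf("zero-variance expression for gene '%s'", zero_var[1L])
  }
  regs <- lapply(split(edges, edges$tf), function(df) {
    tf <- df$tf[1L]
    r <- as.vector(cor(expr[tf, ], t(expr[df$target, , drop = FALSE])))
    if (any(r == 0)) {
      warnf("Pearson r exactly 0 for %d edge(s) of %s: assigned positive mode",
            sum(r == 0), tf)
    }
    mode <- ifelse(r >= 0, 1L, -1L)
    w <- stats::setNames(df$mi, df$target)
    signed_regulon(tf, pos = w[mode == 1L], neg = w[mode == -1L])
  })
  structure(regs, class = "regulon_set")
}

#' Construct a signed regulon
#'
#' @param tf TF gene id.
#' @param pos,neg named numeric vectors: MI weights named by target id.
#' @return object of class `signed_regulon`.
#' @export
signed_regulon <- function(tf, pos = numeric(0), neg = numeric(0)) {
  if (length(pos) > 0L) pos <- pos[order(names(pos))]
  if (length(neg) > 0L) neg <- neg[order(names(neg))]
  if (length(intersect(names(pos), names(neg))) > 0L) {
    stopf("positive and negative target sets of %s overlap", tf)
  }
  structure(list(tf = tf, pos = pos, neg = neg), class = "signed_regulon")
}

#' @export
print.signed_regulon <- function(x, ...) {
  cat(sprintf("<signed_regulon> %s: %d positive, %d negative targets\n",
              x$tf, length(x$pos), length(x$neg)))
  invisible(x)
}

#' Regulon size
#' @param regulon a `signed_regulon`.
#' @return number of targets across both modes.
#' @export
regulon_size <- function(regulon) length(regulon$pos) + length(regulon$neg)

#' Targets of a regulon
#' @param regulon a `signed_regulon`.
#' @return character vector of target ids (both modes).
#' @export
regulon_targets <- function(regulon) c(names(regulon$pos), names(regulon$neg))

#' Filter regulons by size
#'
#' The reporting tier keeps regulons with strictly more than `min_targets`
#' targets (`rule = "gt"`, 25 by default in the reporting funnel); the MRA
#' tier keeps regulons with at least `min_targets` targets (`rule = "geq"`,
#' 100 by default). Both thresholds are configurable.
#'
#' @param regulons a `regulon_set`.
#' @param min_targets size threshold.
#' @param rule `"geq"` (size >= min_targets) or `"gt"` (size > min_targets).
#' @return the filtered `regulon_set`.
#' @export
filter_regulons <- function(regulons, min_targets = 100L,
                            rule = c("geq", "gt")) {
  rule <- match.arg(rule)
  sizes <- vapply(regulons, regulon_size, integer(1))
  keep <- if (rule == "geq") sizes >= min_targets else sizes > min_targets
  structure(regulons[keep], class = "regulon_set")
}

#' Infer a signed TF-centered network from a reference cohort
#'
#' End-to-end network inference: permutation MI threshold, raw network,
#' bootstrap consensus, DPI pruning, Pearson mode assignment and regulon-size
#' filtering. Stage-wise edge counts are logged via `message()`.
#'
#' @inheritParams bootstrap_consensus
#' @param dpi_tolerance DPI tolerance (default 0, the strict rule).
#' @param min_targets MRA-tier regulon size floor (default 100, `>=` rule).
#' @return list with elements `regulons` (`regulon_set`, size-filtered),
#'   `all_regulons` (unfiltered), `edges` (post-DPI edge table) and
#'   `provenance` (every parameter, including the seed).
#' @export
infer_network <- function(expr, tf_list, n_perm = 1000L, n_boot = 100L,
                          p_cutoff = 0.001, consensus = 0.95,
                          dpi_tolerance = 0, n_bins = NULL,
                          min_targets = 100L, seed = NULL) {
  expr <- validate_expression_matrix(expr)
  if (is.null(n_bins)) n_bins <- default_bins(ncol(expr))
  thr <- permutation_threshold(expr, tf_list, n_perm = n_perm,
                               p_cutoff = p_cutoff, n_bins = n_bins,
                               seed = if (is.null(seed)) NULL else derive_seed(seed, 1L))
  message(sprintf("MI threshold (p <= %g): %.4f nats", p_cutoff, thr))
  boot <- bootstrap_consensus(expr, tf_list, thr, n_boot = n_boot,
                              consensus = consensus, n_bins = n_bins,
                              p_cutoff = p_cutoff,
                              seed = if (is.null(seed)) NULL else derive_seed(seed, 2L))
  message(sprintf("bootstrap consensus edges: %d", nrow(boot)))
  pruned <- apply_dpi(boot, tf_list, tolerance = dpi_tolerance)
  message(sprintf("post-DPI edges: %d", nrow(pruned)))
  regulons <- assign_modes(expr, pruned, tf_list)
  filtered <- filter_regulons(regulons, min_targets = min_targets, rule = "geq")
  message(sprintf("regulons: %d inferred, %d with >= %d targets",
                  length(regulons), length(filtered), min_targets))
  list(
    regulons = filtered,
    all_regulons = regulons,
    edges = pruned,
    provenance = list(
      n_perm = n_perm, n_boot = n_boot, p_cutoff = p_cutoff,
      consensus = consensus, dpi_tolerance = dpi_tolerance,
      n_bins = n_bins, min_targets = min_targets, seed = seed,
      threshold = thr
    )
  )
}
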