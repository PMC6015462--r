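#' Equal-frequency bin assignments
#'
#' Rank-based discretisation used by the mutual information estimator. Ties
#' are broken by original position ("first") so the assignment is fully
#' deterministic and invariant to strictly monotone transforms.
#'
#' @param x numeric vector.
#' @param n_bins number of bins (>= 2).
#' @return integer vector of bin indices in `1:n_bins`.
#' @keywords internal
equalfreq_bins <- function(x, n_bins) {
  n <- length(x)
  as.integer(ceiling(rank(x, ties.method = "first") * n_bins / n))
}

#' Default bin count for the MI estimator
#'
#' Cochran-style rule for the joint histogram: enough bins to resolve the
#' dependence structure while keeping the expected count per joint cell at
#' or above 5, i.e. `max(2, floor(sqrt(n / 5)))`. Bounding the expected cell
#' count bounds the plug-in estimator's bias, `(B - 1)^2 / (2n)` nats, which
#' otherwise swamps weak dependence signals.
#'
#' @param n sample count.
#' @return integer bin count.
#' @export
default_bins <- function(n) max(2L, as.integer(floor(sqrt(n / 5))))

#' Mutual information between two expression profiles
#'
#' Plug-in mutual information (in nats) on the joint histogram of
#' equal-frequency (rank) binned vectors:
#' \deqn{I = \sum_{ij} p_{ij} \log\left(p_{ij} / (p_i q_j)\right).}
#' Rank binning makes the estimate symmetric in its arguments and invariant
#' to strictly monotone transforms of either vector.
#'
#' @param x,y numeric vectors of equal length.
#' @param n_bins number of bins per margin; default [default_bins()].
#' @return non-negative mutual information in nats. A constant vector carries
#'   no rank structure: the function returns 0 with a warning.
#' @export
#' @examples
#' estimate_mi(1:4, 1:4, n_bins = 2)  # = log(2)
estimate_mi <- function(x, y, n_bins = default_bins(length(x))) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n_bins < 2) stopf("n_bins must be >= 2")
  if (n < 2 * n_bins) stopf("need at least 2*n_bins samples (%d < %d)", n, 2L * n_bins)
  if (anyNA(x) || anyNA(y)) stopf("missing values in input")
  if (sd(x) == 0 || sd(y) == 0) {
    warnf("constant vector: no rank structure, MI set to 0")
    return(0)
  }
  bx <- equalfreq_bins(x, n_bins)
  by <- equalfreq_bins(y, n_bins)
  joint <- tabulate(bx + n_bins * (by - 1L), nbins = n_bins * n_bins) / n
  px <- tabulate(bx, nbins = n_bins) / n
  qy <- tabulate(by, nbins = n_bins) / n
  pq <- as.vector(outer(px, qy))
  keep <- joint > 0
  max(0, sum(joint[keep] * log(joint[keep] / pq[keep])))
}

# Bulk MI between rows of `a` and rows of `b` (numeric matrices, samples in
# columns), through the C++ joint-histogram kernel.
mi_rows <- function(a, b, n_bins) {
  bins_a <- t(apply(a, 1L, equalfreq_bins, n_bins = n_bins))
  bins_b <- t(apply(b, 1L, equalfreq_bins, n_bins = n_bins))
  if (nrow(a) == 1L) bins_a <- matrix(bins_a, nrow = 1L)
  if (nrow(b) == 1L) bins_b <- matrix(bins_b, nrow = 1L)
  out <- .mi_matrix_binned(bins_a, bins_b, as.integer(n_bins))
  dimnames(out) <- list(rownames(a), rownames(b))
  out
}
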