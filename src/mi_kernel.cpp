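#include <Rcpp.h>
using namespace Rcpp;

// Mutual information (nats) between every row of binsA and every row of
// binsB, where the inputs hold equal-frequency bin assignments in 1..n_bins.
// The plug-in estimate sum_ij p_ij * log(p_ij / (p_i * q_j)) is computed from
// the joint histogram of each pair of rows.
// Row-wise paired MI: out[i] = MI(binsA[i, ], binsB[i, ]).
// [[Rcpp::export(name = ".mi_pairs_binned")]]
NumericVector mi_pairs_binned(IntegerMatrix binsA, IntegerMatrix binsB,
                              int n_bins) {
  const int m = binsA.nrow(), n = binsA.ncol();
  if (binsB.nrow() != m || binsB.ncol() != n) stop("dimension mismatch");
  NumericVector out(m);
  std::vector<int> joint(n_bins * n_bins);
  std::vector<int> margA(n_bins), margB(n_bins);
  const double ln_n = std::log((double)n);
  for (int i = 0; i < m; ++i) {
    std::fill(joint.begin(), joint.end(), 0);
    std::fill(margA.begin(), margA.end(), 0);
    std::fill(margB.begin(), margB.end(), 0);
    for (int s = 0; s < n; ++s) {
      int a = binsA(i, s) - 1, b = binsB(i, s) - 1;
      joint[a * n_bins + b]++;
      margA[a]++;
      margB[b]++;
    }
    double mi = 0.0;
    for (int a = 0; a < n_bins; ++a) {
      if (margA[a] == 0) continue;
      for (int b = 0; b < n_bins; ++b) {
        int c = joint[a * n_bins + b];
        if (c == 0 || margB[b] == 0) continue;
        mi += (double)c / n *
              (std::log((double)c) + ln_n - std::log((double)margA[a]) -
               std::log((double)margB[b]));
      }
    }
    out[i] = mi < 0 ? 0.0 : mi;
  }
  return out;
}

// [[Rcpp::export(name = ".mi_matrix_binned")]]
NumericMatrix mi_matrix_binned(IntegerMatrix binsA, IntegerMatrix binsB,
                               int n_bins) {
  const int na = binsA.nrow(), nb = binsB.nrow(), n = binsA.ncol();
  if (binsB.ncol() != n) stop("sample dimension mismatch");
  NumericMatrix out(na, nb);
  std::vector<int> joint(n_bins * n_bins);
  std::vector<int> margA(n_bins), margB(n_bins);
  const double ln_n = std::log((double)n);
  for (int i = 0; i < na; ++i) {
    std::fill(margA.begin(), margA.end(), 0);
    for (int s = 0; s < n; ++s) margA[binsA(i, s) - 1]++;
    for (int j = 0; j < nb; ++j) {
      std::fill(joint.begin(), joint.end(), 0);
      std::fill(margB.begin(), margB.end(), 0);
      for (int s = 0; s < n; ++s) {
        int a = binsA(i, s) - 1, b = binsB(j, s) - 1;
        joint[a * n_bins + b]++;
        margB[b]++;
      }
      double mi = 0.0;
      for (int a = 0; a < n_bins; ++a) {
        if (margA[a] == 0) continue;
        for (int b = 0; b < n_bins; ++b) {
          int c = joint[a * n_bins + b];
          if (c == 0 || margB[b] == 0) continue;
          // c/n * log( (c*n) / (margA*margB) )
          mi += (double)c / n *
                (std::log((double)c) + ln_n - std::log((double)margA[a]) -
                 std::log((double)margB[b]));
        }
      }
      out(i, j) = mi < 0 ? 0.0 : mi;
    }
  }
  return out;
}
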