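#include <Rcpp.h>
using namespace Rcpp;

// Greedy farthest point sampling. Maintains one running array of squared
// min-distances to the chosen set: O(nk) time, O(n) extra memory. Ties on
// the maximum are broken toward the lowest index (strict > while scanning
// in ascending order).
// [[Rcpp::export]]
IntegerVector fps_cpp(NumericMatrix X, int k, int start) {
  const int n = X.nrow(), d = X.ncol();
  if (k < 1 || k > n) stop("k must be in 1..n");
  if (start < 1 || start > n) stop("start index out of range");
  std::vector<double> mind(n, R_PosInf);
  IntegerVector chosen(k);
  int last = start - 1;
  chosen[0] = last + 1;
  for (int step = 1; step < k; ++step) {
    double best = -1.0;
    int best_i = -1;
    for (int i = 0; i < n; ++i) {
      double dist = 0.0;
      for (int j = 0; j < d; ++j) {
        const double diff = X(i, j) - X(last, j);
        dist += diff * diff;
      }
      if (dist < mind[i]) mind[i] = dist;
      if (mind[i] > best) {
        best = mind[i];
        best_i = i;
      }
    }
    if (best <= 0.0)
      stop("fewer than k distinct points in the data");
    chosen[step] = best_i + 1;
    last = best_i;
  }
  return chosen;
}

// Nearest-representative (Voronoi) assignment with ties broken toward the
// lowest representative index.
// [[Rcpp::export]]
IntegerVector assign_cpp(NumericMatrix X, NumericMatrix R) {
  const int n = X.nrow(), d = X.ncol(), K = R.nrow();
  if (R.ncol() != d) stop("dimension mismatch between points and representatives");
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int best_k = 0;
    for (int k = 0; k < K; ++k) {
      double dist = 0.0;
      for (int j = 0; j < d; ++j) {
        const double diff = X(i, j) - R(k, j);
        dist += diff * diff;
      }
      if (dist < best) {
        best = dist;
        best_k = k;
      }
    }
    out[i] = best_k + 1;
  }
  return out;
}

// Euclidean distance from each point to its nearest representative.
// [[Rcpp::export]]
NumericVector nearest_dist_cpp(NumericMatrix X, NumericMatrix R) {
  const int n = X.nrow(), d = X.ncol(), K = R.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int k = 0; k < K; ++k) {
      double dist = 0.0;
      for (int j = 0; j < d; ++j) {
        const double diff = X(i, j) - R(k, j);
        dist += diff * diff;
      }
      if (dist < best) best = dist;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
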