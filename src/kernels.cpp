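#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Full Euclidean distance matrix via the Gram-matrix identity.
// Clamps tiny negative values produced by cancellation before sqrt.
// [[Rcpp::export]]
arma::mat cpp_pairwise_dist(const arma::mat& X) {
  arma::vec sq = arma::sum(arma::square(X), 1);
  arma::mat D = -2.0 * (X * X.t());
  D.each_col() += sq;
  D.each_row() += sq.t();
  D.diag().zeros();
  D.transform([](double v) { return v > 0.0 ? std::sqrt(v) : 0.0; });
  return D;
}

// Exact k nearest neighbours from a precomputed distance matrix.
// Self is excluded; ties in distance are broken by ascending point index.
// Returns a list with 1-based index matrix (n x k) and distances (n x k).
// [[Rcpp::export]]
List cpp_knn_from_dist(const arma::mat& D, const int k) {
  const int n = D.n_rows;
  IntegerMatrix idx(n, k);
  NumericMatrix dst(n, k);
  std::vector<std::pair<double, int> > cand(n - 1);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      cand[m++] = std::make_pair(D(i, j), j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int q = 0; q < k; ++q) {
      idx(i, q) = cand[q].second + 1;
      dst(i, q) = cand[q].first;
    }
  }
  return List::create(_["indices"] = idx, _["dists"] = dst);
}

// Minimum spanning tree of the complete mutual-reachability graph:
// w(i, j) = max(D(i, j), core[i], core[j]).  Prim's algorithm, O(n^2).
// Returns (n - 1) x 3 matrix: from, to (1-based), weight; edges in insertion order.
// [[Rcpp::export]]
arma::mat cpp_mst_mutual_reachability(const arma::mat& D, const arma::vec& core) {
  const int n = D.n_rows;
  std::vector<bool> in_tree(n, false);
  std::vector<double> best(n, std::numeric_limits<double>::infinity());
  std::vector<int> parent(n, -1);
  arma::mat edges(n - 1, 3);
  in_tree[0] = true;
  for (int j = 1; j < n; ++j) {
    best[j] = std::max(D(0, j), std::max(core[0], core[j]));
    parent[j] = 0;
  }
  for (int e = 0; e < n - 1; ++e) {
    int v = -1;
    double bw = std::numeric_limits<double>::infinity();
    for (int j = 0; j < n; ++j) {
      if (!in_tree[j] && best[j] < bw) { bw = best[j]; v = j; }
    }
    in_tree[v] = true;
    edges(e, 0) = parent[v] + 1;
    edges(e, 1) = v + 1;
    edges(e, 2) = best[v];
    for (int j = 0; j < n; ++j) {
      if (in_tree[j]) continue;
      double w = std::max(D(v, j), std::max(core[v], core[j]));
      if (w < best[j]) { best[j] = w; parent[j] = v; }
    }
  }
  return edges;
}
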