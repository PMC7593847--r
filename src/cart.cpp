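#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Binary classification trees for Monte-Carlo feature selection.
// Splits maximise information gain (bits); trees are grown until nodes are
// pure or no admissible split leaves >= min_leaf samples in each child.
// Node bookkeeping (IG, samples reaching the node) feeds the relative
// importance aggregation done in R.

namespace {

double entropy_bits(const std::vector<int>& cnt, int n) {
  if (n == 0) return 0.0;
  double h = 0.0;
  for (size_t i = 0; i < cnt.size(); ++i) {
    if (cnt[i] > 0) {
      double p = static_cast<double>(cnt[i]) / n;
      h -= p * std::log2(p);
    }
  }
  return h;
}

struct Node {
  int feature;      // column index (0-based), -1 for leaf
  double threshold; // x <= threshold goes left
  int left, right;  // node indices, -1 for leaf
  int pred;         // majority class at the node
  double ig;        // information gain of the split (bits), 0 for leaf
  int n_node;       // training samples reaching the node
};

struct Grower {
  const NumericMatrix& X;
  const IntegerVector& y;
  int n_class;
  int min_leaf;
  std::vector<Node> nodes;

  Grower(const NumericMatrix& X_, const IntegerVector& y_, int nc, int ml)
      : X(X_), y(y_), n_class(nc), min_leaf(ml) {}

  int grow(std::vector<int>& idx) {
    int m = static_cast<int>(idx.size());
    std::vector<int> cnt(n_class, 0);
    for (int i = 0; i < m; ++i) cnt[y[idx[i]]]++;
    int pred = 0;
    for (int c = 1; c < n_class; ++c)
      if (cnt[c] > cnt[pred]) pred = c; // ties keep the lower class index
    double h_parent = entropy_bits(cnt, m);

    int me = static_cast<int>(nodes.size());
    nodes.push_back({-1, 0.0, -1, -1, pred, 0.0, m});

    if (h_parent <= 0.0 || m < 2 * min_leaf) return me;

    int best_f = -1, best_cut = -1;
    double best_ig = 1e-12, best_thr = 0.0;
    int p = X.ncol();
    std::vector<int> ord(m);
    std::vector<int> lcnt(n_class);

    for (int f = 0; f < p; ++f) {
      for (int i = 0; i < m; ++i) ord[i] = idx[i];
      std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
      std::fill(lcnt.begin(), lcnt.end(), 0);
      for (int i = 0; i < m - 1; ++i) {
        lcnt[y[ord[i]]]++;
        if (X(ord[i], f) >= X(ord[i + 1], f)) continue; // not a boundary
        int nl = i + 1, nr = m - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        std::vector<int> rcnt(n_class);
        for (int c = 0; c < n_class; ++c) rcnt[c] = cnt[c] - lcnt[c];
        double ig = h_parent -
                    (nl * entropy_bits(lcnt, nl) + nr * entropy_bits(rcnt, nr)) / m;
        if (ig > best_ig) { // first strictly-better split wins: deterministic
          best_ig = ig;
          best_f = f;
          best_cut = i;
          best_thr = 0.5 * (X(ord[i], f) + X(ord[i + 1], f));
        }
      }
    }

    if (best_f < 0) return me; // no admissible split: impure leaf

    std::vector<int> li, ri;
    li.reserve(m);
    ri.reserve(m);
    for (int i = 0; i < m; ++i) {
      if (X(idx[i], best_f) <= best_thr) li.push_back(idx[i]);
      else ri.push_back(idx[i]);
    }
    nodes[me].feature = best_f;
    nodes[me].threshold = best_thr;
    nodes[me].ig = best_ig;
    int l = grow(li);
    int r = grow(ri);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }
};

} // namespace

// [[Rcpp::export]]
List cart_grow(NumericMatrix X, IntegerVector y, int n_class, int min_leaf) {
  int n = X.nrow();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  for (int i = 0; i < n; ++i)
    if (y[i] < 0 || y[i] >= n_class) stop("class labels out of range");
  Grower g(X, y, n_class, min_leaf);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  g.grow(idx);

  int k = static_cast<int>(g.nodes.size());
  IntegerVector feature(k), left(k), right(k), pred(k), n_node(k);
  NumericVector threshold(k), ig(k);
  for (int i = 0; i < k; ++i) {
    const Node& nd = g.nodes[i];
    feature[i] = nd.feature;
    threshold[i] = nd.threshold;
    left[i] = nd.left;
    right[i] = nd.right;
    pred[i] = nd.pred;
    ig[i] = nd.ig;
    n_node[i] = nd.n_node;
  }
  return List::create(
      _["feature"] = feature, _["threshold"] = threshold, _["left"] = left,
      _["right"] = right, _["pred"] = pred, _["ig"] = ig, _["n_node"] = n_node,
      _["n_tree"] = n);
}

// [[Rcpp::export]]
IntegerVector cart_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"], pred = tree["pred"];
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    }
    out[i] = pred[node];
  }
  return out;
}
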