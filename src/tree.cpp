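#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Entropy (base 2) of a class-count vector summing to n.
static double entropy_counts(const std::vector<int>& cnt, int n) {
  if (n <= 0) return 0.0;
  double h = 0.0;
  for (size_t k = 0; k < cnt.size(); ++k) {
    if (cnt[k] > 0) {
      double p = static_cast<double>(cnt[k]) / n;
      h -= p * std::log2(p);
    }
  }
  return h;
}

struct TreeAcc {
  std::vector<int> feat;     // 1-based feature index per internal node
  std::vector<double> gain;  // information gain of the node's split
  std::vector<int> nnode;    // samples reaching the node
};

// Recursive induction. idx: training rows in this node; tidx: test rows routed
// here. Leaves assign the majority class (ties -> smallest class index).
static void grow(const NumericMatrix& X, const IntegerVector& y, int K,
                 const NumericMatrix& Xt, IntegerVector& pred,
                 std::vector<int>& idx, std::vector<int>& tidx,
                 int min_split, TreeAcc& acc) {
  const int n = static_cast<int>(idx.size());
  std::vector<int> cnt(K, 0);
  for (int i : idx) cnt[y[i]]++;

  int maj = 0;
  for (int k = 1; k < K; ++k) if (cnt[k] > cnt[maj]) maj = k;
  bool pure = (cnt[maj] == n);

  if (pure || n < min_split) {
    for (int t : tidx) pred[t] = maj;
    return;
  }

  const double h_parent = entropy_counts(cnt, n);
  int best_feat = -1;
  double best_gain = 0.0, best_thr = 0.0;

  std::vector<int> ord(idx);
  std::vector<int> lcnt(K);
  for (int j = 0; j < X.ncol(); ++j) {
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return X(a, j) < X(b, j);
    });
    std::fill(lcnt.begin(), lcnt.end(), 0);
    for (int i = 0; i < n - 1; ++i) {
      lcnt[y[ord[i]]]++;
      double v0 = X(ord[i], j), v1 = X(ord[i + 1], j);
      if (v1 <= v0) continue;  // only split between distinct values
      int nl = i + 1, nr = n - nl;
      std::vector<int> rcnt(K);
      for (int k = 0; k < K; ++k) rcnt[k] = cnt[k] - lcnt[k];
      double g = h_parent
        - (static_cast<double>(nl) / n) * entropy_counts(lcnt, nl)
        - (static_cast<double>(nr) / n) * entropy_counts(rcnt, nr);
      if (g > best_gain + 1e-12) {  // strict: ties keep lowest feature index
        best_gain = g;
        best_feat = j;
        best_thr = v0 + (v1 - v0) / 2.0;
      }
    }
  }

  if (best_feat < 0 || best_gain <= 0.0) {
    for (int t : tidx) pred[t] = maj;
    return;
  }

  acc.feat.push_back(best_feat + 1);
  acc.gain.push_back(best_gain);
  acc.nnode.push_back(n);

  std::vector<int> li, ri, lt, rt;
  for (int i : idx) (X(i, best_feat) <= best_thr ? li : ri).push_back(i);
  for (int t : tidx) (Xt(t, best_feat) <= best_thr ? lt : rt).push_back(t);
  grow(X, y, K, Xt, pred, li, lt, min_split, acc);
  grow(X, y, K, Xt, pred, ri, rt, min_split, acc);
}

// Fit one entropy-criterion classification tree and route test samples.
//
// X: training samples x features; y: 0-based integer classes; K: class count;
// Xt: test samples x features (same columns). Returns per-internal-node
// records (1-based feature index, information gain, node sample count) and
// 0-based predicted classes for the rows of Xt.
// [[Rcpp::export(name = ".fit_entropy_tree")]]
List fit_entropy_tree(NumericMatrix X, IntegerVector y, int K,
                      NumericMatrix Xt, int min_split = 2) {
  if (X.nrow() != y.size()) stop("X rows and y length differ");
  if (Xt.ncol() != X.ncol()) stop("train and test feature counts differ");
  TreeAcc acc;
  IntegerVector pred(Xt.nrow());
  std::vector<int> idx(X.nrow()), tidx(Xt.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  for (int i = 0; i < Xt.nrow(); ++i) tidx[i] = i;
  grow(X, y, K, Xt, pred, idx, tidx, min_split, acc);
  return List::create(
    _["feature"] = wrap(acc.feat),
    _["gain"] = wrap(acc.gain),
    _["n_node"] = wrap(acc.nnode),
    _["pred"] = pred);
}
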