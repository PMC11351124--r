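// Bagged random forest of CART trees for binary classification.
// Gini or entropy split quality, mtry feature subsampling, bootstrap
// resampling from an explicitly seeded mt19937 stream (deterministic for a
// given seed). Trees are returned as flat node tables so they can be
// serialised to plain text by the model store.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

struct TreeNodes {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= thr
  std::vector<int> left, right;  // child node ids, -1 for leaf
  std::vector<double> value;     // P(class 1) at node
};

static double impurity(double p, int criterion) {
  if (criterion == 0) return 2.0 * p * (1.0 - p); // gini
  if (p <= 0.0 || p >= 1.0) return 0.0;           // entropy
  return -(p * std::log2(p) + (1.0 - p) * std::log2(1.0 - p));
}

static int build_node(const NumericMatrix& X, const IntegerVector& y,
                      std::vector<int>& idx, int lo, int hi, int mtry,
                      int criterion, int min_node, TreeNodes& T,
                      std::mt19937& rng, int depth) {
  const int n = hi - lo;
  int pos = 0;
  for (int t = lo; t < hi; ++t) pos += y[idx[t]];
  const double p = (double)pos / n;

  const int node = (int)T.feature.size();
  T.feature.push_back(-1);
  T.threshold.push_back(0.0);
  T.left.push_back(-1);
  T.right.push_back(-1);
  T.value.push_back(p);

  if (n < 2 * min_node || pos == 0 || pos == n || depth > 64) return node;

  const int d = X.ncol();
  // sample mtry distinct features
  std::vector<int> feats(d);
  for (int k = 0; k < d; ++k) feats[k] = k;
  for (int k = 0; k < mtry; ++k) {
    std::uniform_int_distribution<int> U(k, d - 1);
    std::swap(feats[k], feats[U(rng)]);
  }

  const double imp0 = impurity(p, criterion);
  int best_f = -1;
  double best_gain = 1e-12, best_thr = 0.0;

  std::vector<std::pair<double, int> > vals(n);
  for (int k = 0; k < mtry; ++k) {
    const int f = feats[k];
    for (int t = 0; t < n; ++t) {
      const int i = idx[lo + t];
      vals[t] = std::make_pair(X(i, f), y[i]);
    }
    std::sort(vals.begin(), vals.end());
    int lpos = 0;
    for (int t = 0; t < n - 1; ++t) {
      lpos += vals[t].second;
      if (vals[t + 1].first <= vals[t].first) continue; // not a cut point
      const int nl = t + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      const double pl = (double)lpos / nl, pr = (double)(pos - lpos) / nr;
      const double gain = imp0 - ((double)nl / n) * impurity(pl, criterion)
                               - ((double)nr / n) * impurity(pr, criterion);
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = (vals[t].first + vals[t + 1].first) / 2.0;
      }
    }
  }
  if (best_f < 0) return node;

  // partition idx[lo, hi) on the chosen split (stable to keep determinism)
  std::vector<int> lpart, rpart;
  lpart.reserve(n); rpart.reserve(n);
  for (int t = lo; t < hi; ++t) {
    if (X(idx[t], best_f) <= best_thr) lpart.push_back(idx[t]);
    else rpart.push_back(idx[t]);
  }
  std::copy(lpart.begin(), lpart.end(), idx.begin() + lo);
  std::copy(rpart.begin(), rpart.end(), idx.begin() + lo + lpart.size());

  T.feature[node] = best_f;
  T.threshold[node] = best_thr;
  const int mid = lo + (int)lpart.size();
  T.left[node] = build_node(X, y, idx, lo, mid, mtry, criterion, min_node,
                            T, rng, depth + 1);
  T.right[node] = build_node(X, y, idx, mid, hi, mtry, criterion, min_node,
                             T, rng, depth + 1);
  return node;
}

// [[Rcpp::export(name = ".rf_train")]]
List rf_train(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
              int criterion, int min_node, int seed) {
  const int n = X.nrow();
  if (y.size() != n) stop("label/feature length mismatch");
  if (mtry < 1 || mtry > X.ncol()) stop("invalid mtry");
  std::mt19937 rng((uint32_t)seed);
  std::uniform_int_distribution<int> boot(0, n - 1);

  List trees(n_trees);
  for (int b = 0; b < n_trees; ++b) {
    std::vector<int> idx(n);
    for (int t = 0; t < n; ++t) idx[t] = boot(rng);
    TreeNodes T;
    build_node(X, y, idx, 0, n, mtry, criterion, min_node, T, rng, 0);
    trees[b] = List::create(
      _["feature"] = IntegerVector(T.feature.begin(), T.feature.end()),
      _["threshold"] = NumericVector(T.threshold.begin(), T.threshold.end()),
      _["left"] = IntegerVector(T.left.begin(), T.left.end()),
      _["right"] = IntegerVector(T.right.begin(), T.right.end()),
      _["value"] = NumericVector(T.value.begin(), T.value.end()));
  }
  return trees;
}

// mean over trees of the leaf P(class 1) -> decision value in [0, 1]
// [[Rcpp::export(name = ".rf_predict")]]
NumericVector rf_predict(List trees, NumericMatrix X) {
  const int n = X.nrow(), B = trees.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    List tr = trees[b];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      out[i] += value[node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= B;
  return out;
}
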