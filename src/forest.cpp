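// Compact random-forest classifier (CART trees, Gini impurity, bootstrap
// bagging, random feature subsets).  Designed for the small descriptor
// matrices screened here (n of order 10^2, p of order 10^1); trains and
// predicts in one call and is deterministic given the seed.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feat = -1;        // -1: leaf
  double thr = 0.0;
  int left = -1, right = -1;
  double prob = 0.0;    // leaf: P(class 1)
};

struct TreeBuilder {
  const NumericMatrix &X;
  const IntegerVector &y;
  int mtry, min_node;
  std::mt19937 &rng;
  std::vector<Node> nodes;
  std::vector<int> feats;

  TreeBuilder(const NumericMatrix &X_, const IntegerVector &y_, int mtry_,
              int min_node_, std::mt19937 &rng_)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_), rng(rng_) {
    feats.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) feats[j] = j;
  }

  int build(std::vector<int> &idx) {
    const int m = (int)idx.size();
    int pos = 0;
    for (int i : idx) pos += y[i];
    Node nd;
    if (m < min_node || pos == 0 || pos == m) {
      nd.prob = (double)pos / m;
      nodes.push_back(nd);
      return (int)nodes.size() - 1;
    }
    // sample mtry features without replacement (partial Fisher-Yates)
    const int p = (int)feats.size();
    for (int j = 0; j < mtry && j < p; ++j) {
      std::uniform_int_distribution<int> U(j, p - 1);
      std::swap(feats[j], feats[U(rng)]);
    }
    double best_gain = 0.0;
    int best_f = -1;
    double best_thr = 0.0;
    const double gini_parent =
        1.0 - std::pow((double)pos / m, 2) - std::pow((double)(m - pos) / m, 2);
    std::vector<std::pair<double, int>> vals(m);
    for (int jj = 0; jj < mtry && jj < p; ++jj) {
      const int f = feats[jj];
      for (int t = 0; t < m; ++t) vals[t] = {X(idx[t], f), y[idx[t]]};
      std::sort(vals.begin(), vals.end());
      int lp = 0;
      for (int t = 0; t < m - 1; ++t) {
        lp += vals[t].second;
        if (vals[t].first == vals[t + 1].first) continue;
        const int nl = t + 1, nr = m - nl, rp = pos - lp;
        const double gl =
            1.0 - std::pow((double)lp / nl, 2) - std::pow((double)(nl - lp) / nl, 2);
        const double gr =
            1.0 - std::pow((double)rp / nr, 2) - std::pow((double)(nr - rp) / nr, 2);
        const double gain =
            gini_parent - ((double)nl / m) * gl - ((double)nr / m) * gr;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_f = f;
          best_thr = (vals[t].first + vals[t + 1].first) / 2.0;
        }
      }
    }
    if (best_f < 0) {
      nd.prob = (double)pos / m;
      nodes.push_back(nd);
      return (int)nodes.size() - 1;
    }
    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_f) <= best_thr)
        li.push_back(i);
      else
        ri.push_back(i);
    }
    nd.feat = best_f;
    nd.thr = best_thr;
    nodes.push_back(nd);
    const int me = (int)nodes.size() - 1;
    const int l = build(li);
    const int r = build(ri);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }

  double predict(const NumericMatrix &Xn, int row, int node) const {
    const Node &nd = nodes[node];
    if (nd.feat < 0) return nd.prob;
    return Xn(row, nd.feat) <= nd.thr ? predict(Xn, row, nd.left)
                                      : predict(Xn, row, nd.right);
  }
};

}  // namespace

// [[Rcpp::export(name = ".rf_fit_predict_cpp")]]
NumericVector rf_fit_predict_cpp(NumericMatrix Xtrain, IntegerVector ytrain,
                                 NumericMatrix Xtest, int ntree, int mtry,
                                 int min_node, int seed) {
  const int n = Xtrain.nrow();
  if (ytrain.size() != n) stop("length(y) != nrow(X)");
  if (Xtest.ncol() != Xtrain.ncol()) stop("feature count mismatch");
  std::mt19937 rng((uint32_t)seed);
  NumericVector prob(Xtest.nrow());
  std::uniform_int_distribution<int> U(0, n - 1);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> boot(n);
    for (int i = 0; i < n; ++i) boot[i] = U(rng);
    TreeBuilder tb(Xtrain, ytrain, mtry, min_node, rng);
    std::vector<int> idx = boot;
    const int root = tb.build(idx);
    for (int q = 0; q < Xtest.nrow(); ++q) prob[q] += tb.predict(Xtest, q, root);
  }
  for (int q = 0; q < Xtest.nrow(); ++q) prob[q] /= ntree;
  return prob;
}
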