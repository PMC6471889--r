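// Bagged regression-tree ensemble (random-forest regression) used by the
// environmental-parameter prediction module. Classic CART variance-
// reduction splits, bootstrap resampling per tree, mtry features examined
// per node. Deterministic for a given seed.

#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;        // -1: leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  double value = 0.0;      // leaf prediction
};

struct Tree {
  std::vector<Node> nodes;
};

struct BuildCtx {
  const NumericMatrix& X;  // n x p
  const NumericVector& y;
  int mtry;
  int min_node;
  std::mt19937& rng;
};

double mean_of(const std::vector<int>& idx, const NumericVector& y) {
  double s = 0.0;
  for (int i : idx) s += y[i];
  return idx.empty() ? 0.0 : s / idx.size();
}

int build_node(BuildCtx& ctx, Tree& tree, std::vector<int>& idx) {
  int id = (int)tree.nodes.size();
  tree.nodes.emplace_back();
  const int n = (int)idx.size();
  double node_mean = mean_of(idx, ctx.y);
  tree.nodes[id].value = node_mean;

  double sse = 0.0;
  for (int i : idx) {
    double d = ctx.y[i] - node_mean;
    sse += d * d;
  }
  if (n < 2 * ctx.min_node || sse <= 1e-12) return id;  // leaf

  const int p = ctx.X.ncol();
  // sample mtry distinct features
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int mtry = std::min(ctx.mtry, p);
  for (int j = 0; j < mtry; ++j) {
    std::uniform_int_distribution<int> u(j, p - 1);
    std::swap(feats[j], feats[u(ctx.rng)]);
  }

  int best_feat = -1;
  double best_thr = 0.0, best_gain = 1e-12;
  std::vector<std::pair<double, double>> xy(n);
  for (int jj = 0; jj < mtry; ++jj) {
    int f = feats[jj];
    for (int k = 0; k < n; ++k)
      xy[k] = {ctx.X(idx[k], f), ctx.y[idx[k]]};
    std::sort(xy.begin(), xy.end());
    if (xy.front().first == xy.back().first) continue;
    // prefix scan over sorted order
    double sl = 0.0, sr = 0.0;
    for (int k = 0; k < n; ++k) sr += xy[k].second;
    for (int k = 0; k < n - 1; ++k) {
      sl += xy[k].second;
      sr -= xy[k].second;
      if (xy[k + 1].first == xy[k].first) continue;
      int nl = k + 1, nr = n - nl;
      if (nl < ctx.min_node || nr < ctx.min_node) continue;
      double gain = sl * sl / nl + sr * sr / nr - (sl + sr) * (sl + sr) / n;
      if (gain > best_gain) {
        best_gain = gain;
        best_feat = f;
        best_thr = 0.5 * (xy[k].first + xy[k + 1].first);
      }
    }
  }
  if (best_feat < 0) return id;  // no usable split among sampled features

  std::vector<int> left_idx, right_idx;
  left_idx.reserve(n);
  right_idx.reserve(n);
  for (int i : idx)
    (ctx.X(i, best_feat) <= best_thr ? left_idx : right_idx).push_back(i);
  if (left_idx.empty() || right_idx.empty()) return id;

  tree.nodes[id].feature = best_feat;
  tree.nodes[id].threshold = best_thr;
  int l = build_node(ctx, tree, left_idx);
  int r = build_node(ctx, tree, right_idx);
  tree.nodes[id].left = l;
  tree.nodes[id].right = r;
  return id;
}

double predict_tree(const Tree& tree, const NumericMatrix& X, int row) {
  int cur = 0;
  while (tree.nodes[cur].feature >= 0)
    cur = (X(row, tree.nodes[cur].feature) <= tree.nodes[cur].threshold)
              ? tree.nodes[cur].left
              : tree.nodes[cur].right;
  return tree.nodes[cur].value;
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_predict")]]
NumericVector rf_fit_predict(NumericMatrix Xtrain, NumericVector ytrain,
                             NumericMatrix Xtest, int ntree, int mtry,
                             int min_node, int seed) {
  const int n = Xtrain.nrow();
  if (ytrain.size() != n) stop("X/y size mismatch");
  if (Xtest.ncol() != Xtrain.ncol()) stop("feature-space mismatch");
  if (n < 1) stop("empty training set");
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> boot(0, n - 1);

  NumericVector pred(Xtest.nrow());
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    Tree tree;
    BuildCtx ctx{Xtrain, ytrain, mtry, min_node, rng};
    build_node(ctx, tree, idx);
    for (int r = 0; r < Xtest.nrow(); ++r)
      pred[r] += predict_tree(tree, Xtest, r);
  }
  for (int r = 0; r < Xtest.nrow(); ++r) pred[r] /= ntree;
  return pred;
}
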