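// Random forest for binary classification: bagged CART trees with Gini
// splitting, per-leaf minimum size, feature subsampling (mtry) and
// mean-decrease-in-impurity importance. Scores are the across-tree mean of
// leaf positive-class fractions, so they live in [0,1] like a probability.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;
  double value;     // positive-class fraction at the node
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, min_leaf, max_depth;
  std::mt19937& rng;
  std::vector<Node> nodes;
  std::vector<double>& importance; // accumulated Gini decrease, length p
  int n_total;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
              int min_leaf_, int max_depth_, std::mt19937& rng_,
              std::vector<double>& imp_, int n_total_)
    : X(X_), y(y_), mtry(mtry_), min_leaf(min_leaf_), max_depth(max_depth_),
      rng(rng_), importance(imp_), n_total(n_total_) {}

  static double gini(double n_pos, double n) {
    if (n <= 0.0) return 0.0;
    double p = n_pos / n;
    return 2.0 * p * (1.0 - p);
  }

  int build(std::vector<int>& idx, int depth) {
    int n = (int)idx.size();
    double n_pos = 0;
    for (int i : idx) n_pos += y[i];
    double node_value = n_pos / n;
    bool pure = (n_pos == 0 || n_pos == n);

    int self = (int)nodes.size();
    nodes.push_back({-1, 0.0, -1, -1, node_value});
    if (pure || n < 2 * min_leaf || (max_depth > 0 && depth >= max_depth))
      return self;

    // sample mtry candidate features without replacement
    int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int j = 0; j < mtry && j < p; ++j) {
      std::uniform_int_distribution<int> d(j, p - 1);
      std::swap(feats[j], feats[d(rng)]);
    }

    double parent_gini = gini(n_pos, (double)n);
    double best_gain = 1e-12;
    int best_feat = -1;
    double best_thr = 0.0;

    std::vector<std::pair<double,int>> vals(n);
    for (int c = 0; c < mtry && c < p; ++c) {
      int f = feats[c];
      for (int k = 0; k < n; ++k) vals[k] = {X(idx[k], f), idx[k]};
      std::sort(vals.begin(), vals.end());
      double left_pos = 0.0;
      for (int k = 0; k < n - 1; ++k) {
        left_pos += y[vals[k].second];
        if (vals[k].first == vals[k + 1].first) continue;
        int nl = k + 1, nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        double child =
          (nl * gini(left_pos, nl) + nr * gini(n_pos - left_pos, nr)) / n;
        double gain = parent_gini - child;
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = f;
          best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
        }
      }
    }
    if (best_feat < 0) return self;

    std::vector<int> li, ri;
    for (int i : idx) (X(i, best_feat) <= best_thr ? li : ri).push_back(i);
    if ((int)li.size() < min_leaf || (int)ri.size() < min_leaf) return self;

    importance[best_feat] += ((double)n / n_total) * best_gain;
    nodes[self].feature = best_feat;
    nodes[self].threshold = best_thr;
    int l = build(li, depth + 1);
    nodes[self].left = l;
    int r = build(ri, depth + 1);
    nodes[self].right = r;
    return self;
  }
};

NumericMatrix pack_tree(const std::vector<Node>& nodes) {
  NumericMatrix m((int)nodes.size(), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].feature;
    m(i, 1) = nodes[i].threshold;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].value;
  }
  return m;
}

double tree_score(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = (X(row, f) <= tree(node, 1)) ? (int)tree(node, 2)
                                        : (int)tree(node, 3);
  }
  return tree(node, 4);
}

} // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                int min_leaf, int max_depth, int seed) {
  int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> pick(0, n - 1);
  List trees(n_trees);
  std::vector<double> importance(p, 0.0);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = pick(rng);
    TreeBuilder tb(X, y, mtry, min_leaf, max_depth, rng, importance, n);
    tb.build(idx, 0);
    trees[t] = pack_tree(tb.nodes);
  }
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = importance[j] / n_trees;
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

namespace {

// tree prediction for one row with one feature's value overridden
double tree_score_override(const NumericMatrix& tree, const NumericMatrix& X,
                           int row, int feat, double value) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    double x = (f == feat) ? value : X(row, f);
    node = (x <= tree(node, 1)) ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return tree(node, 4);
}

} // namespace

// Random forest fit plus out-of-bag permutation importance: per tree, the
// drop in OOB accuracy when a feature's values are permuted among the OOB
// rows; reported as the across-tree z-score (mean / (sd / sqrt(n_trees))),
// the scale the shadow-feature comparison uses.
// [[Rcpp::export(name = ".rf_fit_mda_cpp")]]
List rf_fit_mda_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                    int min_leaf, int max_depth, int seed) {
  int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> pick(0, n - 1);
  List trees(n_trees);
  std::vector<double> mdi(p, 0.0);
  std::vector<double> sum_drop(p, 0.0), sum_drop2(p, 0.0);

  std::vector<int> inbag(n);
  std::vector<int> oob;
  std::vector<double> perm_vals;

  for (int t = 0; t < n_trees; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      idx[i] = pick(rng);
      ++inbag[idx[i]];
    }
    TreeBuilder tb(X, y, mtry, min_leaf, max_depth, rng, mdi, n);
    tb.build(idx, 0);
    NumericMatrix tree = pack_tree(tb.nodes);
    trees[t] = tree;

    oob.clear();
    for (int i = 0; i < n; ++i)
      if (inbag[i] == 0) oob.push_back(i);
    int m = (int)oob.size();
    if (m == 0) continue;

    // baseline OOB accuracy of this tree (majority call at the leaf)
    int base_correct = 0;
    for (int i : oob)
      base_correct += ((tree_score(tree, X, i) > 0.5) ? 1 : 0) == y[i];

    // which features the tree actually uses
    std::vector<bool> used(p, false);
    for (int nd = 0; nd < tree.nrow(); ++nd)
      if (tree(nd, 0) >= 0) used[(int)tree(nd, 0)] = true;

    for (int f = 0; f < p; ++f) {
      if (!used[f]) continue; // drop is exactly 0; zeros enter the moments
      perm_vals.resize(m);
      for (int k = 0; k < m; ++k) perm_vals[k] = X(oob[k], f);
      for (int k = m - 1; k > 0; --k) {
        std::uniform_int_distribution<int> d(0, k);
        std::swap(perm_vals[k], perm_vals[d(rng)]);
      }
      int correct = 0;
      for (int k = 0; k < m; ++k) {
        double sc = tree_score_override(tree, X, oob[k], f, perm_vals[k]);
        correct += ((sc > 0.5) ? 1 : 0) == y[oob[k]];
      }
      double drop = (double)(base_correct - correct) / m;
      sum_drop[f] += drop;
      sum_drop2[f] += drop * drop;
    }
  }

  NumericVector z(p), imp(p);
  for (int f = 0; f < p; ++f) {
    double mean = sum_drop[f] / n_trees;
    double var = sum_drop2[f] / n_trees - mean * mean;
    if (var < 0) var = 0;
    double se = std::sqrt(var / n_trees);
    z[f] = (se > 0) ? mean / se : 0.0;
    imp[f] = mean;
  }
  return List::create(_["trees"] = trees, _["importance"] = z,
                      _["raw_mda"] = imp);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += tree_score(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}
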