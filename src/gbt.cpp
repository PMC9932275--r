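// Gradient boosted trees for binary classification with logistic loss and
// second-order (gradient/hessian) split gains: learning rate eta, exact
// greedy splits, L2 leaf regularisation lambda = 1, minimum child hessian
// weight, row subsampling per round and per-tree column subsampling.
// Raw predictions are additive margins; scores are sigmoid(margin).
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const double LAMBDA = 1.0;

struct GNode {
  int feature;
  double threshold;
  int left, right;
  double weight; // leaf output on margin scale (eta already applied)
};

struct GTreeBuilder {
  const NumericMatrix& X;
  const std::vector<double>& grad;
  const std::vector<double>& hess;
  const std::vector<int>& cols; // usable columns after colsample
  int max_depth;
  double min_child_weight, eta;
  std::vector<GNode> nodes;

  GTreeBuilder(const NumericMatrix& X_, const std::vector<double>& g,
               const std::vector<double>& h, const std::vector<int>& cols_,
               int max_depth_, double mcw, double eta_)
    : X(X_), grad(g), hess(h), cols(cols_), max_depth(max_depth_),
      min_child_weight(mcw), eta(eta_) {}

  int build(std::vector<int>& idx, int depth) {
    double G = 0.0, H = 0.0;
    for (int i : idx) { G += grad[i]; H += hess[i]; }
    int self = (int)nodes.size();
    nodes.push_back({-1, 0.0, -1, -1, -eta * G / (H + LAMBDA)});
    if (depth >= max_depth || (int)idx.size() < 2) return self;

    double parent_score = G * G / (H + LAMBDA);
    double best_gain = 1e-12;
    int best_feat = -1;
    double best_thr = 0.0;
    int n = (int)idx.size();
    std::vector<std::pair<double,int>> vals(n);
    for (int f : cols) {
      for (int k = 0; k < n; ++k) vals[k] = {X(idx[k], f), idx[k]};
      std::sort(vals.begin(), vals.end());
      double GL = 0.0, HL = 0.0;
      for (int k = 0; k < n - 1; ++k) {
        GL += grad[vals[k].second];
        HL += hess[vals[k].second];
        if (vals[k].first == vals[k + 1].first) continue;
        double HR = H - HL, GR = G - GL;
        if (HL < min_child_weight || HR < min_child_weight) continue;
        double gain = 0.5 * (GL * GL / (HL + LAMBDA) +
                             GR * GR / (HR + LAMBDA) - parent_score);
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
    if (li.empty() || ri.empty()) return self;
    nodes[self].feature = best_feat;
    nodes[self].threshold = best_thr;
    nodes[self].left = build(li, depth + 1);
    nodes[self].right = build(ri, depth + 1);
    return self;
  }
};

NumericMatrix pack_gtree(const std::vector<GNode>& nodes) {
  NumericMatrix m((int)nodes.size(), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].feature;
    m(i, 1) = nodes[i].threshold;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].weight;
  }
  return m;
}

double gtree_margin(const NumericMatrix& tree, const NumericMatrix& X,
                    int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = (X(row, f) <= tree(node, 1)) ? (int)tree(node, 2)
                                        : (int)tree(node, 3);
  }
  return tree(node, 4);
}

inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

} // namespace

// [[Rcpp::export(name = ".gbt_fit_cpp")]]
List gbt_fit_cpp(NumericMatrix X, IntegerVector y, int n_rounds, double eta,
                 int max_depth, double min_child_weight, double subsample,
                 double colsample, int seed) {
  int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned)seed);
  std::vector<double> margin(n, 0.0), grad(n), hess(n);
  List trees(n_rounds);

  int n_cols = std::max(1, (int)std::round(colsample * p));
  int n_rows = std::max(2, (int)std::round(subsample * n));

  for (int t = 0; t < n_rounds; ++t) {
    for (int i = 0; i < n; ++i) {
      double pr = sigmoid(margin[i]);
      grad[i] = pr - y[i];
      hess[i] = std::max(pr * (1.0 - pr), 1e-16);
    }
    // row subsample without replacement
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) rows[i] = i;
    if (n_rows < n) {
      for (int i = 0; i < n_rows; ++i) {
        std::uniform_int_distribution<int> d(i, n - 1);
        std::swap(rows[i], rows[d(rng)]);
      }
      rows.resize(n_rows);
    }
    // column subsample per tree
    std::vector<int> cols(p);
    for (int j = 0; j < p; ++j) cols[j] = j;
    if (n_cols < p) {
      for (int j = 0; j < n_cols; ++j) {
        std::uniform_int_distribution<int> d(j, p - 1);
        std::swap(cols[j], cols[d(rng)]);
      }
      cols.resize(n_cols);
    }
    GTreeBuilder tb(X, grad, hess, cols, max_depth, min_child_weight, eta);
    tb.build(rows, 0);
    NumericMatrix packed = pack_gtree(tb.nodes);
    trees[t] = packed;
    for (int i = 0; i < n; ++i) margin[i] += gtree_margin(packed, X, i);
  }
  return List::create(_["trees"] = trees);
}

// [[Rcpp::export(name = ".gbt_predict_cpp")]]
NumericVector gbt_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += gtree_margin(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] = sigmoid(out[i]);
  return out;
}
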