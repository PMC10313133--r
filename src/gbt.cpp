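// Gradient-boosted decision trees with second-order (Newton) boosting and
// logistic loss -- exact greedy split search.  Deterministic: no sampling.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Node {
  int feature = -1;       // -1: leaf
  double threshold = 0.0; // go left if x < threshold
  int left = -1, right = -1;
  double value = 0.0;     // leaf weight
};

struct SplitResult {
  int feature = -1;
  double threshold = 0.0, gain = 0.0;
};

static SplitResult best_split(const NumericMatrix& X,
                              const std::vector<double>& g,
                              const std::vector<double>& h,
                              const std::vector<int>& idx,
                              double lambda, double gamma,
                              double min_child_weight) {
  SplitResult best;
  const int n = (int)idx.size(), p = X.ncol();
  double G = 0, H = 0;
  for (int i : idx) { G += g[i]; H += h[i]; }
  const double parent = G * G / (H + lambda);
  std::vector<std::pair<double, int>> vals(n);
  for (int f = 0; f < p; ++f) {
    for (int j = 0; j < n; ++j) vals[j] = {X(idx[j], f), idx[j]};
    std::sort(vals.begin(), vals.end());
    double GL = 0, HL = 0;
    for (int j = 0; j < n - 1; ++j) {
      GL += g[vals[j].second];
      HL += h[vals[j].second];
      if (vals[j + 1].first <= vals[j].first) continue; // no cut between ties
      const double GR = G - GL, HR = H - HL;
      if (HL < min_child_weight || HR < min_child_weight) continue;
      const double gain = 0.5 * (GL * GL / (HL + lambda) +
                                 GR * GR / (HR + lambda) - parent) - gamma;
      if (gain > best.gain + 1e-12) {
        best.gain = gain;
        best.feature = f;
        best.threshold = 0.5 * (vals[j].first + vals[j + 1].first);
      }
    }
  }
  return best;
}

static int build_node(const NumericMatrix& X, const std::vector<double>& g,
                      const std::vector<double>& h, std::vector<int>& idx,
                      int depth, int max_depth, double lambda, double gamma,
                      double min_child_weight, std::vector<Node>& nodes) {
  double G = 0, H = 0;
  for (int i : idx) { G += g[i]; H += h[i]; }
  Node nd;
  nd.value = -G / (H + lambda);
  SplitResult sp;
  if (depth < max_depth && (int)idx.size() >= 2)
    sp = best_split(X, g, h, idx, lambda, gamma, min_child_weight);
  const int me = (int)nodes.size();
  nodes.push_back(nd);
  if (sp.feature >= 0) {
    std::vector<int> li, ri;
    for (int i : idx) (X(i, sp.feature) < sp.threshold ? li : ri).push_back(i);
    nodes[me].feature = sp.feature;
    nodes[me].threshold = sp.threshold;
    int l = build_node(X, g, h, li, depth + 1, max_depth, lambda, gamma,
                       min_child_weight, nodes);
    int r = build_node(X, g, h, ri, depth + 1, max_depth, lambda, gamma,
                       min_child_weight, nodes);
    nodes[me].left = l;
    nodes[me].right = r;
  }
  return me;
}

static double tree_predict(const NumericMatrix& tree, const NumericMatrix& X,
                           int row) {
  int node = 0;
  while ((int)tree(node, 0) >= 0) {
    node = X(row, (int)tree(node, 0)) < tree(node, 1) ? (int)tree(node, 2)
                                                      : (int)tree(node, 3);
  }
  return tree(node, 4);
}

static NumericMatrix pack(const std::vector<Node>& nodes) {
  NumericMatrix m((int)nodes.size(), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].feature;
    m(i, 1) = nodes[i].threshold;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].value;
  }
  colnames(m) = CharacterVector::create("feature", "threshold", "left",
                                        "right", "value");
  return m;
}

// [[Rcpp::export(name = ".gbt_train_cpp")]]
List gbt_train_cpp(NumericMatrix X, NumericVector y, int nrounds, double eta,
                   int max_depth, double lambda, double gamma,
                   double min_child_weight, double base_margin) {
  const int n = X.nrow();
  std::vector<double> f(n, base_margin), g(n), h(n);
  List trees(nrounds);
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  for (int t = 0; t < nrounds; ++t) {
    for (int i = 0; i < n; ++i) {
      const double p = 1.0 / (1.0 + std::exp(-f[i]));
      g[i] = p - y[i];
      h[i] = std::max(p * (1.0 - p), 1e-16);
    }
    std::vector<Node> nodes;
    std::vector<int> idx = all;
    build_node(X, g, h, idx, 0, max_depth, lambda, gamma, min_child_weight,
               nodes);
    NumericMatrix tm = pack(nodes);
    for (int i = 0; i < n; ++i) f[i] += eta * tree_predict(tm, X, i);
    trees[t] = tm;
  }
  return List::create(Named("trees") = trees,
                      Named("base_margin") = base_margin,
                      Named("eta") = eta);
}

// [[Rcpp::export(name = ".gbt_margin_cpp")]]
NumericVector gbt_margin_cpp(List trees, NumericMatrix X, double base_margin,
                             double eta) {
  const int n = X.nrow();
  NumericVector out(n, base_margin);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) out[i] += eta * tree_predict(tm, X, i);
  }
  return out;
}
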