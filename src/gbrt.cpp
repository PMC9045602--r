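// Gradient-boosted regression trees with Huber loss.
//
// Deterministic by construction: no feature or row subsampling, greedy
// exact splits scanned in fixed feature order, strict-improvement
// tie-breaking.  Trees are stored in flat arrays so that staged
// predictions (an ensemble truncated to the first m trees) can be read
// off a single fit.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // split: x[feature] <= threshold -> left
  int left, right;  // child indices, -1 for leaf
  double value;     // leaf update (already Huber-corrected, unscaled)
};

struct Tree {
  std::vector<Node> nodes;
};

double quantile_type7(std::vector<double> v, double p) {
  if (v.empty()) return 0.0;
  std::sort(v.begin(), v.end());
  const double h = (v.size() - 1) * p;
  const size_t lo = static_cast<size_t>(std::floor(h));
  const size_t hi = static_cast<size_t>(std::ceil(h));
  return v[lo] + (h - lo) * (v[hi] - v[lo]);
}

double median_of(std::vector<double> v) { return quantile_type7(std::move(v), 0.5); }

// Huber-optimal leaf value: median of residuals plus the trimmed-mean
// correction (Friedman 2001, eq. for the M-regression leaf update).
double huber_leaf_value(const std::vector<double>& resid, double delta) {
  if (resid.empty()) return 0.0;
  const double med = median_of(resid);
  double corr = 0.0;
  for (double r : resid) {
    const double d = r - med;
    corr += (d >= 0 ? 1.0 : -1.0) * std::min(std::fabs(d), delta);
  }
  return med + corr / resid.size();
}

// Greedy exact least-squares split for the working response g on rows idx.
bool best_split(const NumericMatrix& X, const std::vector<double>& g,
                const std::vector<int>& idx, int min_leaf,
                int* best_feat, double* best_thresh, double* best_gain) {
  const int n = static_cast<int>(idx.size());
  const int p = X.ncol();
  double sum = 0.0;
  for (int i : idx) sum += g[i];
  const double parent_ss = sum * sum / n;

  *best_gain = 0.0;
  *best_feat = -1;
  std::vector<std::pair<double, double>> xv(n); // (x, g)
  for (int j = 0; j < p; ++j) {
    for (int t = 0; t < n; ++t) xv[t] = std::make_pair(X(idx[t], j), g[idx[t]]);
    std::sort(xv.begin(), xv.end());
    double left_sum = 0.0;
    for (int t = 0; t < n - 1; ++t) {
      left_sum += xv[t].second;
      if (xv[t].first == xv[t + 1].first) continue;
      const int nl = t + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      const double right_sum = sum - left_sum;
      const double gain =
          left_sum * left_sum / nl + right_sum * right_sum / nr - parent_ss;
      if (gain > *best_gain + 1e-12) {
        *best_gain = gain;
        *best_feat = j;
        *best_thresh = 0.5 * (xv[t].first + xv[t + 1].first);
      }
    }
  }
  return *best_feat >= 0;
}

int grow(Tree& tree, const NumericMatrix& X, const std::vector<double>& g,
         const std::vector<double>& resid, double delta,
         std::vector<int>& idx, int depth, int max_depth, int min_leaf) {
  Node node;
  node.feature = -1;
  node.threshold = 0.0;
  node.left = node.right = -1;
  node.value = 0.0;

  int feat;
  double thresh, gain;
  if (depth < max_depth && static_cast<int>(idx.size()) >= 2 * min_leaf &&
      best_split(X, g, idx, min_leaf, &feat, &thresh, &gain)) {
    std::vector<int> lidx, ridx;
    for (int i : idx) {
      if (X(i, feat) <= thresh) lidx.push_back(i); else ridx.push_back(i);
    }
    node.feature = feat;
    node.threshold = thresh;
    const int self = static_cast<int>(tree.nodes.size());
    tree.nodes.push_back(node);
    const int l = grow(tree, X, g, resid, delta, lidx, depth + 1, max_depth, min_leaf);
    const int r = grow(tree, X, g, resid, delta, ridx, depth + 1, max_depth, min_leaf);
    tree.nodes[self].left = l;
    tree.nodes[self].right = r;
    return self;
  }
  std::vector<double> rleaf;
  rleaf.reserve(idx.size());
  for (int i : idx) rleaf.push_back(resid[i]);
  node.value = huber_leaf_value(rleaf, delta);
  const int self = static_cast<int>(tree.nodes.size());
  tree.nodes.push_back(node);
  return self;
}

double tree_predict(const Tree& tree, const NumericMatrix& X, int row) {
  int cur = 0;
  while (tree.nodes[cur].feature >= 0) {
    cur = (X(row, tree.nodes[cur].feature) <= tree.nodes[cur].threshold)
              ? tree.nodes[cur].left
              : tree.nodes[cur].right;
  }
  return tree.nodes[cur].value;
}

List pack_tree(const Tree& tree) {
  const int m = static_cast<int>(tree.nodes.size());
  IntegerVector feature(m), left(m), right(m);
  NumericVector threshold(m), value(m);
  for (int i = 0; i < m; ++i) {
    feature[i] = tree.nodes[i].feature;
    threshold[i] = tree.nodes[i].threshold;
    left[i] = tree.nodes[i].left;
    right[i] = tree.nodes[i].right;
    value[i] = tree.nodes[i].value;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right, _["value"] = value);
}

Tree unpack_tree(const List& packed) {
  IntegerVector feature = packed["feature"], left = packed["left"],
                right = packed["right"];
  NumericVector threshold = packed["threshold"], value = packed["value"];
  Tree tree;
  tree.nodes.resize(feature.size());
  for (int i = 0; i < feature.size(); ++i) {
    tree.nodes[i] = {feature[i], threshold[i], left[i], right[i], value[i]};
  }
  return tree;
}

} // namespace

// [[Rcpp::export(name = ".gbrt_fit_cpp")]]
List gbrt_fit_cpp(NumericMatrix X, NumericVector y, int n_trees,
                  double learning_rate, int max_depth, double huber_alpha,
                  int min_leaf) {
  const int n = X.nrow();
  std::vector<double> F(n), resid(n), g(n);
  std::vector<double> yv(y.begin(), y.end());
  const double f0 = median_of(yv);
  std::fill(F.begin(), F.end(), f0);

  List trees(n_trees);
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;

  for (int m = 0; m < n_trees; ++m) {
    std::vector<double> absr(n);
    for (int i = 0; i < n; ++i) {
      resid[i] = y[i] - F[i];
      absr[i] = std::fabs(resid[i]);
    }
    double delta = quantile_type7(absr, huber_alpha);
    if (delta <= 0) delta = 1e-10;
    for (int i = 0; i < n; ++i) {
      g[i] = (std::fabs(resid[i]) <= delta)
                 ? resid[i]
                 : delta * ((resid[i] >= 0) ? 1.0 : -1.0);
    }
    Tree tree;
    std::vector<int> idx = all;
    grow(tree, X, g, resid, delta, idx, 0, max_depth, min_leaf);
    for (int i = 0; i < n; ++i) F[i] += learning_rate * tree_predict(tree, X, i);
    trees[m] = pack_tree(tree);
  }
  return List::create(_["init"] = f0, _["learning_rate"] = learning_rate,
                      _["trees"] = trees);
}

// [[Rcpp::export(name = ".gbrt_predict_cpp")]]
NumericVector gbrt_predict_cpp(List model, NumericMatrix X, int n_trees) {
  const double init = model["init"];
  const double lr = model["learning_rate"];
  List trees = model["trees"];
  const int m = std::min<int>(n_trees, trees.size());
  const int n = X.nrow();
  NumericVector out(n, init);
  for (int t = 0; t < m; ++t) {
    Tree tree = unpack_tree(trees[t]);
    for (int i = 0; i < n; ++i) out[i] += lr * tree_predict(tree, X, i);
  }
  return out;
}

// [[Rcpp::export(name = ".gbrt_staged_predict_cpp")]]
NumericMatrix gbrt_staged_predict_cpp(List model, NumericMatrix X,
                                      IntegerVector stages) {
  const double init = model["init"];
  const double lr = model["learning_rate"];
  List trees = model["trees"];
  const int n = X.nrow();
  NumericMatrix out(n, stages.size());
  std::vector<double> cur(n, init);
  int done = 0;
  for (int s = 0; s < stages.size(); ++s) {
    const int target = std::min<int>(stages[s], trees.size());
    for (; done < target; ++done) {
      Tree tree = unpack_tree(trees[done]);
      for (int i = 0; i < n; ++i) cur[i] += lr * tree_predict(tree, X, i);
    }
    for (int i = 0; i < n; ++i) out(i, s) = cur[i];
  }
  return out;
}
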