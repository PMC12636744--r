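// Random forest for binary classification: CART trees, gini impurity,
// bootstrap resampling, per-split feature subsampling, minimum leaf size,
// no depth cap. Uses R's RNG so set.seed() on the R side makes the whole
// forest deterministic. Scores are the fraction of trees voting positive
// (leaf majority; exact ties contribute 0.5).

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;      // -1 for leaves
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<double> vote;      // defined for leaves
};

inline double gini(int pos, int n) {
  if (n == 0) return 0.0;
  double p = (double)pos / n;
  return 2.0 * p * (1.0 - p);
}

// Partial Fisher-Yates draw of mtry distinct indices from 0..p-1
void sample_features(std::vector<int>& pool, int mtry, std::vector<int>& out) {
  int p = pool.size();
  for (int i = 0; i < mtry; ++i) {
    int j = i + (int)(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
}

struct SplitResult {
  int feature = -1;
  double threshold = 0.0;
  double decrease = 0.0;
};

SplitResult best_split(const NumericMatrix& X, const IntegerVector& y,
                       const std::vector<int>& idx,
                       const std::vector<int>& feats, int min_leaf) {
  int n = idx.size();
  int pos = 0;
  for (int i : idx) pos += y[i];
  double g_parent = gini(pos, n);
  SplitResult best;
  std::vector<std::pair<double, int>> vals(n);
  for (int f : feats) {
    for (int i = 0; i < n; ++i)
      vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    int lpos = 0;
    for (int i = 0; i < n - 1; ++i) {
      lpos += vals[i].second;
      int nl = i + 1, nr = n - nl;
      if (vals[i].first == vals[i + 1].first) continue;
      if (nl < min_leaf || nr < min_leaf) continue;
      double dec = g_parent - ((double)nl / n) * gini(lpos, nl)
                            - ((double)nr / n) * gini(pos - lpos, nr);
      if (dec > best.decrease + 1e-12) {
        best.decrease = dec;
        best.feature = f;
        best.threshold = vals[i].first +
          (vals[i + 1].first - vals[i].first) / 2.0;
      }
    }
  }
  return best;
}

void grow_tree(const NumericMatrix& X, const IntegerVector& y,
               int mtry, int min_leaf, Tree& tree,
               std::vector<double>& importance) {
  int n = X.nrow(), p = X.ncol();
  // bootstrap sample
  std::vector<int> boot(n);
  for (int i = 0; i < n; ++i) {
    int j = (int)(unif_rand() * n);
    if (j >= n) j = n - 1;
    boot[i] = j;
  }
  std::vector<int> pool(p);
  for (int f = 0; f < p; ++f) pool[f] = f;
  std::vector<int> feats(mtry);

  // iterative growth with an explicit stack of (node_id, sample indices)
  std::vector<std::pair<int, std::vector<int>>> stack;
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.vote.push_back(0.0);
  stack.push_back(std::make_pair(0, boot));

  while (!stack.empty()) {
    int node = stack.back().first;
    std::vector<int> idx = std::move(stack.back().second);
    stack.pop_back();
    int nn = idx.size();
    int pos = 0;
    for (int i : idx) pos += y[i];
    bool pure = (pos == 0 || pos == nn);
    SplitResult sp;
    if (!pure && nn >= 2 * min_leaf) {
      sample_features(pool, mtry, feats);
      sp = best_split(X, y, idx, feats, min_leaf);
    }
    if (sp.feature < 0) {
      double frac = (double)pos / nn;
      tree.vote[node] = frac > 0.5 ? 1.0 : (frac == 0.5 ? 0.5 : 0.0);
      continue;
    }
    importance[sp.feature] += ((double)nn / n) * sp.decrease;
    std::vector<int> lidx, ridx;
    lidx.reserve(nn); ridx.reserve(nn);
    for (int i : idx) {
      if (X(i, sp.feature) <= sp.threshold) lidx.push_back(i);
      else ridx.push_back(i);
    }
    int lnode = tree.feature.size();
    int rnode = lnode + 1;
    for (int k = 0; k < 2; ++k) {
      tree.feature.push_back(-1);
      tree.threshold.push_back(0.0);
      tree.left.push_back(-1);
      tree.right.push_back(-1);
      tree.vote.push_back(0.0);
    }
    tree.feature[node] = sp.feature;
    tree.threshold[node] = sp.threshold;
    tree.left[node] = lnode;
    tree.right[node] = rnode;
    stack.push_back(std::make_pair(rnode, std::move(ridx)));
    stack.push_back(std::make_pair(lnode, std::move(lidx)));
  }
}

double predict_tree(const Tree& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree.feature[node] >= 0) {
    node = (X(row, tree.feature[node]) <= tree.threshold[node])
             ? tree.left[node] : tree.right[node];
  }
  return tree.vote[node];
}

} // namespace

// [[Rcpp::export]]
List rf_grow_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                 int min_leaf) {
  int p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  std::vector<double> importance(p, 0.0);
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    Tree tree;
    grow_tree(X, y, mtry, min_leaf, tree, importance);
    trees[t] = List::create(
      Named("feature") = wrap(tree.feature),
      Named("threshold") = wrap(tree.threshold),
      Named("left") = wrap(tree.left),
      Named("right") = wrap(tree.right),
      Named("vote") = wrap(tree.vote));
  }
  for (int f = 0; f < p; ++f) importance[f] /= n_trees;
  return List::create(Named("trees") = trees,
                      Named("importance") = wrap(importance));
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  int n_trees = trees.size();
  int n = X.nrow();
  NumericVector scores(n, 0.0);
  std::vector<Tree> parsed(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    List tl = trees[t];
    parsed[t].feature = as<std::vector<int>>(tl["feature"]);
    parsed[t].threshold = as<std::vector<double>>(tl["threshold"]);
    parsed[t].left = as<std::vector<int>>(tl["left"]);
    parsed[t].right = as<std::vector<int>>(tl["right"]);
    parsed[t].vote = as<std::vector<double>>(tl["vote"]);
  }
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int t = 0; t < n_trees; ++t) s += predict_tree(parsed[t], X, i);
    scores[i] = s / n_trees;
  }
  return scores;
}
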