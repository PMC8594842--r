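// Random-forest core for classifier fusion and permutation ranking.
//
// Configuration is the decorrelated-forest recipe used throughout the
// package: full-size bootstrap with replacement, best cross-entropy
// (information) split among `mtry` features sampled uniformly at each node,
// trees grown until terminal nodes are pure or unsplittable, majority vote.
// Importance is classic per-tree out-of-bag permutation importance, with
// columns permuted jointly per feature *group* so a one-hot-encoded
// categorical vote is permuted as one meta-feature.
//
// RNG: std::mt19937 raw output with modulo reduction — avoids
// std::*_distribution so results are bit-identical across C++ standard
// libraries. Tree-growing and permutation streams are seeded independently
// from the one master seed.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937 gen;
  explicit Rng(uint32_t seed) : gen(seed) {}
  // bounded draw in [0, n)
  uint32_t below(uint32_t n) { return gen() % n; }
  void shuffle(std::vector<int>& v) {
    for (int i = (int)v.size() - 1; i > 0; --i) {
      int j = (int)below((uint32_t)i + 1);
      std::swap(v[i], v[j]);
    }
  }
};

struct Tree {
  std::vector<int> feature;      // split feature, -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;  // child node ids, -1 for leaf
  std::vector<int> leaf_class;   // 0/1 at leaves, -1 internal

  int new_node() {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    leaf_class.push_back(-1);
    return (int)feature.size() - 1;
  }

  int predict_row(const double* x) const {
    int node = 0;
    while (feature[node] >= 0)
      node = (x[feature[node]] <= threshold[node]) ? left[node] : right[node];
    return leaf_class[node];
  }
};

inline double entropy2(double n1, double n) {
  if (n <= 0.0) return 0.0;
  double p = n1 / n;
  double h = 0.0;
  if (p > 0.0) h -= p * std::log(p);
  if (p < 1.0) h -= (1.0 - p) * std::log(1.0 - p);
  return h;
}

struct SplitResult {
  bool valid = false;
  double gain = -1.0;
  double threshold = 0.0;
};

// Best information-gain split of `idx` rows on feature j.
SplitResult best_split(const NumericMatrix& X, const IntegerVector& y,
                       const std::vector<int>& idx, int j) {
  SplitResult res;
  const int n = (int)idx.size();
  std::vector<std::pair<double, int>> v(n);
  int pos = 0;
  for (int i = 0; i < n; ++i) {
    v[i] = {X(idx[i], j), y[idx[i]]};
    pos += y[idx[i]];
  }
  std::sort(v.begin(), v.end());
  if (v.front().first == v.back().first) return res;  // constant
  const double h_parent = entropy2(pos, n);
  int nl = 0, posl = 0;
  for (int i = 0; i < n - 1; ++i) {
    ++nl;
    posl += v[i].second;
    if (v[i].first == v[i + 1].first) continue;
    int nr = n - nl, posr = pos - posl;
    double gain = h_parent -
      ((double)nl / n) * entropy2(posl, nl) -
      ((double)nr / n) * entropy2(posr, nr);
    if (gain > res.gain) {
      res.valid = true;
      res.gain = gain;
      res.threshold = v[i].first + (v[i + 1].first - v[i].first) / 2.0;
    }
  }
  return res;
}

void grow_node(Tree& tree, int node, const NumericMatrix& X,
               const IntegerVector& y, std::vector<int>& idx,
               int mtry, Rng& rng) {
  const int n = (int)idx.size();
  int pos = 0;
  for (int i = 0; i < n; ++i) pos += y[idx[i]];

  if (pos == 0 || pos == n) {  // pure
    tree.leaf_class[node] = (pos == n) ? 1 : 0;
    return;
  }

  // candidate features: non-constant within the node
  const int p = X.ncol();
  std::vector<int> cand;
  cand.reserve(p);
  for (int j = 0; j < p; ++j) {
    double x0 = X(idx[0], j);
    for (int i = 1; i < n; ++i) {
      if (X(idx[i], j) != x0) { cand.push_back(j); break; }
    }
  }
  if (cand.empty()) {  // unsplittable impure node: majority, tie -> positive
    tree.leaf_class[node] = (2 * pos >= n) ? 1 : 0;
    return;
  }

  // sample mtry candidates without replacement, evaluate in ascending
  // feature order so ties break on the lower feature index
  int m = std::min<int>(mtry, (int)cand.size());
  rng.shuffle(cand);
  std::vector<int> tried(cand.begin(), cand.begin() + m);
  std::sort(tried.begin(), tried.end());

  int best_j = -1;
  SplitResult best;
  for (int j : tried) {
    SplitResult s = best_split(X, y, idx, j);
    if (s.valid && s.gain > best.gain) { best = s; best_j = j; }
  }
  if (best_j < 0) {  // all sampled features constant: resample from the rest
    for (int j : cand) {
      SplitResult s = best_split(X, y, idx, j);
      if (s.valid && s.gain > best.gain) { best = s; best_j = j; }
    }
  }
  if (best_j < 0) {
    tree.leaf_class[node] = (2 * pos >= n) ? 1 : 0;
    return;
  }

  std::vector<int> lidx, ridx;
  lidx.reserve(n);
  ridx.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (X(idx[i], best_j) <= best.threshold) lidx.push_back(idx[i]);
    else ridx.push_back(idx[i]);
  }
  idx.clear();
  idx.shrink_to_fit();

  tree.feature[node] = best_j;
  tree.threshold[node] = best.threshold;
  int l = tree.new_node();
  int r = tree.new_node();
  tree.left[node] = l;
  tree.right[node] = r;
  grow_node(tree, l, X, y, lidx, mtry, rng);
  grow_node(tree, r, X, y, ridx, mtry, rng);
}

List tree_to_list(const Tree& t) {
  return List::create(
    _["feature"] = IntegerVector(t.feature.begin(), t.feature.end()),
    _["threshold"] = NumericVector(t.threshold.begin(), t.threshold.end()),
    _["left"] = IntegerVector(t.left.begin(), t.left.end()),
    _["right"] = IntegerVector(t.right.begin(), t.right.end()),
    _["leaf_class"] = IntegerVector(t.leaf_class.begin(), t.leaf_class.end()));
}

Tree tree_from_list(const List& l) {
  Tree t;
  IntegerVector f = l["feature"], le = l["left"], ri = l["right"],
                lc = l["leaf_class"];
  NumericVector th = l["threshold"];
  t.feature.assign(f.begin(), f.end());
  t.threshold.assign(th.begin(), th.end());
  t.left.assign(le.begin(), le.end());
  t.right.assign(ri.begin(), ri.end());
  t.leaf_class.assign(lc.begin(), lc.end());
  return t;
}

}  // namespace

// [[Rcpp::export(name = ".forest_fit")]]
List forest_fit(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int seed, IntegerVector group, bool importance) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need at least 2 samples");
  if (p < 1) stop("need at least 1 feature");

  Rng seeder((uint32_t)seed);
  std::vector<uint32_t> tree_seeds(ntree), perm_seeds(ntree);
  for (int t = 0; t < ntree; ++t) tree_seeds[t] = seeder.gen();
  Rng perm_seeder((uint32_t)seed ^ 0x9e3779b9u);
  for (int t = 0; t < ntree; ++t) perm_seeds[t] = perm_seeder.gen();

  int ngroup = 0;
  for (int j = 0; j < p; ++j) ngroup = std::max(ngroup, group[j] + 1);

  std::vector<Tree> trees(ntree);
  std::vector<int> oob_vote1(n, 0), oob_total(n, 0);
  std::vector<double> imp_sum(ngroup, 0.0);
  int imp_trees = 0;

  std::vector<double> xrow(p);

  for (int t = 0; t < ntree; ++t) {
    Rng rng(tree_seeds[t]);
    // full-size bootstrap with replacement
    std::vector<int> inbag_count(n, 0);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int k = (int)rng.below((uint32_t)n);
      idx[i] = k;
      inbag_count[k]++;
    }
    int root = trees[t].new_node();
    grow_node(trees[t], root, X, y, idx, mtry, rng);

    // out-of-bag bookkeeping
    std::vector<int> oob;
    for (int i = 0; i < n; ++i) if (inbag_count[i] == 0) oob.push_back(i);
    if (oob.empty()) continue;

    std::vector<int> pred(oob.size());
    int err0 = 0;
    for (size_t k = 0; k < oob.size(); ++k) {
      int i = oob[k];
      for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
      pred[k] = trees[t].predict_row(xrow.data());
      oob_total[i]++;
      oob_vote1[i] += pred[k];
      if (pred[k] != y[i]) err0++;
    }

    if (importance) {
      imp_trees++;
      Rng prng(perm_seeds[t]);
      std::vector<int> perm((int)oob.size());
      for (size_t k = 0; k < perm.size(); ++k) perm[k] = (int)k;
      for (int g = 0; g < ngroup; ++g) {
        prng.shuffle(perm);
        int errg = 0;
        for (size_t k = 0; k < oob.size(); ++k) {
          int i = oob[k], donor = oob[perm[k]];
          for (int j = 0; j < p; ++j)
            xrow[j] = (group[j] == g) ? X(donor, j) : X(i, j);
          if (trees[t].predict_row(xrow.data()) != y[i]) errg++;
        }
        imp_sum[g] += (double)(errg - err0) / (double)oob.size();
      }
    }
  }

  double oob_err = NA_REAL;
  {
    int used = 0, wrong = 0;
    for (int i = 0; i < n; ++i) {
      if (oob_total[i] == 0) continue;
      used++;
      int call = (2 * oob_vote1[i] >= oob_total[i]) ? 1 : 0;
      if (call != y[i]) wrong++;
    }
    if (used > 0) oob_err = (double)wrong / used;
  }

  List tl(ntree);
  for (int t = 0; t < ntree; ++t) tl[t] = tree_to_list(trees[t]);

  NumericVector imp(ngroup, NA_REAL);
  if (importance && imp_trees > 0)
    for (int g = 0; g < ngroup; ++g) imp[g] = imp_sum[g] / imp_trees;

  return List::create(
    _["trees"] = tl,
    _["oob_error"] = oob_err,
    _["importance"] = imp,
    _["ntree"] = ntree,
    _["mtry"] = mtry,
    _["seed"] = seed);
}

// [[Rcpp::export(name = ".forest_votes")]]
NumericVector forest_votes(List trees, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol(), ntree = trees.size();
  NumericVector out(n);
  std::vector<Tree> ts(ntree);
  for (int t = 0; t < ntree; ++t) ts[t] = tree_from_list(trees[t]);
  std::vector<double> xrow(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
    int v = 0;
    for (int t = 0; t < ntree; ++t) v += ts[t].predict_row(xrow.data());
    out[i] = (double)v / ntree;
  }
  return out;
}
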