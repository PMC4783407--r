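// Random-forest engine for classification on small-n,
// wide-p feature matrices. Kept in C++ because nested leave-one-out with
// per-tree OOB permutation importance re-fits and re-scores forests
// thousands of times per analysis.
//
// All randomness (bootstrap draws, per-node feature subsampling, OOB
// permutations) flows through R's RNG, so set.seed() on the R side makes
// every result reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct TreeNodes {
  std::vector<int> feature;     // split feature (0-based); -1 for leaf
  std::vector<double> threshold; // x[feature] <= threshold goes left
  std::vector<int> left, right;  // child node ids; -1 for leaf
  std::vector<int> pred;         // leaf class (0-based); -1 for internal
};

inline int rand_int(int n) {
  // uniform integer in [0, n); unif_rand() < 1 guaranteed
  int k = static_cast<int>(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

int majority_class(const std::vector<int> &cnt) {
  int best = 0;
  for (size_t c = 1; c < cnt.size(); ++c)
    if (cnt[c] > cnt[best]) best = static_cast<int>(c);
  return best; // ties -> lowest class index
}

double gini_impurity(const std::vector<int> &cnt, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (size_t c = 0; c < cnt.size(); ++c) {
    double f = static_cast<double>(cnt[c]) / n;
    g -= f * f;
  }
  return g;
}

// Grow one tree on the (possibly repeated) row indices in `rows`.
void grow_node(const NumericMatrix &X, const IntegerVector &y, int K,
               std::vector<int> rows, int mtry, int min_leaf,
               std::vector<int> &feat_pool, TreeNodes &tree, int node_id) {
  const int n = static_cast<int>(rows.size());
  std::vector<int> cnt(K, 0);
  for (int r : rows) cnt[y[r]]++;

  bool pure = false;
  for (int c = 0; c < K; ++c)
    if (cnt[c] == n) { pure = true; break; }

  if (pure || n < std::max(2, 2 * min_leaf)) {
    tree.pred[node_id] = majority_class(cnt);
    return;
  }

  const int p = X.ncol();
  // sample mtry distinct features (partial Fisher-Yates on the pool)
  int best_feat = -1;
  double best_thr = 0.0, best_score = -1.0;
  double parent_gini = gini_impurity(cnt, n);

  for (int m = 0; m < mtry; ++m) {
    int j = m + rand_int(p - m);
    std::swap(feat_pool[m], feat_pool[j]);
    int f = feat_pool[m];

    // sort node rows by feature value
    std::vector<std::pair<double, int>> v(n);
    for (int i = 0; i < n; ++i) v[i] = { X(rows[i], f), y[rows[i]] };
    std::sort(v.begin(), v.end());
    if (v.front().first == v.back().first) continue; // constant in node

    std::vector<int> lcnt(K, 0), rcnt(cnt);
    for (int i = 0; i + 1 < n; ++i) {
      lcnt[v[i].second]++;
      rcnt[v[i].second]--;
      if (v[i].first == v[i + 1].first) continue; // not a boundary
      int nl = i + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      double dec = parent_gini
        - (static_cast<double>(nl) / n) * gini_impurity(lcnt, nl)
        - (static_cast<double>(nr) / n) * gini_impurity(rcnt, nr);
      if (dec > best_score) {
        best_score = dec;
        best_feat = f;
        best_thr = 0.5 * (v[i].first + v[i + 1].first);
      }
    }
  }

  if (best_feat < 0) { // all sampled features constant within node
    tree.pred[node_id] = majority_class(cnt);
    return;
  }

  std::vector<int> lrows, rrows;
  for (int r : rows)
    (X(r, best_feat) <= best_thr ? lrows : rrows).push_back(r);
  rows.clear(); rows.shrink_to_fit();

  int lid = static_cast<int>(tree.feature.size());
  tree.feature.push_back(-1); tree.threshold.push_back(0.0);
  tree.left.push_back(-1); tree.right.push_back(-1); tree.pred.push_back(-1);
  int rid = static_cast<int>(tree.feature.size());
  tree.feature.push_back(-1); tree.threshold.push_back(0.0);
  tree.left.push_back(-1); tree.right.push_back(-1); tree.pred.push_back(-1);

  tree.feature[node_id] = best_feat;
  tree.threshold[node_id] = best_thr;
  tree.left[node_id] = lid;
  tree.right[node_id] = rid;

  grow_node(X, y, K, std::move(lrows), mtry, min_leaf, feat_pool, tree, lid);
  grow_node(X, y, K, std::move(rrows), mtry, min_leaf, feat_pool, tree, rid);
}

inline int predict_row(const TreeNodes &t, const NumericMatrix &X, int row) {
  int node = 0;
  while (t.feature[node] >= 0)
    node = (X(row, t.feature[node]) <= t.threshold[node]) ? t.left[node]
                                                          : t.right[node];
  return t.pred[node];
}

inline int predict_row_perm(const TreeNodes &t, const NumericMatrix &X,
                            int row, int perm_feat, double perm_val) {
  int node = 0;
  while (t.feature[node] >= 0) {
    double x = (t.feature[node] == perm_feat) ? perm_val
                                              : X(row, t.feature[node]);
    node = (x <= t.threshold[node]) ? t.left[node] : t.right[node];
  }
  return t.pred[node];
}

TreeNodes unpack_tree(const List &tr) {
  TreeNodes t;
  IntegerVector f = tr["feature"], l = tr["left"], r = tr["right"],
                pr = tr["pred"];
  NumericVector th = tr["threshold"];
  t.feature.assign(f.begin(), f.end());
  t.threshold.assign(th.begin(), th.end());
  t.left.assign(l.begin(), l.end());
  t.right.assign(r.begin(), r.end());
  t.pred.assign(pr.begin(), pr.end());
  return t;
}

} // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_classes, int n_trees,
                int mtry, int min_leaf) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;

  List trees(n_trees);
  IntegerMatrix inbag(n, n_trees); // bootstrap multiplicity of row i in tree t
  std::vector<int> feat_pool(p);

  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) {
      int r = rand_int(n);
      rows[i] = r;
      inbag(r, t)++;
    }
    for (int j = 0; j < p; ++j) feat_pool[j] = j;

    TreeNodes tree;
    tree.feature.push_back(-1); tree.threshold.push_back(0.0);
    tree.left.push_back(-1); tree.right.push_back(-1); tree.pred.push_back(-1);
    grow_node(X, y, n_classes, std::move(rows), mtry, min_leaf, feat_pool,
              tree, 0);

    trees[t] = List::create(
      _["feature"] = IntegerVector(tree.feature.begin(), tree.feature.end()),
      _["threshold"] = NumericVector(tree.threshold.begin(),
                                     tree.threshold.end()),
      _["left"] = IntegerVector(tree.left.begin(), tree.left.end()),
      _["right"] = IntegerVector(tree.right.begin(), tree.right.end()),
      _["pred"] = IntegerVector(tree.pred.begin(), tree.pred.end()));
  }

  return List::create(_["trees"] = trees, _["inbag"] = inbag);
}

// Per-tree class predictions: rows of X x trees, 0-based classes.
// [[Rcpp::export]]
IntegerMatrix rf_predict_cpp(List trees, NumericMatrix X) {
  const int m = X.nrow(), T = trees.size();
  IntegerMatrix out(m, T);
  for (int t = 0; t < T; ++t) {
    TreeNodes tr = unpack_tree(trees[t]);
    for (int i = 0; i < m; ++i) out(i, t) = predict_row(tr, X, i);
  }
  return out;
}

// OOB permutation importance: for each tree, the increase of its OOB error
// when one feature's OOB values are randomly permuted; importance is the
// mean increase over all trees. Features a tree never splits on contribute
// exactly zero for that tree and are skipped (identical result, no RNG use).
// [[Rcpp::export]]
NumericVector rf_importance_cpp(List trees, IntegerMatrix inbag,
                                NumericMatrix X, IntegerVector y) {
  const int n = X.nrow(), p = X.ncol(), T = trees.size();
  NumericVector imp(p);

  for (int t = 0; t < T; ++t) {
    TreeNodes tr = unpack_tree(trees[t]);

    std::vector<int> oob;
    for (int i = 0; i < n; ++i)
      if (inbag(i, t) == 0) oob.push_back(i);
    const int no = static_cast<int>(oob.size());
    if (no == 0) continue;

    int base_err = 0;
    for (int i : oob)
      if (predict_row(tr, X, i) != y[i]) base_err++;

    // distinct features used by this tree
    std::vector<int> used(tr.feature);
    used.erase(std::remove(used.begin(), used.end(), -1), used.end());
    std::sort(used.begin(), used.end());
    used.erase(std::unique(used.begin(), used.end()), used.end());

    std::vector<double> vals(no);
    for (int f : used) {
      for (int i = 0; i < no; ++i) vals[i] = X(oob[i], f);
      for (int i = no - 1; i > 0; --i) // Fisher-Yates
        std::swap(vals[i], vals[rand_int(i + 1)]);
      int perm_err = 0;
      for (int i = 0; i < no; ++i)
        if (predict_row_perm(tr, X, oob[i], f, vals[i]) != y[oob[i]])
          perm_err++;
      imp[f] += static_cast<double>(perm_err - base_err) / no;
    }
  }

  for (int f = 0; f < p; ++f) imp[f] /= T;
  return imp;
}
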