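// Random-forest classifier used for tumour/normal discrimination:
// CART trees (Gini split, grown to purity, no pruning), subsampling without
// replacement by default, OOB bookkeeping, and conditional permutation
// importance where a feature is permuted within the strata carved out by the
// in-tree split points of its correlated covariates.
//
// All randomness comes from R's RNG (unif_rand), so set.seed() on the R side
// makes every fit and importance computation reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <vector>

using namespace Rcpp;

// uniform integer in [0, n)
static inline int rand_int(int n) {
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

struct TreeBuf {
  std::vector<int> var, left, right, pred;
  std::vector<double> val;
  int add_node() {
    var.push_back(-1);
    left.push_back(-1);
    right.push_back(-1);
    pred.push_back(-1);
    val.push_back(0.0);
    return (int)var.size() - 1;
  }
};

// flat view of a grown tree for fast traversal
struct TreeView {
  const int *var, *left, *right, *pred;
  const double *val;
};

static TreeView view_tree(const List &tree) {
  TreeView tv;
  tv.var = INTEGER(((IntegerVector)tree["var"]));
  tv.left = INTEGER(((IntegerVector)tree["left"]));
  tv.right = INTEGER(((IntegerVector)tree["right"]));
  tv.pred = INTEGER(((IntegerVector)tree["pred"]));
  tv.val = REAL(((NumericVector)tree["val"]));
  return tv;
}

static inline int predict_row(const TreeView &tv, const NumericMatrix &X,
                              int row, int ovr_var = -1, double ovr_val = 0.0) {
  int node = 0;
  while (tv.var[node] >= 0) {
    double x = (tv.var[node] == ovr_var) ? ovr_val : X(row, tv.var[node]);
    node = (x <= tv.val[node]) ? tv.left[node] : tv.right[node];
  }
  return tv.pred[node];
}

static inline int leaf_of_row(const TreeView &tv, const NumericMatrix &X, int row) {
  int node = 0;
  while (tv.var[node] >= 0) {
    double x = X(row, tv.var[node]);
    node = (x <= tv.val[node]) ? tv.left[node] : tv.right[node];
  }
  return node;
}

// grow one CART tree on the given rows; explicit stack, Gini criterion
static void grow_tree(const NumericMatrix &X, const IntegerVector &y,
                      const std::vector<int> &rows0, int mtry, TreeBuf &tb) {
  const int m = X.ncol();
  std::vector<std::pair<int, std::vector<int> > > stack;
  int root = tb.add_node();
  stack.push_back(std::make_pair(root, rows0));
  std::vector<int> feat_pool(m);
  std::vector<std::pair<double, int> > vals;

  while (!stack.empty()) {
    int node = stack.back().first;
    std::vector<int> rows = stack.back().second;
    stack.pop_back();

    int n = (int)rows.size();
    int n1 = 0;
    for (int i = 0; i < n; ++i) n1 += y[rows[i]];
    int n0 = n - n1;
    if (n0 == 0 || n1 == 0) { // pure leaf
      tb.pred[node] = (n1 > 0) ? 1 : 0;
      continue;
    }

    // draw mtry candidate features without replacement
    for (int i = 0; i < m; ++i) feat_pool[i] = i;
    int k = mtry < m ? mtry : m;
    double parent_score = ((double)n0 * n0 + (double)n1 * n1) / n;
    double best_score = parent_score + 1e-12;
    int best_var = -1;
    double best_split = 0.0;

    for (int c = 0; c < k; ++c) {
      int swap_at = c + rand_int(m - c);
      std::swap(feat_pool[c], feat_pool[swap_at]);
      int f = feat_pool[c];

      vals.clear();
      for (int i = 0; i < n; ++i)
        vals.push_back(std::make_pair(X(rows[i], f), rows[i]));
      std::sort(vals.begin(), vals.end());

      int l0 = 0, l1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        if (y[vals[i].second] == 1) ++l1; else ++l0;
        if (vals[i + 1].first <= vals[i].first) continue; // tied values
        int nl = i + 1, nr = n - nl;
        int r0 = n0 - l0, r1 = n1 - l1;
        double score = ((double)l0 * l0 + (double)l1 * l1) / nl +
                       ((double)r0 * r0 + (double)r1 * r1) / nr;
        if (score > best_score) {
          best_score = score;
          best_var = f;
          best_split = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }

    if (best_var < 0) { // unsplittable on the sampled candidates: majority leaf
      tb.pred[node] = (n1 > n0) ? 1 : 0;
      continue;
    }

    std::vector<int> lrows, rrows;
    for (int i = 0; i < n; ++i) {
      if (X(rows[i], best_var) <= best_split) lrows.push_back(rows[i]);
      else rrows.push_back(rows[i]);
    }
    tb.var[node] = best_var;
    tb.val[node] = best_split;
    int lid = tb.add_node();
    int rid = tb.add_node();
    tb.left[node] = lid;
    tb.right[node] = rid;
    stack.push_back(std::make_pair(lid, lrows));
    stack.push_back(std::make_pair(rid, rrows));
  }
}

// [[Rcpp::export]]
List grow_forest_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                     double sample_frac, bool replace) {
  const int n = X.nrow();
  List trees(n_trees), oob(n_trees);
  std::vector<int> pool(n);

  int k_sub = (int)(sample_frac * n + 0.5);
  if (k_sub < 1) k_sub = 1;
  if (k_sub > n) k_sub = n;

  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> inbag;
    std::vector<bool> seen(n, false);
    if (replace) {
      for (int i = 0; i < n; ++i) {
        int r = rand_int(n);
        inbag.push_back(r);
        seen[r] = true;
      }
    } else {
      for (int i = 0; i < n; ++i) pool[i] = i;
      for (int i = 0; i < k_sub; ++i) {
        int j = i + rand_int(n - i);
        std::swap(pool[i], pool[j]);
        inbag.push_back(pool[i]);
        seen[pool[i]] = true;
      }
    }
    TreeBuf tb;
    grow_tree(X, y, inbag, mtry, tb);
    trees[t] = List::create(
        _["var"] = IntegerVector(tb.var.begin(), tb.var.end()),
        _["val"] = NumericVector(tb.val.begin(), tb.val.end()),
        _["left"] = IntegerVector(tb.left.begin(), tb.left.end()),
        _["right"] = IntegerVector(tb.right.begin(), tb.right.end()),
        _["pred"] = IntegerVector(tb.pred.begin(), tb.pred.end()));
    std::vector<int> ob;
    for (int i = 0; i < n; ++i)
      if (!seen[i]) ob.push_back(i + 1); // 1-based for R
    oob[t] = IntegerVector(ob.begin(), ob.end());
  }
  return List::create(_["trees"] = trees, _["oob"] = oob);
}

// [[Rcpp::export]]
IntegerMatrix forest_predict_per_tree_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  IntegerMatrix out(n, T);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    TreeView tv = view_tree(tr);
    for (int i = 0; i < n; ++i) out(i, t) = predict_row(tv, X, i);
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix forest_leaf_ids_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  IntegerMatrix out(n, T);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    TreeView tv = view_tree(tr);
    for (int i = 0; i < n; ++i) out(i, t) = leaf_of_row(tv, X, i) + 1;
  }
  return out;
}

// Conditional permutation MDA. cond_sets: per feature, the 1-based indices
// of its conditioning covariates (empty vector => unconditional permutation).
// For every tree, each feature is permuted among the tree's OOB rows within
// strata given by the partition cells that the conditioning covariates'
// split points (in that tree) induce; MDA_j = mean over trees of
// (permuted OOB error - original OOB error).
// [[Rcpp::export]]
NumericVector conditional_mda_cpp(List trees, List oob, NumericMatrix X,
                                  IntegerVector y, List cond_sets) {
  const int m = X.ncol(), T = trees.size();
  NumericVector mda(m);
  int used_trees = 0;

  for (int t = 0; t < T; ++t) {
    IntegerVector ob = oob[t];
    int no = ob.size();
    if (no == 0) continue;
    ++used_trees;
    List tr = trees[t];
    TreeView tv = view_tree(tr);
    IntegerVector var = tr["var"];

    // split values per feature used in this tree (sorted)
    std::map<int, std::vector<double> > splits;
    NumericVector val = tr["val"];
    for (int nd = 0; nd < var.size(); ++nd)
      if (var[nd] >= 0) splits[var[nd]].push_back(val[nd]);
    for (std::map<int, std::vector<double> >::iterator it = splits.begin();
         it != splits.end(); ++it)
      std::sort(it->second.begin(), it->second.end());

    std::vector<int> rows(no);
    for (int i = 0; i < no; ++i) rows[i] = ob[i] - 1;

    double base_err = 0.0;
    for (int i = 0; i < no; ++i)
      base_err += (predict_row(tv, X, rows[i]) != y[rows[i]]);
    base_err /= no;

    for (int j = 0; j < m; ++j) {
      // conditioning covariates actually split on in this tree
      IntegerVector cs = cond_sets[j];
      std::vector<int> cvar;
      std::vector<const std::vector<double> *> cvals;
      for (int c = 0; c < cs.size(); ++c) {
        std::map<int, std::vector<double> >::iterator it = splits.find(cs[c] - 1);
        if (it != splits.end()) {
          cvar.push_back(cs[c] - 1);
          cvals.push_back(&it->second);
        }
      }

      // strata: cell of the conditioning split-point grid for each OOB row
      std::map<std::vector<int>, std::vector<int> > groups;
      std::vector<int> key(cvar.size());
      for (int i = 0; i < no; ++i) {
        for (size_t c = 0; c < cvar.size(); ++c) {
          double x = X(rows[i], cvar[c]);
          key[c] = (int)(std::upper_bound(cvals[c]->begin(), cvals[c]->end(), x) -
                         cvals[c]->begin());
        }
        groups[key].push_back(i);
      }

      // permute feature j within each stratum (Fisher-Yates, R RNG)
      std::vector<double> pv(no);
      for (int i = 0; i < no; ++i) pv[i] = X(rows[i], j);
      for (std::map<std::vector<int>, std::vector<int> >::iterator g = groups.begin();
           g != groups.end(); ++g) {
        std::vector<int> &idx = g->second;
        for (int i = (int)idx.size() - 1; i > 0; --i) {
          int k = rand_int(i + 1);
          std::swap(pv[idx[i]], pv[idx[k]]);
        }
      }

      double err = 0.0;
      for (int i = 0; i < no; ++i)
        err += (predict_row(tv, X, rows[i], j, pv[i]) != y[rows[i]]);
      err /= no;
      mda[j] += err - base_err;
    }
  }
  if (used_trees > 0)
    for (int j = 0; j < m; ++j) mda[j] /= used_trees;
  return mda;
}
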