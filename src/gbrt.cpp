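// Gradient-boosted regression trees with squared-error loss on small-range
// integer features. Level-wise exact greedy splits via per-node value
// histograms; columns are stored sparsely (only entries differing from the
// column's majority value), so histogram accumulation costs O(nnz) per level
// with the majority bin derived from node totals. No row or column
// subsampling: fits are fully deterministic. Leaf weights and split gains
// carry an L2 penalty (lambda), xgboost-style.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

struct TreeNode {
  int feat;      // 0-based feature, -1 for leaf
  double thr;    // go left iff x <= thr (original value scale)
  int left, right;
  double value;  // leaf weight
  double gain;   // split gain (for importance)
};

// sparse column store: rows whose value differs from the column majority
struct SparseCols {
  int n, p;
  std::vector<int> fmin, nbin, mode_code;
  std::vector<std::vector<int>> rows_, codes_;

  void init(const IntegerMatrix& X) {
    n = X.nrow();
    p = X.ncol();
    fmin.resize(p); nbin.resize(p); mode_code.resize(p);
    rows_.resize(p); codes_.resize(p);
    const int* xp = INTEGER(X);
    for (int j = 0; j < p; ++j) {
      const int* col = xp + (size_t)j * n;
      int lo = col[0], hi = col[0];
      for (int i = 1; i < n; ++i) {
        if (col[i] == NA_INTEGER) stop("NaN/NA in features");
        if (col[i] < lo) lo = col[i];
        if (col[i] > hi) hi = col[i];
      }
      if (col[0] == NA_INTEGER) stop("NaN/NA in features");
      fmin[j] = lo;
      int K = hi - lo + 1;
      if (K > 4096) stop("feature value range too wide for histogram");
      nbin[j] = K;
      if (K < 2) { mode_code[j] = 0; continue; }
      std::vector<int> cnt(K, 0);
      for (int i = 0; i < n; ++i) cnt[col[i] - lo]++;
      int mc = 0;
      for (int c = 1; c < K; ++c) if (cnt[c] > cnt[mc]) mc = c;
      mode_code[j] = mc;
      rows_[j].reserve(n - cnt[mc]);
      codes_[j].reserve(n - cnt[mc]);
      for (int i = 0; i < n; ++i) {
        int c = col[i] - lo;
        if (c != mc) { rows_[j].push_back(i); codes_[j].push_back(c); }
      }
    }
  }
};

struct LevelNode {   // bookkeeping for one active node during construction
  int tree_idx;
  double sum;
  int cnt;
  int best_feat;
  int best_cut;
  double best_gain;
};

static void build_tree(const SparseCols& SC, const IntegerMatrix& X,
                       const std::vector<double>& grad, int max_depth,
                       int min_child, double lambda,
                       std::vector<TreeNode>& nodes,
                       std::vector<double>& importance,
                       std::vector<int>& leaf_of_row) {
  int n = SC.n, p = SC.p;
  const int* xp = INTEGER(X);

  std::vector<int> node_of(n, 0);       // active-level slot per row, -1 done
  std::vector<LevelNode> level(1);
  {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += grad[i];
    nodes.push_back({-1, 0.0, -1, -1, 0.0, 0.0});
    level[0] = {0, s, n, -1, 0, 1e-12};
  }

  std::vector<double> hsum;
  std::vector<int> hcnt;

  for (int depth = 0; depth < max_depth; ++depth) {
    int nl = level.size();
    if (nl == 0) break;
    for (int q = 0; q < nl; ++q) {
      level[q].best_feat = -1;
      level[q].best_gain = 1e-12;
    }
    for (int j = 0; j < p; ++j) {
      int K = SC.nbin[j];
      if (K < 2) continue;
      hsum.assign((size_t)nl * K, 0.0);
      hcnt.assign((size_t)nl * K, 0);
      const std::vector<int>& rj = SC.rows_[j];
      const std::vector<int>& cj = SC.codes_[j];
      for (size_t t = 0; t < rj.size(); ++t) {
        int q = node_of[rj[t]];
        if (q < 0) continue;
        hsum[(size_t)q * K + cj[t]] += grad[rj[t]];
        hcnt[(size_t)q * K + cj[t]] += 1;
      }
      int mc = SC.mode_code[j];
      for (int q = 0; q < nl; ++q) {
        LevelNode& nd = level[q];
        if (nd.cnt < 2 * min_child) continue;
        double* hs = &hsum[(size_t)q * K];
        int* hc = &hcnt[(size_t)q * K];
        double other_sum = 0.0;
        int other_cnt = 0;
        for (int c = 0; c < K; ++c) {
          if (c == mc) continue;
          other_sum += hs[c];
          other_cnt += hc[c];
        }
        hs[mc] = nd.sum - other_sum;
        hc[mc] = nd.cnt - other_cnt;
        double base = nd.sum * nd.sum / (nd.cnt + lambda);
        double sL = 0.0; int nL = 0;
        for (int c = 0; c < K - 1; ++c) {
          sL += hs[c]; nL += hc[c];
          int nR = nd.cnt - nL;
          if (nL < min_child || nR < min_child) continue;
          double sR = nd.sum - sL;
          double g = sL * sL / (nL + lambda) + sR * sR / (nR + lambda) - base;
          if (g > nd.best_gain + 1e-12) {
            nd.best_gain = g;
            nd.best_feat = j;
            nd.best_cut = SC.fmin[j] + c;
          }
        }
      }
    }

    // materialize splits, re-assign rows, collect next level
    std::vector<LevelNode> next;
    std::vector<int> slot_map(nl, -1); // level slot -> first-child next slot
    for (int q = 0; q < nl; ++q) {
      LevelNode& nd = level[q];
      TreeNode& tn = nodes[nd.tree_idx];
      if (nd.best_feat < 0) {
        tn.value = nd.sum / (nd.cnt + lambda);
        continue;
      }
      importance[nd.best_feat] += nd.best_gain;
      int left_idx = nodes.size(), right_idx = nodes.size() + 1;
      tn.feat = nd.best_feat;
      tn.thr = nd.best_cut;
      tn.gain = nd.best_gain;
      tn.left = left_idx;
      tn.right = right_idx;
      nodes.push_back({-1, 0.0, -1, -1, 0.0, 0.0});  // invalidates tn
      nodes.push_back({-1, 0.0, -1, -1, 0.0, 0.0});
      slot_map[q] = next.size();
      next.push_back({left_idx, 0.0, 0, -1, 0, 1e-12});
      next.push_back({right_idx, 0.0, 0, -1, 0, 1e-12});
    }
    for (int i = 0; i < n; ++i) {
      int q = node_of[i];
      if (q < 0) continue;
      LevelNode& nd = level[q];
      if (nd.best_feat < 0) {           // became a leaf
        leaf_of_row[i] = nd.tree_idx;
        node_of[i] = -1;
        continue;
      }
      int child = slot_map[q];
      if (xp[(size_t)nd.best_feat * n + i] > nd.best_cut) child += 1;
      node_of[i] = child;
      next[child].sum += grad[i];
      next[child].cnt += 1;
    }
    level.swap(next);
  }
  // remaining active nodes at max depth become leaves
  for (size_t q = 0; q < level.size(); ++q) {
    TreeNode& tn = nodes[level[q].tree_idx];
    tn.value = level[q].sum / (level[q].cnt + lambda);
  }
  for (int i = 0; i < n; ++i)
    if (node_of[i] >= 0) leaf_of_row[i] = level[node_of[i]].tree_idx;
}

static double predict_one_tree(const NumericMatrix& tree,
                               const IntegerMatrix& X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    if (X(row, f) <= tree(node, 1)) node = (int)tree(node, 2);
    else node = (int)tree(node, 3);
  }
  return tree(node, 4);
}

static NumericMatrix pack_tree(const std::vector<TreeNode>& nodes) {
  NumericMatrix m(nodes.size(), 6);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].feat;
    m(i, 1) = nodes[i].thr;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].value;
    m(i, 5) = nodes[i].gain;
  }
  return m;
}

// [[Rcpp::export]]
List gbrt_fit_cpp(IntegerMatrix X, NumericVector y,
                  IntegerMatrix Xval, NumericVector yval,
                  int nrounds, double eta, int max_depth, int min_child,
                  double lambda, int patience) {
  int n = X.nrow(), p = X.ncol();
  if (n == 0 || p == 0) stop("empty training matrix");
  for (int i = 0; i < n; ++i)
    if (NumericVector::is_na(y[i])) stop("NaN in training labels");

  SparseCols SC;
  SC.init(X);

  double base = 0.0;
  for (int i = 0; i < n; ++i) base += y[i];
  base /= n;

  std::vector<double> pred(n, base), grad(n);
  int nval = Xval.nrow();
  std::vector<double> pval(nval, base);
  std::vector<double> importance(p, 0.0);
  std::vector<double> val_rmse;
  List trees(nrounds);
  int best_iter = nrounds, rounds_done = 0;
  double best_rmse = std::numeric_limits<double>::infinity();
  std::vector<int> leaf_of_row(n);

  for (int m = 0; m < nrounds; ++m) {
    for (int i = 0; i < n; ++i) grad[i] = y[i] - pred[i];
    std::vector<TreeNode> nodes;
    build_tree(SC, X, grad, max_depth, min_child, lambda, nodes, importance,
               leaf_of_row);
    NumericMatrix tm = pack_tree(nodes);
    trees[m] = tm;
    rounds_done = m + 1;
    for (int i = 0; i < n; ++i) pred[i] += eta * nodes[leaf_of_row[i]].value;
    if (nval > 0) {
      double se = 0.0;
      for (int i = 0; i < nval; ++i) {
        pval[i] += eta * predict_one_tree(tm, Xval, i);
        double e = yval[i] - pval[i];
        se += e * e;
      }
      double rmse = std::sqrt(se / nval);
      val_rmse.push_back(rmse);
      if (rmse < best_rmse - 1e-10) {
        best_rmse = rmse;
        best_iter = m + 1;
      } else if ((m + 1) - best_iter >= patience) {
        break;
      }
    }
  }
  if (nval == 0) best_iter = rounds_done;

  // importance restricted to the trees actually used
  std::vector<double> imp_used(p, 0.0);
  for (int m = 0; m < best_iter; ++m) {
    NumericMatrix tm = trees[m];
    for (int i = 0; i < tm.nrow(); ++i)
      if (tm(i, 0) >= 0) imp_used[(int)tm(i, 0)] += tm(i, 5);
  }

  List used(best_iter);
  for (int m = 0; m < best_iter; ++m) used[m] = trees[m];
  return List::create(_["trees"] = used,
                      _["best_iter"] = best_iter,
                      _["base"] = base,
                      _["importance"] = NumericVector(imp_used.begin(),
                                                      imp_used.end()),
                      _["valid_rmse"] = NumericVector(val_rmse.begin(),
                                                      val_rmse.end()));
}

// [[Rcpp::export]]
NumericVector gbrt_predict_cpp(List trees, double base, double eta,
                               IntegerMatrix X) {
  int n = X.nrow();
  NumericVector out(n, base);
  for (int m = 0; m < trees.size(); ++m) {
    NumericMatrix tm = trees[m];
    for (int i = 0; i < n; ++i) out[i] += eta * predict_one_tree(tm, X, i);
  }
  return out;
}
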