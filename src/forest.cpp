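#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Regression random forest: CART trees with variance-reduction splits,
// bootstrap resampling and random feature subsets per node. Uses R's RNG
// stream throughout so set.seed() on the R side fully determines a fit.

namespace {

struct TreeBuf {
  std::vector<int> feature;      // split feature (0-based), -1 for leaf
  std::vector<double> threshold; // x <= threshold goes left
  std::vector<int> left, right;  // child node ids, -1 for leaf
  std::vector<double> value;     // node mean of y
};

// uniform integer in [0, n)
inline int runif_int(int n) {
  int k = (int)std::floor(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

int grow(const NumericMatrix& X, const NumericVector& y,
         std::vector<int>& idx, int lo, int hi,
         int mtry, int min_node, TreeBuf& T,
         std::vector<int>& feats, std::vector<int>& ord) {
  const int n = hi - lo;
  double sum = 0.0, sum2 = 0.0;
  for (int a = lo; a < hi; ++a) {
    const double v = y[idx[a]];
    sum += v; sum2 += v * v;
  }
  const int node = (int)T.feature.size();
  T.feature.push_back(-1);
  T.threshold.push_back(0.0);
  T.left.push_back(-1);
  T.right.push_back(-1);
  T.value.push_back(sum / n);

  const double sse = sum2 - sum * sum / n;
  if (n <= min_node || sse <= 1e-12) return node;

  const int p = X.ncol();
  // sample mtry features without replacement (partial Fisher-Yates)
  for (int j = 0; j < p; ++j) feats[j] = j;
  int best_f = -1;
  double best_gain = 0.0, best_thr = 0.0;
  for (int m = 0; m < mtry; ++m) {
    const int pick = m + runif_int(p - m);
    std::swap(feats[m], feats[pick]);
    const int f = feats[m];

    // order node samples by feature f
    ord.resize(n);
    for (int a = 0; a < n; ++a) ord[a] = idx[lo + a];
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return X(a, f) < X(b, f); });
    double sl = 0.0;
    for (int a = 0; a < n - 1; ++a) {
      sl += y[ord[a]];
      const double xa = X(ord[a], f), xb = X(ord[a + 1], f);
      if (xa >= xb) continue; // not a valid cut between ties
      const int nl = a + 1, nr = n - nl;
      const double sr = sum - sl;
      const double gain = sl * sl / nl + sr * sr / nr - sum * sum / n;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_f = f;
        best_thr = xa + (xb - xa) / 2.0;
      }
    }
  }
  if (best_f < 0) return node; // all sampled features constant on this node

  // partition idx[lo,hi) by the split
  int mid = lo;
  for (int a = lo; a < hi; ++a)
    if (X(idx[a], best_f) <= best_thr) std::swap(idx[a], idx[mid++]);
  if (mid == lo || mid == hi) return node; // numeric degeneracy guard

  T.feature[node] = best_f;
  T.threshold[node] = best_thr;
  const int l = grow(X, y, idx, lo, mid, mtry, min_node, T, feats, ord);
  T.left[node] = l;
  const int r = grow(X, y, idx, mid, hi, mtry, min_node, T, feats, ord);
  T.right[node] = r;
  return node;
}

inline double tree_pred_row(const TreeBuf& T, const NumericMatrix& X, int i,
                            int swap_feat = -1, double swap_val = 0.0) {
  int node = 0;
  while (T.feature[node] >= 0) {
    const int f = T.feature[node];
    const double x = (f == swap_feat) ? swap_val : X(i, f);
    node = (x <= T.threshold[node]) ? T.left[node] : T.right[node];
  }
  return T.value[node];
}

NumericMatrix pack_tree(const TreeBuf& T) {
  const int m = (int)T.feature.size();
  NumericMatrix out(m, 5);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = T.feature[i];
    out(i, 1) = T.threshold[i];
    out(i, 2) = T.left[i];
    out(i, 3) = T.right[i];
    out(i, 4) = T.value[i];
  }
  return out;
}

inline double packed_pred_row(const NumericMatrix& T, const NumericMatrix& X,
                              int i) {
  int node = 0;
  while (T(node, 0) >= 0) {
    const int f = (int)T(node, 0);
    node = (X(i, f) <= T(node, 1)) ? (int)T(node, 2) : (int)T(node, 3);
  }
  return T(node, 4);
}

} // namespace

// Fit a regression forest. X: samples x features. Returns packed trees,
// out-of-bag predictions and (optionally) permutation importance computed
// on each tree's OOB samples.
// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int min_node, bool importance) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;

  List trees(ntree);
  NumericVector oob_sum(n, 0.0);
  IntegerVector oob_cnt(n, 0);
  NumericVector imp(p, 0.0);
  IntegerVector imp_cnt(p, 0);

  std::vector<int> idx(n), feats(p), ord, boot(n), oob;
  std::vector<char> inbag(n);
  std::vector<double> base_pred;

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      boot[i] = runif_int(n);
      inbag[boot[i]] = 1;
    }
    for (int i = 0; i < n; ++i) idx[i] = boot[i];

    TreeBuf T;
    grow(X, y, idx, 0, n, mtry, min_node, T, feats, ord);
    trees[t] = pack_tree(T);

    oob.clear();
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob.push_back(i);
    if (oob.empty()) continue;

    base_pred.resize(oob.size());
    double mse0 = 0.0;
    for (size_t a = 0; a < oob.size(); ++a) {
      base_pred[a] = tree_pred_row(T, X, oob[a]);
      const double e = base_pred[a] - y[oob[a]];
      mse0 += e * e;
      oob_sum[oob[a]] += base_pred[a];
      oob_cnt[oob[a]] += 1;
    }
    mse0 /= oob.size();

    if (importance) {
      const int no = (int)oob.size();
      std::vector<int> perm(no);
      for (int j = 0; j < p; ++j) {
        for (int a = 0; a < no; ++a) perm[a] = a;
        for (int a = no - 1; a > 0; --a)
          std::swap(perm[a], perm[runif_int(a + 1)]);
        double mse1 = 0.0;
        for (int a = 0; a < no; ++a) {
          const double xv = X(oob[perm[a]], j);
          const double e = tree_pred_row(T, X, oob[a], j, xv) - y[oob[a]];
          mse1 += e * e;
        }
        mse1 /= no;
        imp[j] += (mse1 - mse0);
        imp_cnt[j] += 1;
      }
    }
  }

  NumericVector oob_pred(n, NA_REAL);
  for (int i = 0; i < n; ++i)
    if (oob_cnt[i] > 0) oob_pred[i] = oob_sum[i] / oob_cnt[i];
  if (importance)
    for (int j = 0; j < p; ++j)
      if (imp_cnt[j] > 0) imp[j] /= imp_cnt[j];

  List out = List::create(_["trees"] = trees, _["oob_pred"] = oob_pred,
                          _["oob_count"] = oob_cnt,
                          _["importance"] = R_NilValue);
  if (importance) out["importance"] = imp;
  return out;
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), ntree = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix T = trees[t];
    for (int i = 0; i < n; ++i) out[i] += packed_pred_row(T, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}
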