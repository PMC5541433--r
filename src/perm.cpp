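#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Permutation kernels for Spearman edge tests, PERMANOVA and ANOSIM.
// All draws come from R's RNG stream (set.seed() on the R side).

namespace {
inline int runif_int(int n) {
  int k = (int)std::floor(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

inline double pearson(const double* a, const double* b, int n) {
  double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  for (int i = 0; i < n; ++i) {
    sa += a[i]; sb += b[i];
    saa += a[i] * a[i]; sbb += b[i] * b[i];
    sab += a[i] * b[i];
  }
  const double va = saa - sa * sa / n, vb = sbb - sb * sb / n;
  if (va <= 0 || vb <= 0) return NA_REAL;
  return (sab - sa * sb / n) / std::sqrt(va * vb);
}
} // namespace

// ranks: taxa x samples matrix of within-taxon average ranks.
// Returns Spearman rho (Pearson on ranks) and two-sided permutation p per
// pair; one margin's ranks are permuted independently per pair.
// [[Rcpp::export]]
List spearman_perm_cpp(NumericMatrix ranks, int nperm) {
  const int p = ranks.nrow(), n = ranks.ncol();
  NumericMatrix rho(p, p), pval(p, p);
  rho.fill_diag(1.0);
  pval.fill_diag(NA_REAL);

  std::vector<double> a(n), b(n), bp(n);
  for (int i = 0; i < p; ++i) {
    for (int k = 0; k < n; ++k) a[k] = ranks(i, k);
    for (int j = i + 1; j < p; ++j) {
      for (int k = 0; k < n; ++k) b[k] = ranks(j, k);
      const double r = pearson(a.data(), b.data(), n);
      rho(i, j) = rho(j, i) = r;
      if (!R_finite(r)) { pval(i, j) = pval(j, i) = NA_REAL; continue; }
      const double robs = std::fabs(r) - 1e-12;
      int cnt = 0;
      bp = b;
      for (int t = 0; t < nperm; ++t) {
        for (int k = n - 1; k > 0; --k)
          std::swap(bp[k], bp[runif_int(k + 1)]);
        const double rp = pearson(a.data(), bp.data(), n);
        if (R_finite(rp) && std::fabs(rp) >= robs) ++cnt;
      }
      pval(i, j) = pval(j, i) = (1.0 + cnt) / (1.0 + nperm);
    }
  }
  return List::create(_["rho"] = rho, _["p"] = pval);
}

namespace {
// pseudo-F from squared distances for a given labelling
double pseudo_f(const NumericMatrix& d2, const std::vector<int>& g,
                int ngroups, std::vector<double>& ssw_g,
                std::vector<int>& n_g) {
  const int n = d2.nrow();
  std::fill(ssw_g.begin(), ssw_g.end(), 0.0);
  std::fill(n_g.begin(), n_g.end(), 0);
  double sst = 0.0;
  for (int i = 0; i < n; ++i) {
    ++n_g[g[i]];
    for (int j = i + 1; j < n; ++j) {
      sst += d2(i, j);
      if (g[i] == g[j]) ssw_g[g[i]] += d2(i, j);
    }
  }
  sst /= n;
  double ssw = 0.0;
  for (int k = 0; k < ngroups; ++k)
    if (n_g[k] > 0) ssw += ssw_g[k] / n_g[k];
  const double ssa = sst - ssw;
  const int dfa = ngroups - 1, dfw = n - ngroups;
  if (ssw <= 0.0 || dfw <= 0) return R_PosInf;
  return (ssa / dfa) / (ssw / dfw);
}
} // namespace

// d2: n x n squared distance matrix; grp: 0-based integer labels.
// [[Rcpp::export]]
List permanova_perm_cpp(NumericMatrix d2, IntegerVector grp, int nperm) {
  const int n = d2.nrow();
  int ngroups = 0;
  std::vector<int> g(n);
  for (int i = 0; i < n; ++i) {
    g[i] = grp[i];
    ngroups = std::max(ngroups, g[i] + 1);
  }
  std::vector<double> ssw_g(ngroups);
  std::vector<int> n_g(ngroups);
  const double fobs = pseudo_f(d2, g, ngroups, ssw_g, n_g);
  int cnt = 0;
  std::vector<int> gp = g;
  for (int t = 0; t < nperm; ++t) {
    for (int k = n - 1; k > 0; --k)
      std::swap(gp[k], gp[runif_int(k + 1)]);
    if (pseudo_f(d2, gp, ngroups, ssw_g, n_g) >= fobs - 1e-12) ++cnt;
  }
  return List::create(_["statistic"] = fobs,
                      _["p"] = (1.0 + cnt) / (1.0 + nperm));
}

namespace {
// ANOSIM R from rank-transformed distances
double anosim_r(const NumericMatrix& rd, const std::vector<int>& g) {
  const int n = rd.nrow();
  double sb = 0, sw = 0;
  long nb = 0, nw = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (g[i] == g[j]) { sw += rd(i, j); ++nw; }
      else              { sb += rd(i, j); ++nb; }
    }
  if (nb == 0 || nw == 0) return NA_REAL;
  const double m = n * (n - 1) / 2.0;
  return (sb / nb - sw / nw) / (m / 2.0);
}
} // namespace

// rd: n x n matrix of average ranks of the n(n-1)/2 distances.
// [[Rcpp::export]]
List anosim_perm_cpp(NumericMatrix rd, IntegerVector grp, int nperm) {
  const int n = rd.nrow();
  std::vector<int> g(grp.begin(), grp.end());
  const double robs = anosim_r(rd, g);
  int cnt = 0;
  std::vector<int> gp = g;
  for (int t = 0; t < nperm; ++t) {
    for (int k = n - 1; k > 0; --k)
      std::swap(gp[k], gp[runif_int(k + 1)]);
    const double rp = anosim_r(rd, gp);
    if (R_finite(rp) && rp >= robs - 1e-12) ++cnt;
  }
  return List::create(_["statistic"] = robs,
                      _["p"] = (1.0 + cnt) / (1.0 + nperm));
}
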