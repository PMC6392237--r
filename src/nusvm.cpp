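// Binary nu-SVC trained by sequential minimal optimisation with the
// two-equality-constraint working-set scheme of Chang & Lin (2001): the
// scaled dual
//
//   min 1/2 a' Q a   s.t. 0 <= a_i <= 1,
//                         sum_{y_i=+1} a_i = sum_{y_i=-1} a_i = nu * n / 2
//
// with Q_ij = y_i y_j K(x_i, x_j), RBF kernel K = exp(-gamma ||xi - xj||^2).
// Working pairs are selected within one class (so both equality constraints
// are preserved), first variable by steepest feasible descent, second by a
// second-order gain criterion. Kernel rows are computed on demand and kept
// in a bounded cache.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

struct KernelCache {
  const NumericMatrix& X;   // n x d
  double gamma;
  std::vector<double> sqnorm;
  std::vector<std::vector<double> > rows;
  std::vector<int> slot_of;          // point -> slot or -1
  std::vector<int> point_in_slot;    // slot -> point
  size_t max_rows, next_evict;
  int n, d;

  KernelCache(const NumericMatrix& X_, double gamma_, size_t max_rows_)
    : X(X_), gamma(gamma_), max_rows(max_rows_ < 2 ? 2 : max_rows_),
      next_evict(0) {
    n = X.nrow(); d = X.ncol();
    sqnorm.resize(n);
    for (int i = 0; i < n; ++i) {
      double s = 0;
      for (int k = 0; k < d; ++k) { double v = X(i, k); s += v * v; }
      sqnorm[i] = s;
    }
    if (max_rows > (size_t)n) max_rows = n;
    rows.resize(max_rows);
    slot_of.assign(n, -1);
    point_in_slot.assign(max_rows, -1);
  }

  const std::vector<double>& row(int i) {
    int s = slot_of[i];
    if (s >= 0) return rows[s];
    s = (int)next_evict;
    next_evict = (next_evict + 1) % max_rows;
    int old = point_in_slot[s];
    if (old >= 0) slot_of[old] = -1;
    point_in_slot[s] = i;
    slot_of[i] = s;
    std::vector<double>& r = rows[s];
    r.resize(n);
    for (int j = 0; j < n; ++j) {
      double dot = 0;
      for (int k = 0; k < d; ++k) dot += X(i, k) * X(j, k);
      r[j] = std::exp(-gamma * (sqnorm[i] + sqnorm[j] - 2.0 * dot));
    }
    return r;
  }
};

} // namespace

// [[Rcpp::export(name = ".nusvc_train_binary")]]
List nusvc_train_binary(NumericMatrix X, IntegerVector y, double nu,
                        double gamma, double eps = 1e-3,
                        int max_iter = 2000000, double cache_mb = 128.0) {
  const int n = X.nrow();
  if (y.size() != n) stop("y length mismatch");
  int npos = 0, nneg = 0;
  for (int i = 0; i < n; ++i) {
    if (y[i] == 1) ++npos; else if (y[i] == -1) ++nneg;
    else stop("y must be +1/-1");
  }
  double sum_each = nu * n / 2.0;
  double bound = std::min(npos, nneg);
  if (sum_each > bound + 1e-12)
    stop("nu = %f infeasible: requires nu <= 2*min(n+, n-)/n = %f",
         nu, 2.0 * bound / n);

  size_t cache_rows = (size_t)std::max(2.0, cache_mb * 131072.0 / n);
  KernelCache K(X, gamma, cache_rows);

  // initial feasible point: fill alphas class by class
  std::vector<double> alpha(n, 0.0);
  double left = sum_each;
  for (int i = 0; i < n && left > 0; ++i)
    if (y[i] == 1) { alpha[i] = std::min(1.0, left); left -= alpha[i]; }
  left = sum_each;
  for (int i = 0; i < n && left > 0; ++i)
    if (y[i] == -1) { alpha[i] = std::min(1.0, left); left -= alpha[i]; }

  // gradient G_i = (Q alpha)_i
  std::vector<double> G(n, 0.0);
  for (int j = 0; j < n; ++j) {
    if (alpha[j] == 0.0) continue;
    const std::vector<double>& kj = K.row(j);
    double ayj = alpha[j] * y[j];
    for (int i = 0; i < n; ++i) G[i] += y[i] * ayj * kj[i];
  }

  const double TAU = 1e-12;
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // per-class maximal violation and steepest i
    int i_sel = -1, cls_sel = 0;
    double worst = eps;
    int i_c[2] = {-1, -1};
    double viol_c[2];
    for (int c = 0; c < 2; ++c) {
      int ysign = c == 0 ? 1 : -1;
      double gmin = std::numeric_limits<double>::infinity();
      double gmax = -std::numeric_limits<double>::infinity();
      int imin = -1;
      for (int i = 0; i < n; ++i) {
        if (y[i] != ysign) continue;
        if (alpha[i] < 1.0 && G[i] < gmin) { gmin = G[i]; imin = i; }
        if (alpha[i] > 0.0 && G[i] > gmax) gmax = G[i];
      }
      i_c[c] = imin;
      viol_c[c] = gmax - gmin;
    }
    // try the more violating class first; fall back to the other
    int order[2] = {viol_c[0] >= viol_c[1] ? 0 : 1,
                    viol_c[0] >= viol_c[1] ? 1 : 0};
    int j_sel = -1;
    std::vector<double> ki;   // copy: row i must survive loading row j
    for (int oc = 0; oc < 2 && j_sel < 0; ++oc) {
      int c = order[oc];
      if (i_c[c] < 0 || viol_c[c] <= worst) continue;
      i_sel = i_c[c]; cls_sel = c == 0 ? 1 : -1;
      ki = K.row(i_sel);
      // second-order choice of j within the class
      double best_gain = 0.0;
      for (int j = 0; j < n; ++j) {
        if (y[j] != cls_sel || alpha[j] <= 0.0) continue;
        double diff = G[j] - G[i_sel];
        if (diff <= 0) continue;
        double quad = 2.0 - 2.0 * ki[j];   // Kii + Kjj - 2Kij, RBF diag = 1
        if (quad < TAU) quad = TAU;
        double gain = diff * diff / quad;
        if (gain > best_gain) { best_gain = gain; j_sel = j; }
      }
    }
    if (j_sel < 0) break;   // KKT satisfied within eps (or no descent pair)

    double quad = 2.0 - 2.0 * ki[j_sel];
    if (quad < TAU) quad = TAU;
    double t = (G[j_sel] - G[i_sel]) / quad;
    t = std::min(t, std::min(1.0 - alpha[i_sel], alpha[j_sel]));
    if (t <= 0) break;
    alpha[i_sel] += t;
    alpha[j_sel] -= t;
    const std::vector<double>& kj = K.row(j_sel);
    int yi = y[i_sel];
    for (int m = 0; m < n; ++m)
      G[m] += t * y[m] * yi * (ki[m] - kj[m]);
  }

  // thresholds per class from free SVs (fallback: bound midpoints)
  double r[2];
  for (int c = 0; c < 2; ++c) {
    int ysign = c == 0 ? 1 : -1;
    double sum = 0; int nfree = 0;
    double ub = std::numeric_limits<double>::infinity();
    double lb = -std::numeric_limits<double>::infinity();
    for (int i = 0; i < n; ++i) {
      if (y[i] != ysign) continue;
      if (alpha[i] > 0.0 && alpha[i] < 1.0) { sum += G[i]; ++nfree; }
      if (alpha[i] < 1.0) ub = std::min(ub, G[i]);
      if (alpha[i] > 0.0) lb = std::max(lb, G[i]);
    }
    r[c] = nfree > 0 ? sum / nfree : (ub + lb) / 2.0;
  }
  // pos free SVs: sum_j y_j a_j K(x_i, .) = r[0]; neg: = -r[1]
  double b = -(r[0] - r[1]) / 2.0;

  std::vector<int> sv;
  for (int i = 0; i < n; ++i) if (alpha[i] > 0) sv.push_back(i);
  NumericVector coef(sv.size());
  IntegerVector svi(sv.size());
  for (size_t k = 0; k < sv.size(); ++k) {
    svi[k] = sv[k] + 1;                  // 1-based for R
    coef[k] = alpha[sv[k]] * y[sv[k]];
  }
  return List::create(_["sv_index"] = svi, _["coef"] = coef, _["b"] = b,
                      _["iterations"] = iter, _["n_sv"] = (int)sv.size(),
                      _["rho"] = (r[0] + r[1]) / 2.0,
                      _["converged"] = iter < max_iter);
}

// [[Rcpp::export(name = ".rbf_decision")]]
NumericVector rbf_decision(NumericMatrix SV, NumericVector coef, double b,
                           double gamma, NumericMatrix Xnew) {
  const int nsv = SV.nrow(), d = SV.ncol(), m = Xnew.nrow();
  if (Xnew.ncol() != d) stop("feature-count mismatch");
  std::vector<double> svn(nsv);
  for (int i = 0; i < nsv; ++i) {
    double s = 0;
    for (int k = 0; k < d; ++k) { double v = SV(i, k); s += v * v; }
    svn[i] = s;
  }
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    double xn = 0;
    for (int k = 0; k < d; ++k) { double v = Xnew(j, k); xn += v * v; }
    double f = b;
    for (int i = 0; i < nsv; ++i) {
      double dot = 0;
      for (int k = 0; k < d; ++k) dot += SV(i, k) * Xnew(j, k);
      f += coef[i] * std::exp(-gamma * (svn[i] + xn - 2.0 * dot));
    }
    out[j] = f;
  }
  return out;
}
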