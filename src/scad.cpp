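#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// SCAD penalty rho_{lambda,gamma}(|b|), piecewise in |b|.
static inline double scad_rho(double b, double lam, double gam) {
  double a = std::fabs(b);
  if (a < lam) return lam * a;
  if (a < gam * lam)
    return -(a * a - 2.0 * gam * lam * a + lam * lam) / (2.0 * (gam - 1.0));
  return (gam + 1.0) * lam * lam / 2.0;
}

// Closed-form minimizer of 0.5*(b - z)^2 + rho_{lambda,gamma}(|b|)
// (the univariate SCAD thresholding rule for a standardized coordinate).
static inline double scad_thresh(double z, double lam, double gam) {
  double az = std::fabs(z);
  double s = (z > 0) ? 1.0 : -1.0;
  if (az <= 2.0 * lam) {
    double d = az - lam;
    return d > 0 ? s * d : 0.0;
  }
  if (az <= gam * lam)
    return s * ((gam - 1.0) * az - gam * lam) / (gam - 2.0);
  return z;
}

// One coordinate-descent sweep over the coordinates listed in idx.
// Returns the largest coefficient change.
static double cd_sweep(const NumericMatrix& X, std::vector<double>& r,
                       std::vector<double>& b, const std::vector<int>& idx,
                       int n, double lam, double gam) {
  double maxdiff = 0.0;
  for (int k = 0; k < (int)idx.size(); ++k) {
    int j = idx[k];
    const double* xj = &X(0, j);
    double dot = 0.0;
    for (int i = 0; i < n; ++i) dot += xj[i] * r[i];
    double z = dot / n + b[j];
    double bnew = scad_thresh(z, lam, gam);
    double d = bnew - b[j];
    if (d != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
      b[j] = bnew;
      double ad = std::fabs(d);
      if (ad > maxdiff) maxdiff = ad;
    }
  }
  return maxdiff;
}

// Coordinate descent for SCAD-penalized least squares along a decreasing
// lambda path with warm starts and active-set cycling. X must be
// column-standardized (mean 0, population sd 1) and y centered; the
// objective is RSS/(2n) + sum_j rho_{lambda,gamma}(|b_j|). The path stops
// early once a solution has more than dfMax nonzeros (denser fits are never
// eligible for selection); nSolved reports how many path points were run.
// [[Rcpp::export(name = ".scadCdPath")]]
List scadCdPath(const NumericMatrix& X, const NumericVector& y,
                const NumericVector& lambda, double gamma,
                double eps, int maxIter, int dfMax, bool recordObjective) {
  const int n = X.nrow(), m = X.ncol(), L = lambda.size();
  NumericMatrix beta(m, L);
  IntegerVector iters(L);
  LogicalVector conv(L);
  std::vector<double> objTrace;

  std::vector<double> b(m, 0.0), r(y.begin(), y.end());
  std::vector<int> all(m);
  for (int j = 0; j < m; ++j) all[j] = j;

  int nSolved = 0;
  for (int l = 0; l < L; ++l) {
    double lam = lambda[l];
    int it = 0;
    bool ok = false;
    while (it < maxIter) {
      ++it;
      double maxdiff = cd_sweep(X, r, b, all, n, lam, gamma);
      if (recordObjective && L == 1) {
        double rss = 0.0, pen = 0.0;
        for (int i = 0; i < n; ++i) rss += r[i] * r[i];
        for (int j = 0; j < m; ++j) pen += scad_rho(b[j], lam, gamma);
        objTrace.push_back(rss / (2.0 * n) + pen);
      }
      if (maxdiff < eps) { ok = true; break; }
      // cycle on the active set until it stabilizes, then re-check all
      std::vector<int> act;
      for (int j = 0; j < m; ++j) if (b[j] != 0.0) act.push_back(j);
      while (it < maxIter && !act.empty()) {
        ++it;
        double d2 = cd_sweep(X, r, b, act, n, lam, gamma);
        if (recordObjective && L == 1) {
          double rss = 0.0, pen = 0.0;
          for (int i = 0; i < n; ++i) rss += r[i] * r[i];
          for (int j = 0; j < m; ++j) pen += scad_rho(b[j], lam, gamma);
          objTrace.push_back(rss / (2.0 * n) + pen);
        }
        if (d2 < eps) break;
      }
    }
    iters[l] = it;
    conv[l] = ok;
    int nnz = 0;
    for (int j = 0; j < m; ++j) {
      beta(j, l) = b[j];
      if (b[j] != 0.0) ++nnz;
    }
    nSolved = l + 1;
    if (dfMax > 0 && nnz > dfMax && l < L - 1) break;
  }

  return List::create(_["beta"] = beta, _["iter"] = iters,
                      _["converged"] = conv, _["nSolved"] = nSolved,
                      _["objective"] = NumericVector(objTrace.begin(),
                                                     objTrace.end()));
}
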