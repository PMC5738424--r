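// Sequential minimal optimization for epsilon-SVR with a precomputed
// (linear) kernel, following the libsvm dual formulation:
//
//   min_{a in R^{2l}}  1/2 a' Qhat a + p' a
//   s.t.  z' a = 0,  0 <= a_k <= C
//
// with z = [+1,...,+1,-1,...,-1], Qhat_kl = z_k z_l K_{i(k) i(l)},
// p = [eps - y; eps + y].  beta = alpha - alpha* gives the usual SV
// coefficients; for a linear kernel w = X' beta.  First-order maximal
// violating pair selection, stopping tolerance as in libsvm (1e-3).
//
// Everything downstream (LOOCV, permutation nulls) only needs the Gram
// matrix K = X X', so the permutation loops reuse K and stay in C++.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const double TAU = 1e-12;

struct SvrFit {
  std::vector<double> beta;
  double b;
  int iter;
  bool converged;
};

// K: l x l kernel (column-major, contiguous); y: l labels.
SvrFit smo_solve(const double* K, const double* y, int l,
                 double C, double eps, double tol, int max_iter) {
  const int m = 2 * l;
  std::vector<double> a(m, 0.0), G(m);
  for (int k = 0; k < l; ++k) {
    G[k] = eps - y[k];
    G[k + l] = eps + y[k];
  }
  auto zsign = [l](int k) { return k < l ? 1.0 : -1.0; };
  auto idx = [l](int k) { return k < l ? k : k - l; };

  int iter = 0;
  bool converged = false;
  for (; iter < max_iter; ++iter) {
    // working set: i maximizes -z_k G_k over I_up, j maximizes z_k G_k over I_low
    double Gmax = -HUGE_VAL, Gmax2 = -HUGE_VAL;
    int i = -1, j = -1;
    for (int k = 0; k < m; ++k) {
      const double zk = zsign(k);
      const bool up = (zk > 0) ? (a[k] < C) : (a[k] > 0);
      const bool low = (zk > 0) ? (a[k] > 0) : (a[k] < C);
      const double v = -zk * G[k];
      if (up && v > Gmax) { Gmax = v; i = k; }
      if (low && -v > Gmax2) { Gmax2 = -v; j = k; }
    }
    if (Gmax + Gmax2 < tol || i < 0 || j < 0) { converged = true; break; }

    const int ii = idx(i), ij = idx(j);
    const double zi = zsign(i), zj = zsign(j);
    const double Kii = K[ii + (size_t)l * ii];
    const double Kjj = K[ij + (size_t)l * ij];
    const double Kij = K[ii + (size_t)l * ij];
    const double Qij = zi * zj * Kij;  // Qhat_ij
    const double old_ai = a[i], old_aj = a[j];

    if (zi != zj) {
      double quad = Kii + Kjj + 2.0 * Qij;
      if (quad <= 0) quad = TAU;
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = a[i] - a[j];
      a[i] += delta; a[j] += delta;
      if (diff > 0) {
        if (a[j] < 0) { a[j] = 0; a[i] = diff; }
      } else {
        if (a[i] < 0) { a[i] = 0; a[j] = -diff; }
      }
      if (diff > 0) {
        if (a[i] > C) { a[i] = C; a[j] = C - diff; }
      } else {
        if (a[j] > C) { a[j] = C; a[i] = C + diff; }
      }
    } else {
      double quad = Kii + Kjj - 2.0 * Qij;
      if (quad <= 0) quad = TAU;
      const double delta = (G[i] - G[j]) / quad;
      const double sum = a[i] + a[j];
      a[i] -= delta; a[j] += delta;
      if (sum > C) {
        if (a[i] > C) { a[i] = C; a[j] = sum - C; }
      } else {
        if (a[j] < 0) { a[j] = 0; a[i] = sum; }
      }
      if (sum > C) {
        if (a[j] > C) { a[j] = C; a[i] = sum - C; }
      } else {
        if (a[i] < 0) { a[i] = 0; a[j] = sum; }
      }
    }

    const double dai = a[i] - old_ai, daj = a[j] - old_aj;
    if (dai == 0 && daj == 0) { converged = true; break; }
    const double* Ki = K + (size_t)l * ii;
    const double* Kj = K + (size_t)l * ij;
    for (int k = 0; k < m; ++k) {
      const double kr = (k < l) ? 1.0 : -1.0;  // z_k
      const int rk = idx(k);
      G[k] += kr * (zi * dai * Ki[rk] + zj * daj * Kj[rk]);
    }
  }

  SvrFit fit;
  fit.beta.resize(l);
  for (int k = 0; k < l; ++k) fit.beta[k] = a[k] - a[k + l];
  fit.iter = iter;
  fit.converged = converged;

  // bias from KKT conditions on free / bound support vectors
  const double tiny = 1e-12 * (C > 0 ? C : 1.0);
  double freesum = 0.0; int nfree = 0;
  double lb = -HUGE_VAL, ub = HUGE_VAL;
  for (int k = 0; k < l; ++k) {
    double f = 0.0;
    const double* col = K + (size_t)l * k;  // symmetric: column = row
    for (int j2 = 0; j2 < l; ++j2) f += fit.beta[j2] * col[j2];
    const double e = y[k] - f;
    const double al = a[k], as = a[k + l];
    if (al > tiny && al < C - tiny) { freesum += e - eps; ++nfree; }
    if (as > tiny && as < C - tiny) { freesum += e + eps; ++nfree; }
    if (al <= tiny && as <= tiny) {
      if (e - eps > lb) lb = e - eps;
      if (e + eps < ub) ub = e + eps;
    }
    if (al >= C - tiny) { if (e - eps < ub) ub = e - eps; }
    if (as >= C - tiny) { if (e + eps > lb) lb = e + eps; }
  }
  if (nfree > 0) fit.b = freesum / nfree;
  else if (std::isfinite(lb) && std::isfinite(ub)) fit.b = (lb + ub) / 2.0;
  else if (std::isfinite(lb)) fit.b = lb;
  else if (std::isfinite(ub)) fit.b = ub;
  else fit.b = 0.0;
  return fit;
}

double pearson(const std::vector<double>& x, const double* y, int n) {
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double sxy = 0, sxx = 0, syy = 0;
  for (int i = 0; i < n; ++i) {
    const double dx = x[i] - mx, dy = y[i] - my;
    sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
  }
  if (sxx <= 0 || syy <= 0) return 0.0;  // constant vector convention
  return sxy / std::sqrt(sxx * syy);
}

// leave-one-out predictions, given full kernel; sub-kernels built per fold
void loocv_preds(const double* K, const double* y, int n,
                 double C, double eps, double tol, int max_iter,
                 std::vector<double>& pred, std::vector<double>& subK,
                 std::vector<double>& suby) {
  const int ns = n - 1;
  subK.resize((size_t)ns * ns);
  suby.resize(ns);
  for (int out = 0; out < n; ++out) {
    int ci = 0;
    for (int j = 0; j < n; ++j) {
      if (j == out) continue;
      int ri = 0;
      const double* colj = K + (size_t)n * j;
      double* scol = subK.data() + (size_t)ns * ci;
      for (int i = 0; i < n; ++i) {
        if (i == out) continue;
        scol[ri++] = colj[i];
      }
      suby[ci++] = y[j];
    }
    SvrFit fit = smo_solve(subK.data(), suby.data(), ns, C, eps, tol, max_iter);
    double f = fit.b;
    int ci2 = 0;
    const double* colo = K + (size_t)n * out;
    for (int j = 0; j < n; ++j) {
      if (j == out) continue;
      f += fit.beta[ci2++] * colo[j];
    }
    pred[out] = f;
  }
}

}  // namespace

// [[Rcpp::export]]
List svr_smo_cpp(NumericMatrix K, NumericVector y, double C, double eps,
                 double tol, int max_iter) {
  const int l = K.nrow();
  if (K.ncol() != l || y.size() != l) stop("kernel/label dimension mismatch");
  SvrFit fit = smo_solve(REAL(K), REAL(y), l, C, eps, tol, max_iter);
  return List::create(_["beta"] = NumericVector(fit.beta.begin(), fit.beta.end()),
                      _["b"] = fit.b, _["iterations"] = fit.iter,
                      _["converged"] = fit.converged);
}

// [[Rcpp::export]]
NumericVector svr_loocv_cpp(NumericMatrix K, NumericVector y, double C,
                            double eps, double tol, int max_iter) {
  const int n = K.nrow();
  std::vector<double> pred(n), subK, suby;
  loocv_preds(REAL(K), REAL(y), n, C, eps, tol, max_iter, pred, subK, suby);
  return NumericVector(pred.begin(), pred.end());
}

// LOOCV accuracy (Pearson r of predictions vs labels) for each column of Yperm
// [[Rcpp::export]]
NumericVector svr_perm_loocv_cpp(NumericMatrix K, NumericMatrix Yperm, double C,
                                 double eps, double tol, int max_iter) {
  const int n = K.nrow(), P = Yperm.ncol();
  if (Yperm.nrow() != n) stop("permutation matrix row mismatch");
  NumericVector acc(P);
  std::vector<double> pred(n), subK, suby;
  for (int p = 0; p < P; ++p) {
    const double* yp = REAL(Yperm) + (size_t)n * p;
    loocv_preds(REAL(K), yp, n, C, eps, tol, max_iter, pred, subK, suby);
    acc[p] = pearson(pred, yp, n);
    if (p % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return acc;
}

// full-sample dual coefficients for each permuted label column
// [[Rcpp::export]]
NumericMatrix svr_perm_fit_cpp(NumericMatrix K, NumericMatrix Yperm, double C,
                               double eps, double tol, int max_iter) {
  const int n = K.nrow(), P = Yperm.ncol();
  if (Yperm.nrow() != n) stop("permutation matrix row mismatch");
  NumericMatrix B(n, P);
  for (int p = 0; p < P; ++p) {
    const double* yp = REAL(Yperm) + (size_t)n * p;
    SvrFit fit = smo_solve(REAL(K), yp, n, C, eps, tol, max_iter);
    std::copy(fit.beta.begin(), fit.beta.end(), B.begin() + (size_t)n * p);
    if (p % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return B;
}
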