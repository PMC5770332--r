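#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Linear C-SVC solved in the dual by SMO with maximal-violating-pair
// working-set selection (the classic LibSVM scheme).  Problems here are
// tiny (tens of trials), so the precomputed Gram matrix is cheap and the
// solver is exact and deterministic.

namespace {

struct SvcFit {
  std::vector<double> alpha; // alpha_i * y_i signed multipliers
  double b;
  int majority; // +1/-1, larger training class (tie -> +1)
};

// K: n x n Gram of the training rows, y in {-1,+1}
SvcFit smo_solve(const std::vector<double>& K, int n,
                 const std::vector<int>& y, double C,
                 double tol, int max_iter) {
  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  int iter = 0;
  while (iter++ < max_iter) {
    // working set: i = argmax_{t in I_up} -y_t G_t, j = argmin_{t in I_low}
    int i = -1, j = -1;
    double Gmax = -1e300, Gmin = 1e300;
    for (int t = 0; t < n; ++t) {
      bool up  = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
      bool low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < tol) break;

    double Kii = K[i * n + i], Kjj = K[j * n + j], Kij = K[i * n + j];
    double eta = Kii + Kjj - 2.0 * Kij;
    if (eta <= 0) eta = 1e-12;
    double ai = alpha[i], aj = alpha[j];
    double delta = (Gmax - Gmin) / eta; // step along (y_i e_i - y_j e_j)
    double ai_new = ai + y[i] * delta;
    double aj_new = aj - y[j] * delta;
    // clip to the box, preserving the equality constraint
    double sum_i = y[i] * ai + y[j] * aj; // conserved quantity
    if (ai_new < 0) ai_new = 0;
    if (ai_new > C) ai_new = C;
    aj_new = y[j] * (sum_i - y[i] * ai_new);
    if (aj_new < 0) { aj_new = 0; ai_new = y[i] * (sum_i - y[j] * aj_new); }
    if (aj_new > C) { aj_new = C; ai_new = y[i] * (sum_i - y[j] * aj_new); }
    if (ai_new < 0) ai_new = 0; else if (ai_new > C) ai_new = C;

    double di = y[i] * (ai_new - ai), dj = y[j] * (aj_new - aj);
    if (std::abs(di) < 1e-15 && std::abs(dj) < 1e-15) break;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (di * K[i * n + t] + dj * K[j * n + t]);
    alpha[i] = ai_new; alpha[j] = aj_new;
  }

  // bias from free support vectors, else midpoint of the KKT interval
  double b = 0.0; int nfree = 0;
  double ub = 1e300, lb = -1e300;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    if (alpha[t] > 0 && alpha[t] < C) { b += -yG; ++nfree; }
    else {
      bool up  = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
      bool low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
      if (up  && -yG < ub) ub = -yG;
      if (low && -yG > lb) lb = -yG;
    }
  }
  if (nfree > 0) b /= nfree;
  else b = (ub + lb) / 2.0;

  SvcFit fit;
  fit.alpha.resize(n);
  int npos = 0;
  for (int t = 0; t < n; ++t) {
    fit.alpha[t] = alpha[t] * y[t];
    if (y[t] == 1) ++npos;
  }
  fit.b = b;
  fit.majority = (2 * npos >= n) ? 1 : -1;
  return fit;
}

// Gram matrix of the rows of X (n x p, column-major from R)
std::vector<double> gram(const NumericMatrix& X) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) s += X(i, k) * X(j, k);
      K[(size_t)i * n + j] = s;
      K[(size_t)j * n + i] = s;
    }
  return K;
}

// decision value for test row r given training subset idx
inline int predict_one(const std::vector<double>& Kfull, int n_all,
                       const std::vector<int>& idx, const SvcFit& fit,
                       int r) {
  double d = fit.b;
  for (size_t s = 0; s < idx.size(); ++s)
    d += fit.alpha[s] * Kfull[(size_t)idx[s] * n_all + r];
  if (d > 0) return 1;
  if (d < 0) return -1;
  return fit.majority; // exact-zero tie -> majority training class
}

// cross-validated accuracy given fold ids (0..n_folds-1) and labels y
double cv_accuracy_impl(const std::vector<double>& Kfull, int n,
                        const std::vector<int>& y,
                        const std::vector<int>& fold, int n_folds,
                        double C, double tol, int max_iter,
                        bool* single_class_fold) {
  int correct = 0, total = 0;
  for (int f = 0; f < n_folds; ++f) {
    std::vector<int> tr, te;
    for (int t = 0; t < n; ++t) (fold[t] == f ? te : tr).push_back(t);
    if (te.empty()) continue;
    int npos = 0;
    std::vector<int> ytr(tr.size());
    for (size_t s = 0; s < tr.size(); ++s) {
      ytr[s] = y[tr[s]];
      if (ytr[s] == 1) ++npos;
    }
    if (npos == 0 || npos == (int)tr.size()) {
      if (single_class_fold) *single_class_fold = true;
      return NA_REAL;
    }
    std::vector<double> Ktr(tr.size() * tr.size());
    for (size_t a = 0; a < tr.size(); ++a)
      for (size_t bI = 0; bI < tr.size(); ++bI)
        Ktr[a * tr.size() + bI] = Kfull[(size_t)tr[a] * n + tr[bI]];
    SvcFit fit = smo_solve(Ktr, (int)tr.size(), ytr, C, tol, max_iter);
    for (size_t s = 0; s < te.size(); ++s) {
      int pred = predict_one(Kfull, n, tr, fit, te[s]);
      if (pred == y[te[s]]) ++correct;
      ++total;
    }
  }
  return total ? (double)correct / total : NA_REAL;
}

std::vector<int> as_pm1(const IntegerVector& y) {
  std::vector<int> out(y.size());
  for (int i = 0; i < y.size(); ++i) {
    if (y[i] != 1 && y[i] != -1) stop("labels must be coded +1/-1");
    out[i] = y[i];
  }
  return out;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".svc_train")]]
List svc_train(NumericMatrix X, IntegerVector y, double C = 1.0,
               double tol = 1e-4, int max_iter = 100000) {
  int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) != nrow(X)");
  std::vector<int> yy = as_pm1(y);
  std::vector<double> K = gram(X);
  SvcFit fit = smo_solve(K, n, yy, C, tol, max_iter);
  NumericVector w(p);
  for (int k = 0; k < p; ++k) {
    double s = 0.0;
    for (int t = 0; t < n; ++t) s += fit.alpha[t] * X(t, k);
    w[k] = s;
  }
  NumericVector av(n);
  for (int t = 0; t < n; ++t) av[t] = fit.alpha[t];
  return List::create(_["w"] = w, _["b"] = fit.b,
                      _["alpha_signed"] = av,
                      _["majority"] = fit.majority);
}

//' @noRd
// [[Rcpp::export(name = ".svc_cv_accuracy")]]
double svc_cv_accuracy(NumericMatrix X, IntegerVector y, IntegerVector fold,
                       int n_folds, double C = 1.0, double tol = 1e-4,
                       int max_iter = 100000) {
  int n = X.nrow();
  if (y.size() != n || fold.size() != n) stop("dimension mismatch");
  std::vector<double> K = gram(X);
  std::vector<int> yy = as_pm1(y), ff(n);
  for (int i = 0; i < n; ++i) ff[i] = fold[i];
  bool bad = false;
  double acc = cv_accuracy_impl(K, n, yy, ff, n_folds, C, tol, max_iter, &bad);
  if (bad) stop("a training fold contains a single class");
  return acc;
}

//' @noRd
// [[Rcpp::export(name = ".svc_cv_perm_accuracies")]]
NumericVector svc_cv_perm_accuracies(NumericMatrix X, IntegerMatrix perms,
                                     IntegerVector fold, int n_folds,
                                     double C = 1.0, double tol = 1e-4,
                                     int max_iter = 100000) {
  int n = X.nrow(), n_perm = perms.ncol();
  if (perms.nrow() != n || fold.size() != n) stop("dimension mismatch");
  std::vector<double> K = gram(X);
  std::vector<int> ff(n);
  for (int i = 0; i < n; ++i) ff[i] = fold[i];
  NumericVector out(n_perm);
  std::vector<int> yy(n);
  for (int pIdx = 0; pIdx < n_perm; ++pIdx) {
    for (int i = 0; i < n; ++i) {
      int v = perms(i, pIdx);
      if (v != 1 && v != -1) stop("labels must be coded +1/-1");
      yy[i] = v;
    }
    out[pIdx] = cv_accuracy_impl(K, n, yy, ff, n_folds, C, tol, max_iter,
                                 nullptr);
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".svc_transfer_accuracies")]]
NumericVector svc_transfer_accuracies(NumericMatrix Xtr, IntegerMatrix ytr_set,
                                      NumericMatrix Xte, IntegerVector yte,
                                      double C = 1.0, double tol = 1e-4,
                                      int max_iter = 100000) {
  int n = Xtr.nrow(), p = Xtr.ncol(), m = Xte.nrow(), nset = ytr_set.ncol();
  if (Xte.ncol() != p) stop("train and test feature spaces differ");
  if (ytr_set.nrow() != n || yte.size() != m) stop("dimension mismatch");
  std::vector<double> K = gram(Xtr);
  // cross Gram: m x n
  std::vector<double> Kx((size_t)m * n);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) s += Xte(i, k) * Xtr(j, k);
      Kx[(size_t)i * n + j] = s;
    }
  NumericVector out(nset);
  std::vector<int> yy(n);
  std::vector<int> yte2 = as_pm1(yte);
  for (int sIdx = 0; sIdx < nset; ++sIdx) {
    int npos = 0;
    for (int i = 0; i < n; ++i) {
      int v = ytr_set(i, sIdx);
      if (v != 1 && v != -1) stop("labels must be coded +1/-1");
      yy[i] = v;
      if (v == 1) ++npos;
    }
    if (npos == 0 || npos == n) { out[sIdx] = NA_REAL; continue; }
    SvcFit fit = smo_solve(K, n, yy, C, tol, max_iter);
    int correct = 0;
    for (int i = 0; i < m; ++i) {
      double d = fit.b;
      for (int j = 0; j < n; ++j) d += fit.alpha[j] * Kx[(size_t)i * n + j];
      int pred = d > 0 ? 1 : (d < 0 ? -1 : fit.majority);
      if (pred == yte2[i]) ++correct;
    }
    out[sIdx] = (double)correct / m;
  }
  return out;
}
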