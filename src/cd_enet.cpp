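// Cyclic coordinate descent for the elastic-net penalized least-squares
// objective
//
//   f(beta) = (1/(2n)) ||y - Z beta||^2
//           + lambda * ( alpha ||beta||_1 + (1 - alpha)/2 ||beta||_2^2 )
//
// solved on precomputed Gram quantities G = Z'Z, c = Z'y, y'y so that a
// leave-one-out fold is a rank-one downdate instead of a data copy.  The
// path solver warm-starts each lambda from the previous solution.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double soft_threshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// One elastic-net solve.  beta and gb (= G beta) are updated in place.
// Returns the number of full sweeps used, or -1 if the relative objective
// tolerance was not reached within maxit sweeps.
static int cd_solve(const double *G, const double *c, double yty, double n,
                    int p, double lambda, double alpha, double tol, int maxit,
                    double *beta, double *gb) {
  const double l1 = lambda * alpha;
  const double l2 = lambda * (1.0 - alpha);

  auto objective = [&]() -> double {
    double quad = 0.0, lin = 0.0, pen1 = 0.0, pen2 = 0.0;
    for (int j = 0; j < p; ++j) {
      quad += beta[j] * gb[j];
      lin += beta[j] * c[j];
      pen1 += std::fabs(beta[j]);
      pen2 += beta[j] * beta[j];
    }
    return (yty - 2.0 * lin + quad) / (2.0 * n) + l1 * pen1 + 0.5 * l2 * pen2;
  };

  double obj = objective();
  // Stop when either the relative objective decrease or the largest
  // scaled squared coefficient update of a sweep falls below tol (the
  // latter relative to the null variance y'y/n, as in glmnet).
  const double change_floor = tol * std::max(yty / n, 1e-12);
  for (int it = 1; it <= maxit; ++it) {
    double max_change = 0.0;
    for (int j = 0; j < p; ++j) {
      const double gjj = G[(size_t)j * p + j];
      if (gjj <= 0.0) {
        // constant-zero predictor: penalized optimum is 0
        beta[j] = 0.0;
        continue;
      }
      const double rho = (c[j] - gb[j] + gjj * beta[j]) / n;
      const double bj = soft_threshold(rho, l1) / (gjj / n + l2);
      const double d = bj - beta[j];
      if (d != 0.0) {
        const double *Gj = G + (size_t)j * p;
        for (int k = 0; k < p; ++k) gb[k] += Gj[k] * d;
        beta[j] = bj;
        const double ch = gjj / n * d * d;
        if (ch > max_change) max_change = ch;
      }
    }
    if (max_change <= change_floor) return it;
    const double objnew = objective();
    if (obj - objnew <= tol * std::max(std::fabs(obj), 1e-12)) return it;
    obj = objnew;
  }
  return -1;
}

static void gram_from_data(const NumericMatrix &Z, const NumericVector &y,
                           std::vector<double> &G, std::vector<double> &c,
                           double &yty) {
  const int n = Z.nrow(), p = Z.ncol();
  G.assign((size_t)p * p, 0.0);
  c.assign(p, 0.0);
  yty = 0.0;
  for (int j = 0; j < p; ++j) {
    for (int k = j; k < p; ++k) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, k);
      G[(size_t)j * p + k] = s;
      G[(size_t)k * p + j] = s;
    }
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, j) * y[i];
    c[j] = s;
  }
  for (int i = 0; i < n; ++i) yty += y[i] * y[i];
}

// [[Rcpp::export]]
List cd_enet_path_cpp(NumericMatrix Z, NumericVector y, NumericVector lambda,
                      double alpha, double tol, int maxit, bool warm) {
  const int n = Z.nrow(), p = Z.ncol(), L = lambda.size();
  std::vector<double> G, c;
  double yty;
  gram_from_data(Z, y, G, c, yty);

  NumericMatrix B(p, L);
  IntegerVector sweeps(L);
  std::vector<double> beta(p, 0.0), gb(p, 0.0);
  for (int l = 0; l < L; ++l) {
    if (!warm) {
      std::fill(beta.begin(), beta.end(), 0.0);
      std::fill(gb.begin(), gb.end(), 0.0);
    }
    int it = cd_solve(G.data(), c.data(), yty, (double)n, p, lambda[l], alpha,
                      tol, maxit, beta.data(), gb.data());
    if (it < 0)
      stop("coordinate descent did not converge within %d sweeps (lambda=%g)",
           maxit, lambda[l]);
    sweeps[l] = it;
    for (int j = 0; j < p; ++j) B(j, l) = beta[j];
  }
  return List::create(_["beta"] = B, _["sweeps"] = sweeps);
}

// Leave-one-out cross-validation over a lambda path: each observation is
// removed by a rank-one downdate of the Gram quantities, the whole path is
// refit on the remaining rows (warm-started along the path), and the
// squared prediction error on the held-out row is accumulated.
// [[Rcpp::export]]
NumericVector cd_enet_loocv_cpp(NumericMatrix Z, NumericVector y,
                                NumericVector lambda, double alpha, double tol,
                                int maxit) {
  const int n = Z.nrow(), p = Z.ncol(), L = lambda.size();
  if (n < 2) stop("leave-one-out cross-validation needs at least 2 rows");
  std::vector<double> G, c;
  double yty;
  gram_from_data(Z, y, G, c, yty);

  std::vector<double> Gi((size_t)p * p), ci(p), beta(p), gb(p);
  NumericVector cverr(L);
  for (int i = 0; i < n; ++i) {
    // downdate
    for (int j = 0; j < p; ++j) {
      const double zij = Z(i, j);
      ci[j] = c[j] - zij * y[i];
      for (int k = 0; k < p; ++k)
        Gi[(size_t)j * p + k] = G[(size_t)j * p + k] - zij * Z(i, k);
    }
    const double ytyi = yty - y[i] * y[i];
    std::fill(beta.begin(), beta.end(), 0.0);
    std::fill(gb.begin(), gb.end(), 0.0);
    for (int l = 0; l < L; ++l) {
      int it = cd_solve(Gi.data(), ci.data(), ytyi, (double)(n - 1), p,
                        lambda[l], alpha, tol, maxit, beta.data(), gb.data());
      if (it < 0)
        stop("coordinate descent did not converge within %d sweeps "
             "(fold %d, lambda=%g)",
             maxit, i + 1, lambda[l]);
      double pred = 0.0;
      for (int j = 0; j < p; ++j) pred += Z(i, j) * beta[j];
      const double e = y[i] - pred;
      cverr[l] += e * e;
    }
  }
  for (int l = 0; l < L; ++l) cverr[l] /= n;
  return cverr;
}
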