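#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One-way random-intercept Gaussian model with known observation precisions:
//   y_ij = mu + b_i + e_ij,  b_i ~ N(0, lambda * s2),  e_ij ~ N(0, s2 / w_ij).
// For fixed variance ratio lambda the profile over mu and s2 is analytic
// (Woodbury identity on the per-individual compound-symmetric blocks), so the
// ML fit reduces to a 1-D maximisation in lambda >= 0.

// Profile log-likelihood at a given lambda. Groups are contiguous: gstart has
// m+1 entries of 0-based offsets into y/w.
static double profile_loglik(const double *y, const double *w, const int *gstart,
                             int m, int n, double lambda,
                             double sum_log_invw,
                             double *sigma2_out) {
  // GLS mean
  double num = 0.0, den = 0.0;
  for (int i = 0; i < m; i++) {
    double s = 0.0, a = 0.0;
    for (int j = gstart[i]; j < gstart[i + 1]; j++) {
      s += w[j];
      a += w[j] * y[j];
    }
    double d = 1.0 + lambda * s;
    num += a / d;
    den += s / d;
  }
  double mu = num / den;

  // Quadratic form and log-determinant correction
  double Q = 0.0, logdet = 0.0;
  for (int i = 0; i < m; i++) {
    double s = 0.0, rw = 0.0;
    for (int j = gstart[i]; j < gstart[i + 1]; j++) {
      double r = y[j] - mu;
      Q += w[j] * r * r;
      rw += w[j] * r;
      s += w[j];
    }
    double d = 1.0 + lambda * s;
    Q -= lambda * rw * rw / d;
    logdet += std::log(d);
  }
  double sigma2 = Q / n;
  if (sigma2 < 1e-300) sigma2 = 1e-300;
  if (sigma2_out) *sigma2_out = sigma2;
  return -0.5 * (n * std::log(2.0 * M_PI) + n * std::log(sigma2) + n +
                 sum_log_invw + logdet);
}

struct VcFit {
  double lambda, sigma2, loglik_full, loglik_null, lrt;
};

static VcFit fit_one(const double *y, const double *w, const int *gstart,
                     int m, int n, double sum_log_invw) {
  VcFit out;
  double s2_null;
  double ll0 = profile_loglik(y, w, gstart, m, n, 0.0, sum_log_invw, &s2_null);

  // Coarse log-spaced grid, then golden-section refinement in the bracketing
  // interval. lambda is the ratio sigma2_individual / sigma2_residual.
  const int ngrid = 23;
  static const double grid[ngrid] = {
    1e-4, 3e-4, 1e-3, 3e-3, 0.01, 0.03, 0.1, 0.2, 0.4, 0.8,
    1.6, 3.2, 6.4, 12.8, 25.6, 51.2, 204.8, 1024.0,
    8192.0, 65536.0, 524288.0, 4194304.0, 33554432.0};
  double best_lam = 0.0, best_ll = ll0;
  int best_k = -1;
  for (int k = 0; k < ngrid; k++) {
    double ll = profile_loglik(y, w, gstart, m, n, grid[k], sum_log_invw, NULL);
    if (ll > best_ll) { best_ll = ll; best_lam = grid[k]; best_k = k; }
  }
  if (best_k >= 0) {
    double lo = (best_k == 0) ? 0.0 : grid[best_k - 1];
    double hi = (best_k == ngrid - 1) ? grid[ngrid - 1] * 8.0 : grid[best_k + 1];
    const double gr = 0.3819660112501051;  // 2 - golden ratio
    double a = lo, b = hi;
    double x1 = a + gr * (b - a), x2 = b - gr * (b - a);
    double f1 = profile_loglik(y, w, gstart, m, n, x1, sum_log_invw, NULL);
    double f2 = profile_loglik(y, w, gstart, m, n, x2, sum_log_invw, NULL);
    for (int it = 0; it < 60 && (b - a) > 1e-9 * (1.0 + b); it++) {
      if (f1 > f2) {
        b = x2; x2 = x1; f2 = f1;
        x1 = a + gr * (b - a);
        f1 = profile_loglik(y, w, gstart, m, n, x1, sum_log_invw, NULL);
      } else {
        a = x1; x1 = x2; f1 = f2;
        x2 = b - gr * (b - a);
        f2 = profile_loglik(y, w, gstart, m, n, x2, sum_log_invw, NULL);
      }
    }
    double lam = (f1 > f2) ? x1 : x2;
    double ll = (f1 > f2) ? f1 : f2;
    if (ll > best_ll) { best_ll = ll; best_lam = lam; }
  }

  double s2_full;
  out.loglik_full = profile_loglik(y, w, gstart, m, n, best_lam, sum_log_invw,
                                   &s2_full);
  if (out.loglik_full < ll0) {  // boundary wins
    best_lam = 0.0;
    out.loglik_full = ll0;
    s2_full = s2_null;
  }
  out.lambda = best_lam;
  out.sigma2 = s2_full;
  out.loglik_null = ll0;
  out.lrt = 2.0 * (out.loglik_full - ll0);
  if (out.lrt < 0) out.lrt = 0;
  return out;
}

// [[Rcpp::export]]
List fit_varcomp_cpp(NumericVector y, NumericVector w, IntegerVector gstart) {
  int n = y.size(), m = gstart.size() - 1;
  double slw = 0.0;
  for (int j = 0; j < n; j++) slw += -std::log(w[j]);
  VcFit f = fit_one(y.begin(), w.begin(), gstart.begin(), m, n, slw);
  return List::create(
      _["lambda"] = f.lambda,
      _["sigma2_residual"] = f.sigma2,
      _["sigma2_individual"] = f.lambda * f.sigma2,
      _["loglik_full"] = f.loglik_full,
      _["loglik_null"] = f.loglik_null,
      _["lrt"] = f.lrt);
}

// Parametric-bootstrap null distribution of the LRT statistic. The statistic
// is invariant to location and scale, so simulating with mu = 0, s2 = 1
// reproduces the null law for any fitted null model with the same design and
// weights. Uses R's RNG so set.seed() on the R side governs reproducibility.
// [[Rcpp::export]]
NumericVector rlrt_null_stats_cpp(NumericVector w, IntegerVector gstart,
                                  int nsim) {
  int n = w.size(), m = gstart.size() - 1;
  double slw = 0.0;
  for (int j = 0; j < n; j++) slw += -std::log(w[j]);
  std::vector<double> ysim(n), sqw(n);
  for (int j = 0; j < n; j++) sqw[j] = 1.0 / std::sqrt(w[j]);
  NumericVector stats(nsim);
  for (int b = 0; b < nsim; b++) {
    for (int j = 0; j < n; j++) ysim[j] = norm_rand() * sqw[j];
    VcFit f = fit_one(ysim.data(), w.begin(), gstart.begin(), m, n, slw);
    stats[b] = f.lrt;
  }
  return stats;
}
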