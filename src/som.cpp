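#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Classic online self-organizing map. The presentation order is drawn on the
// R side (one index per step) so all randomness stays under R's RNG; training
// here is fully deterministic given that order and the initial codebook.
//
// X:        n x d data matrix
// codebook: u x d initial codebook (modified copy returned)
// ux, uy:   unit coordinates in the plane (hex layout prepared in R)
// order:    0-based sample index presented at each step (length = total steps)
// alpha:    learning rate, linear decay alpha0 -> alpha1
// radius:   neighborhood radius, linear decay r0 -> r1 (Gaussian kernel)
// [[Rcpp::export]]
NumericMatrix som_train_cpp(NumericMatrix X, NumericMatrix codebook,
                            NumericVector ux, NumericVector uy,
                            IntegerVector order,
                            double alpha0, double alpha1,
                            double r0, double r1) {
  int n = X.nrow(), d = X.ncol(), u = codebook.nrow();
  int T = order.size();
  NumericMatrix cb = clone(codebook);

  // pairwise squared distances between units on the grid
  std::vector<double> ud2(u * u);
  for (int a = 0; a < u; a++)
    for (int b = 0; b < u; b++) {
      double dx = ux[a] - ux[b], dy = uy[a] - uy[b];
      ud2[a * u + b] = dx * dx + dy * dy;
    }

  for (int t = 0; t < T; t++) {
    double frac = (T > 1) ? (double)t / (double)(T - 1) : 0.0;
    double alpha = alpha0 + (alpha1 - alpha0) * frac;
    double r = r0 + (r1 - r0) * frac;
    if (r < 1e-8) r = 1e-8;
    double inv2r2 = 1.0 / (2.0 * r * r);

    int s = order[t];
    // best-matching unit
    int bmu = 0;
    double bestd = R_PosInf;
    for (int a = 0; a < u; a++) {
      double acc = 0.0;
      for (int k = 0; k < d; k++) {
        double diff = X(s, k) - cb(a, k);
        acc += diff * diff;
      }
      if (acc < bestd) { bestd = acc; bmu = a; }
    }
    // neighborhood update
    const double *row = &ud2[(size_t)bmu * u];
    for (int a = 0; a < u; a++) {
      double h = std::exp(-row[a] * inv2r2);
      if (h < 1e-6) continue;
      double ah = alpha * h;
      for (int k = 0; k < d; k++)
        cb(a, k) += ah * (X(s, k) - cb(a, k));
    }
  }
  return cb;
}

// Best-matching unit (0-based) and quantization error for a data set.
// [[Rcpp::export]]
List som_map_cpp(NumericMatrix X, NumericMatrix codebook) {
  int n = X.nrow(), d = X.ncol(), u = codebook.nrow();
  IntegerVector bmu(n);
  NumericVector dist(n);
  for (int s = 0; s < n; s++) {
    int best = 0;
    double bestd = R_PosInf;
    for (int a = 0; a < u; a++) {
      double acc = 0.0;
      for (int k = 0; k < d; k++) {
        double diff = X(s, k) - codebook(a, k);
        acc += diff * diff;
      }
      if (acc < bestd) { bestd = acc; best = a; }
    }
    bmu[s] = best;
    dist[s] = std::sqrt(bestd);
  }
  return List::create(_["unit"] = bmu, _["dist"] = dist);
}
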