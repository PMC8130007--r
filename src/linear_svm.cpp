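#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L2-regularized L1-loss (hinge) linear SVM
// (Hsieh et al., ICML 2008). Samples are the *columns* of a dgCMatrix so each
// coordinate update touches one contiguous slice of the CSC arrays. The bias
// term is handled by augmenting every sample with a constant feature, which
// the caller appends as the last row.
//
// Deterministic: the per-epoch permutation comes from an xorshift32 generator
// seeded from R, so results are bit-reproducible for a fixed seed.

static inline uint32_t xorshift32(uint32_t &s) {
  s ^= s << 13; s ^= s >> 17; s ^= s << 5;
  return s;
}

// [[Rcpp::export(name = ".svm_dcd")]]
NumericVector svm_dcd(S4 Xt, NumericVector y, double C,
                      double tol, int max_epochs, int seed) {
  IntegerVector dims = Xt.slot("Dim");
  const int p = dims[0];           // features (incl. bias row)
  const int n = dims[1];           // samples
  IntegerVector ip = Xt.slot("p");
  IntegerVector ii = Xt.slot("i");
  NumericVector xv = Xt.slot("x");
  if (y.size() != n) stop("label/sample length mismatch");

  std::vector<double> w(p, 0.0), alpha(n, 0.0), qd(n);
  for (int j = 0; j < n; ++j) {
    double s = 0.0;
    for (int k = ip[j]; k < ip[j + 1]; ++k) s += xv[k] * xv[k];
    qd[j] = s;
  }

  std::vector<int> order(n);
  for (int j = 0; j < n; ++j) order[j] = j;
  uint32_t rng = (uint32_t)seed;
  if (rng == 0) rng = 0x9e3779b9u;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    // Fisher-Yates shuffle of the visiting order
    for (int j = n - 1; j > 0; --j) {
      int k = (int)(xorshift32(rng) % (uint32_t)(j + 1));
      std::swap(order[j], order[k]);
    }
    double max_pg = 0.0;
    for (int idx = 0; idx < n; ++idx) {
      int j = order[idx];
      if (qd[j] <= 0.0) continue;
      double g = -1.0;  // y_j * w'x_j - 1
      for (int k = ip[j]; k < ip[j + 1]; ++k) g += w[ii[k]] * xv[k] * y[j];
      // projected gradient
      double pg = g;
      if (alpha[j] <= 0.0) pg = std::min(g, 0.0);
      else if (alpha[j] >= C) pg = std::max(g, 0.0);
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (std::fabs(pg) > 1e-12) {
        double a_old = alpha[j];
        double a_new = std::min(std::max(a_old - g / qd[j], 0.0), C);
        double d = (a_new - a_old) * y[j];
        if (d != 0.0) {
          for (int k = ip[j]; k < ip[j + 1]; ++k) w[ii[k]] += d * xv[k];
          alpha[j] = a_new;
        }
      }
    }
    if (max_pg < tol) break;
  }
  return NumericVector(w.begin(), w.end());
}
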