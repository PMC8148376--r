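#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sinc(double t) {
  // sin(t)/t with the analytic t -> 0 limit
  if (std::fabs(t) < 1e-8) return 1.0 - t * t / 6.0;
  return std::sin(t) / t;
}

// Debye formula: I(q) = sum_i sum_j f_i(q) f_j(q) sinc(q r_ij).
// `ff` is an n x nq matrix of per-scatterer form factors on the q grid
// (constant form factors are passed as a recycled matrix from R).
// [[Rcpp::export]]
NumericVector debye_intensity_cpp(NumericMatrix coords, NumericMatrix ff,
                                  NumericVector q) {
  int n = coords.nrow(), nq = q.size();
  NumericVector I(nq);
  // diagonal terms
  for (int k = 0; k < nq; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += ff(i, k) * ff(i, k);
    I[k] = s;
  }
  // off-diagonal terms (symmetric, counted twice)
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      double dz = coords(i, 2) - coords(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      for (int k = 0; k < nq; ++k)
        I[k] += 2.0 * ff(i, k) * ff(j, k) * sinc(q[k] * r);
    }
  }
  return I;
}

// Frame-averaged Debye intensity over an ensemble stored as a
// n_frames x n x 3 array (column-major, as an R array).
// [[Rcpp::export]]
NumericVector debye_ensemble_cpp(NumericVector frames, int n_frames, int n,
                                 NumericMatrix ff, NumericVector q) {
  int nq = q.size();
  NumericVector I(nq);
  NumericMatrix conf(n, 3);
  for (int f = 0; f < n_frames; ++f) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        conf(i, d) = frames[f + (R_xlen_t)n_frames * (d * (R_xlen_t)n + i)];
    NumericVector If = debye_intensity_cpp(conf, ff, q);
    for (int k = 0; k < nq; ++k) I[k] += If[k];
  }
  for (int k = 0; k < nq; ++k) I[k] /= n_frames;
  return I;
}
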