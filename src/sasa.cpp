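#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area with a deterministic
// golden-spiral quadrature point set, so results are bit-reproducible.
// A test point on bead i's expanded sphere (radius r_i + probe) counts as
// accessible when it lies outside every other bead's expanded sphere.
// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix coords, NumericVector radii,
                       double probe, int n_points) {
  int n = coords.nrow();
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));  // golden angle
  for (int k = 0; k < n_points; ++k) {
    double zz = 1.0 - 2.0 * (k + 0.5) / n_points;
    double rr = std::sqrt(std::max(0.0, 1.0 - zz * zz));
    double phi = ga * k;
    px[k] = rr * std::cos(phi);
    py[k] = rr * std::sin(phi);
    pz[k] = zz;
  }

  NumericVector area(n);
  std::vector<double> Rexp(n);
  for (int i = 0; i < n; ++i) Rexp[i] = radii[i] + probe;

  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      double dz = coords(i, 2) - coords(j, 2);
      double lim = Rexp[i] + Rexp[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nbr.push_back(j);
    }
    int n_acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double tx = coords(i, 0) + Rexp[i] * px[k];
      double ty = coords(i, 1) + Rexp[i] * py[k];
      double tz = coords(i, 2) + Rexp[i] * pz[k];
      bool buried = false;
      for (size_t m = 0; m < nbr.size(); ++m) {
        int j = nbr[m];
        double dx = tx - coords(j, 0);
        double dy = ty - coords(j, 1);
        double dz = tz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < Rexp[j] * Rexp[j]) {
          buried = true;
          break;
        }
      }
      if (!buried) ++n_acc;
    }
    area[i] = 4.0 * M_PI * Rexp[i] * Rexp[i] * n_acc / n_points;
  }
  return area;
}
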