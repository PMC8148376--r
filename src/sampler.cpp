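#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Coarse-grained chain Monte Carlo sampler.
//
// Energy model (all terms in kT):
//   * WCA excluded volume between beads |i-j| >= 2 (purely repulsive,
//     truncated-shifted LJ, cut at 2^(1/6) * sigma),
//   * uniform short-range square-well attraction of depth eps_attr for
//     r < attr_cutoff (constant inside the core, so it never competes
//     with the WCA wall),
//   * Debye-Hueckel screened Coulomb: q_i q_j * lB * exp(-r/lD) / r.
// Bonds are rigid (length fixed by construction): every trial move is a
// rigid rotation of a sub-chain, so bond lengths are preserved exactly
// and internal distances within the moved block are unchanged -- the
// energy difference only involves moved x unmoved cross pairs.

struct PairPot {
  std::vector<double> radius;  // per-bead radius; sigma_ij = r_i + r_j
  double eps_wca;
  double eps_attr;
  double attr_cut2;
  double lB;
  double lD;
  bool   coulomb;

  double energy(double r2, int i, int j, double qi, double qj) const {
    double e = 0.0;
    double sig = radius[i] + radius[j];
    double sig2 = sig * sig;
    if (eps_wca > 0.0 && r2 < std::pow(2.0, 1.0 / 3.0) * sig2) {
      double s2 = sig2 / r2;
      double s6 = s2 * s2 * s2;
      e += 4.0 * eps_wca * (s6 * s6 - s6) + eps_wca;
    }
    if (r2 < attr_cut2) e -= eps_attr;
    if (coulomb && qi != 0.0 && qj != 0.0) {
      double r = std::sqrt(r2);
      e += qi * qj * lB * std::exp(-r / lD) / r;
    }
    return e;
  }
};

static inline double dist2(const std::vector<double>& x,
                           const std::vector<double>& y,
                           const std::vector<double>& z,
                           int i, int j) {
  double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
  return dx * dx + dy * dy + dz * dz;
}

// Energy between block [a, b] and the rest of the chain (pairs |i-j| >= 2).
static double cross_energy(const std::vector<double>& x,
                           const std::vector<double>& y,
                           const std::vector<double>& z,
                           const std::vector<double>& q,
                           int n, int a, int b, const PairPot& pot) {
  double e = 0.0;
  for (int i = a; i <= b; ++i) {
    for (int j = 0; j < n; ++j) {
      if (j >= a && j <= b) continue;
      if (std::abs(i - j) < 2) continue;
      e += pot.energy(dist2(x, y, z, i, j), i, j, q[i], q[j]);
    }
  }
  return e;
}

static double total_energy(const std::vector<double>& x,
                           const std::vector<double>& y,
                           const std::vector<double>& z,
                           const std::vector<double>& q,
                           int n, const PairPot& pot) {
  double e = 0.0;
  for (int i = 0; i < n - 2; ++i)
    for (int j = i + 2; j < n; ++j)
      e += pot.energy(dist2(x, y, z, i, j), i, j, q[i], q[j]);
  return e;
}

// Rotate points [a, b] about an axis through origin point (ox,oy,oz) with
// unit direction (ux,uy,uz) by angle theta (Rodrigues).
static void rotate_block(std::vector<double>& x, std::vector<double>& y,
                         std::vector<double>& z, int a, int b,
                         double ox, double oy, double oz,
                         double ux, double uy, double uz, double theta) {
  double c = std::cos(theta), s = std::sin(theta), omc = 1.0 - c;
  for (int i = a; i <= b; ++i) {
    double px = x[i] - ox, py = y[i] - oy, pz = z[i] - oz;
    double dot = ux * px + uy * py + uz * pz;
    double cx = uy * pz - uz * py;
    double cy = uz * px - ux * pz;
    double cz = ux * py - uy * px;
    x[i] = ox + px * c + cx * s + ux * dot * omc;
    y[i] = oy + py * c + cy * s + uy * dot * omc;
    z[i] = oz + pz * c + cz * s + uz * dot * omc;
  }
}

static void random_unit_vector(double& ux, double& uy, double& uz) {
  double n2;
  do {
    ux = 2.0 * R::unif_rand() - 1.0;
    uy = 2.0 * R::unif_rand() - 1.0;
    uz = 2.0 * R::unif_rand() - 1.0;
    n2 = ux * ux + uy * uy + uz * uz;
  } while (n2 < 1e-12 || n2 > 1.0);
  double inv = 1.0 / std::sqrt(n2);
  ux *= inv; uy *= inv; uz *= inv;
}

// [[Rcpp::export]]
List cg_sample_cpp(NumericMatrix coords0, NumericVector charges,
                   NumericVector bead_radii, double eps_wca, double eps_attr,
                   double attr_cutoff, double bjerrum, double debye,
                   int n_sweeps, int n_discard, int save_stride,
                   NumericVector move_weights, double pivot_max_angle,
                   double crank_max_angle) {
  int n = coords0.nrow();
  std::vector<double> x(n), y(n), z(n), q(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords0(i, 0); y[i] = coords0(i, 1); z[i] = coords0(i, 2);
    q[i] = charges[i];
  }

  PairPot pot;
  pot.radius.resize(n);
  for (int i = 0; i < n; ++i) pot.radius[i] = bead_radii[i];
  pot.eps_wca = eps_wca;
  pot.eps_attr = eps_attr;
  pot.attr_cut2 = attr_cutoff * attr_cutoff;
  pot.lB = bjerrum;
  pot.lD = debye;
  pot.coulomb = debye > 0.0 && bjerrum > 0.0;

  double w_pivot = move_weights[0], w_crank = move_weights[1];
  double w_sum = w_pivot + w_crank + move_weights[2];
  w_pivot /= w_sum; w_crank /= w_sum;

  int n_keep = 0;
  for (int s = n_discard; s < n_sweeps; ++s)
    if ((s - n_discard) % save_stride == 0) ++n_keep;
  if (n_keep < 1) n_keep = 1;
  NumericVector frames(n_keep * n * 3);
  int frame_idx = 0;

  long att[3] = {0, 0, 0}, acc[3] = {0, 0, 0};
  std::vector<double> xs(n), ys(n), zs(n);

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int mv = 0; mv < n; ++mv) {
      double u = R::unif_rand();
      int kind;       // 0 pivot, 1 crankshaft, 2 single-bead
      int a, b;       // moved block (inclusive)
      double ox, oy, oz, ux, uy, uz, theta;

      if (n >= 3 && u < w_pivot) {
        kind = 0;
        int p = 1 + (int)(R::unif_rand() * (n - 2));  // pivot bead, 1..n-2
        bool tail = R::unif_rand() < 0.5;
        if (tail) { a = p + 1; b = n - 1; } else { a = 0; b = p - 1; }
        ox = x[p]; oy = y[p]; oz = z[p];
        random_unit_vector(ux, uy, uz);
        theta = pivot_max_angle * (2.0 * R::unif_rand() - 1.0);
      } else if (n >= 3 && u < w_pivot + w_crank) {
        kind = 1;
        int i = (int)(R::unif_rand() * (n - 2));
        int maxlen = n - 1 - i;                       // j - i in [2, maxlen]
        int span = 2 + (int)(R::unif_rand() * (maxlen - 1));
        if (span > maxlen) span = maxlen;
        int j = i + span;
        a = i + 1; b = j - 1;
        ox = x[i]; oy = y[i]; oz = z[i];
        ux = x[j] - x[i]; uy = y[j] - y[i]; uz = z[j] - z[i];
        double nn = std::sqrt(ux * ux + uy * uy + uz * uz);
        if (nn < 1e-9) continue;
        ux /= nn; uy /= nn; uz /= nn;
        theta = crank_max_angle * (2.0 * R::unif_rand() - 1.0);
      } else {
        kind = 2;
        if (n < 3) continue;
        int i = (int)(R::unif_rand() * (n - 2));
        int j = i + 2;
        a = b = i + 1;
        ox = x[i]; oy = y[i]; oz = z[i];
        ux = x[j] - x[i]; uy = y[j] - y[i]; uz = z[j] - z[i];
        double nn = std::sqrt(ux * ux + uy * uy + uz * uz);
        if (nn < 1e-9) continue;
        ux /= nn; uy /= nn; uz /= nn;
        theta = crank_max_angle * (2.0 * R::unif_rand() - 1.0);
      }

      ++att[kind];
      double e_old = cross_energy(x, y, z, q, n, a, b, pot);
      for (int i = a; i <= b; ++i) { xs[i] = x[i]; ys[i] = y[i]; zs[i] = z[i]; }
      rotate_block(x, y, z, a, b, ox, oy, oz, ux, uy, uz, theta);
      double de = cross_energy(x, y, z, q, n, a, b, pot) - e_old;

      bool accept = de <= 0.0 ||
        (de < 50.0 && R::unif_rand() < std::exp(-de));
      if (accept) {
        ++acc[kind];
      } else {
        for (int i = a; i <= b; ++i) { x[i] = xs[i]; y[i] = ys[i]; z[i] = zs[i]; }
      }
    }

    if (sweep >= n_discard && (sweep - n_discard) % save_stride == 0 &&
        frame_idx < n_keep) {
      for (int i = 0; i < n; ++i) {
        frames[frame_idx + n_keep * (0L * n + i)] = x[i];
        frames[frame_idx + n_keep * (1L * n + i)] = y[i];
        frames[frame_idx + n_keep * (2L * n + i)] = z[i];
      }
      ++frame_idx;
    }
  }

  // frames laid out as [frame, bead, dim] for an R array dim = c(n_keep, n, 3)
  frames.attr("dim") = IntegerVector::create(frame_idx > 0 ? n_keep : 1, n, 3);

  double e_final = total_energy(x, y, z, q, n, pot);
  return List::create(
    _["frames"] = frames,
    _["n_frames"] = n_keep,
    _["attempted"] = NumericVector::create(att[0], att[1], att[2]),
    _["accepted"] = NumericVector::create(acc[0], acc[1], acc[2]),
    _["final_energy"] = e_final);
}
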