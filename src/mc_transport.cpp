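// Voxel photon Monte Carlo for the balloon-in-tissue phantom.
//
// Photon-only analog transport in the kerma approximation: free paths are
// sampled by exact ray tracing of the optical depth through the voxel grid
// (Amanatides-Woo stepping); interactions are photoelectric (absorption),
// incoherent (free-electron Klein-Nishina) and coherent (Thomson angular
// redistribution, no energy loss). Two dose estimators:
//   0 = track-length kerma: each path segment scores E * mu_tr * l / mass,
//   1 = interaction site: analog energy deposits at real collision sites.
// Photons falling below the cutoff deposit their remaining energy locally.
//
// Reproducibility: each history h draws from its own counter-based splitmix64
// stream seeded from (seed, h), so a fixed seed gives bit-identical results
// and paired runs over different phantoms share common random numbers
// history by history.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t state;
  explicit Rng(uint64_t s) : state(s) {}
  uint64_t next_u64() {
    uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  // uniform in [0, 1)
  double unif() { return (next_u64() >> 11) * (1.0 / 9007199254740992.0); }
};

inline uint64_t mix_seed(uint64_t seed, uint64_t h) {
  uint64_t z = seed ^ (h * 0xd1342543de82ef95ULL + 0x2545f4914f6cdd1dULL);
  z = (z ^ (z >> 33)) * 0xff51afd7ed558ccdULL;
  z = (z ^ (z >> 33)) * 0xc4ceb9fe1a85ec53ULL;
  return z ^ (z >> 33);
}

// rotate direction u by polar angle (ct, st) and azimuth phi
inline void rotate_dir(double* u, double ct, double st, double phi) {
  double cp = std::cos(phi), sp = std::sin(phi);
  double ux = u[0], uy = u[1], uz = u[2];
  if (std::fabs(uz) > 0.99999999) {
    u[0] = st * cp;
    u[1] = st * sp;
    u[2] = ct * (uz > 0 ? 1.0 : -1.0);
  } else {
    double denom = std::sqrt(1.0 - uz * uz);
    u[0] = ux * ct + st * (ux * uz * cp - uy * sp) / denom;
    u[1] = uy * ct + st * (uy * uz * cp + ux * sp) / denom;
    u[2] = uz * ct - st * denom * cp;
  }
  double n = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  u[0] /= n; u[1] /= n; u[2] /= n;
}

// Klein-Nishina: sample x = E'/E by rejection with a uniform proposal
inline double sample_kn(Rng& rng, double k, double& cos_theta) {
  double xmin = 1.0 / (1.0 + 2.0 * k);
  double M = xmin + 1.0 / xmin;
  double x, f;
  do {
    x = xmin + (1.0 - xmin) * rng.unif();
    double ct = 1.0 + 1.0 / k - 1.0 / (k * x);
    double s2 = 1.0 - ct * ct;
    f = x + 1.0 / x - s2;
  } while (rng.unif() * M > f);
  cos_theta = 1.0 + 1.0 / k - 1.0 / (k * x);
  return x;
}

// Coherent (Rayleigh) angular distribution: Thomson modulated by the square
// of a hydrogen-like (Thomas-Fermi screened) atomic form factor,
// [F(q)/F(0)]^2 = (1 + kappa * (1 - cos)) ^ -4 with
// kappa = (E * scr)^2 / 2 and scr the per-material screening constant
// (1/MeV). Sample cos from the form-factor part by inverse CDF, then reject
// on the Thomson term (1 + cos^2) / 2.
inline double sample_rayleigh(Rng& rng, double kappa) {
  double ct;
  if (kappa < 1e-12) {
    do {
      ct = 2.0 * rng.unif() - 1.0;
    } while (rng.unif() > 0.5 * (1.0 + ct * ct));
    return ct;
  }
  double tmax3 = std::pow(1.0 + 2.0 * kappa, -3.0);
  do {
    double u = rng.unif();
    double t = std::pow(tmax3 + u * (1.0 - tmax3), -1.0 / 3.0);
    ct = 1.0 - (t - 1.0) / kappa;
  } while (rng.unif() > 0.5 * (1.0 + ct * ct));
  return ct;
}

} // namespace

// [[Rcpp::export]]
List mc_transport_cpp(IntegerVector material_index, IntegerVector dims,
                      double voxel_cm, NumericVector origin,
                      NumericMatrix mu_tot, NumericMatrix mu_tr,
                      NumericMatrix f_pe, NumericMatrix f_coh,
                      NumericVector coh_scr, NumericVector density,
                      double loge0, double dloge,
                      NumericVector src_center, NumericVector src_half,
                      NumericVector spec_e, NumericVector spec_cdf,
                      double cutoff_mev, int estimator,
                      double n_hist_d, int n_batch, double seed_d,
                      double shell_bin_cm, int n_shell,
                      bool keep_batch_dose) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = static_cast<R_xlen_t>(nx) * ny * nz;
  const int n_mat = mu_tot.ncol();
  const int n_e = mu_tot.nrow();
  const long long n_hist = static_cast<long long>(n_hist_d);
  const uint64_t seed = static_cast<uint64_t>(seed_d);
  const double h = voxel_cm;

  // voxel -> radial shell bin (centre at the grid origin), voxel masses
  std::vector<int> shell_of(nvox);
  std::vector<double> shell_count(n_shell, 0.0);
  std::vector<double> inv_mass(n_mat);
  for (int m = 0; m < n_mat; ++m) {
    inv_mass[m] = 1.0 / (density[m] * h * h * h);
  }
  {
    R_xlen_t v = 0;
    for (int iz = 0; iz < nz; ++iz) {
      double z = origin[2] + iz * h;
      for (int iy = 0; iy < ny; ++iy) {
        double y = origin[1] + iy * h;
        for (int ix = 0; ix < nx; ++ix, ++v) {
          double x = origin[0] + ix * h;
          double r = std::sqrt(x * x + y * y + z * z);
          int b = static_cast<int>(r / shell_bin_cm);
          shell_of[v] = (b < n_shell) ? b : -1;
          if (b < n_shell) shell_count[b] += 1.0;
        }
      }
    }
  }

  std::vector<double> batch(nvox, 0.0), sum(nvox, 0.0), sumsq(nvox, 0.0);
  NumericMatrix shell_batch(n_shell, n_batch);
  NumericMatrix batch_dose; // optional per-batch voxel means
  if (keep_batch_dose) batch_dose = NumericMatrix(nvox, n_batch);

  const int* mat = INTEGER(material_index);
  const double kmec2 = 1.0 / 0.51099895;
  const int n_lines = spec_e.size();

  long long per_batch = n_hist / n_batch;
  long long done = 0;

  for (int b = 0; b < n_batch; ++b) {
    std::fill(batch.begin(), batch.end(), 0.0);
    double* shcol = &shell_batch(0, b);
    long long nb = (b == n_batch - 1) ? (n_hist - done) : per_batch;

    for (long long hh = 0; hh < nb; ++hh) {
      Rng rng(mix_seed(seed, static_cast<uint64_t>(done + hh)));

      // energy from the line spectrum
      double u = rng.unif();
      int lo = 0, hi = n_lines - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (spec_cdf[mid] < u) lo = mid + 1; else hi = mid;
      }
      double E = spec_e[lo];

      // emission point uniform in the source parallelepiped, isotropic dir
      double pos[3], dir[3];
      for (int i = 0; i < 3; ++i) {
        pos[i] = src_center[i] + (2.0 * rng.unif() - 1.0) * src_half[i];
      }
      double ct = 2.0 * rng.unif() - 1.0;
      double st = std::sqrt(1.0 - ct * ct);
      double phi = 2.0 * M_PI * rng.unif();
      dir[0] = st * std::cos(phi); dir[1] = st * std::sin(phi); dir[2] = ct;

      bool alive = true;
      while (alive) {
        // per-material coefficients at the current energy
        double le = std::log(E);
        double fi = (le - loge0) / dloge;
        int i0 = static_cast<int>(fi);
        if (i0 < 0) i0 = 0;
        if (i0 > n_e - 2) i0 = n_e - 2;
        double w1 = fi - i0;
        if (w1 < 0) w1 = 0; if (w1 > 1) w1 = 1;
        double mu_c[8], mutr_c[8], fpe_c[8], fcoh_c[8];
        for (int m = 0; m < n_mat; ++m) {
          mu_c[m] = (1 - w1) * mu_tot(i0, m) + w1 * mu_tot(i0 + 1, m);
          mutr_c[m] = (1 - w1) * mu_tr(i0, m) + w1 * mu_tr(i0 + 1, m);
          fpe_c[m] = (1 - w1) * f_pe(i0, m) + w1 * f_pe(i0 + 1, m);
          fcoh_c[m] = (1 - w1) * f_coh(i0, m) + w1 * f_coh(i0 + 1, m);
        }

        // ray-trace one free path
        double tau = -std::log(1.0 - rng.unif());
        int ix = static_cast<int>(std::floor((pos[0] - origin[0]) / h + 0.5));
        int iy = static_cast<int>(std::floor((pos[1] - origin[1]) / h + 0.5));
        int iz = static_cast<int>(std::floor((pos[2] - origin[2]) / h + 0.5));
        if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
          break; // emitted outside the grid
        }
        int stepx = dir[0] > 0 ? 1 : -1;
        int stepy = dir[1] > 0 ? 1 : -1;
        int stepz = dir[2] > 0 ? 1 : -1;
        const double big = 1e30;
        double tdx = dir[0] != 0 ? h / std::fabs(dir[0]) : big;
        double tdy = dir[1] != 0 ? h / std::fabs(dir[1]) : big;
        double tdz = dir[2] != 0 ? h / std::fabs(dir[2]) : big;
        double bx = origin[0] + (ix + 0.5 * stepx) * h;
        double by = origin[1] + (iy + 0.5 * stepy) * h;
        double bz = origin[2] + (iz + 0.5 * stepz) * h;
        double tmx = dir[0] != 0 ? (bx - pos[0]) / dir[0] : big;
        double tmy = dir[1] != 0 ? (by - pos[1]) / dir[1] : big;
        double tmz = dir[2] != 0 ? (bz - pos[2]) / dir[2] : big;
        double t = 0.0;
        bool interacted = false;

        while (true) {
          R_xlen_t v = static_cast<R_xlen_t>(iz) * nx * ny +
                       static_cast<R_xlen_t>(iy) * nx + ix;
          int m = mat[v] - 1;
          double mu = mu_c[m];
          double tedge = tmx < tmy ? (tmx < tmz ? tmx : tmz)
                                   : (tmy < tmz ? tmy : tmz);
          double seg = tedge - t;
          if (mu * seg >= tau) {
            double s = tau / mu;
            if (estimator == 0) {
              double dep = E * mutr_c[m] * s * inv_mass[m];
              batch[v] += dep;
              int sb = shell_of[v];
              if (sb >= 0) shcol[sb] += dep;
            }
            t += s;
            interacted = true;
            break;
          }
          if (estimator == 0 && seg > 0) {
            double dep = E * mutr_c[m] * seg * inv_mass[m];
            batch[v] += dep;
            int sb = shell_of[v];
            if (sb >= 0) shcol[sb] += dep;
          }
          tau -= mu * seg;
          t = tedge;
          if (tmx <= tmy && tmx <= tmz) {
            ix += stepx; tmx += tdx;
            if (ix < 0 || ix >= nx) break;
          } else if (tmy <= tmz) {
            iy += stepy; tmy += tdy;
            if (iy < 0 || iy >= ny) break;
          } else {
            iz += stepz; tmz += tdz;
            if (iz < 0 || iz >= nz) break;
          }
        }
        if (!interacted) break; // escaped the grid

        pos[0] += t * dir[0]; pos[1] += t * dir[1]; pos[2] += t * dir[2];
        R_xlen_t v = static_cast<R_xlen_t>(iz) * nx * ny +
                     static_cast<R_xlen_t>(iy) * nx + ix;
        int m = mat[v] - 1;
        int sb = shell_of[v];

        double u2 = rng.unif();
        if (u2 < fpe_c[m]) {
          // photoelectric absorption
          if (estimator == 1) {
            double dep = E * inv_mass[m];
            batch[v] += dep;
            if (sb >= 0) shcol[sb] += dep;
          }
          alive = false;
        } else if (u2 < fpe_c[m] + fcoh_c[m]) {
          // coherent: direction change only (forward-peaked)
          double es = E * coh_scr[m];
          double cs = sample_rayleigh(rng, 0.5 * es * es);
          rotate_dir(dir, cs, std::sqrt(1.0 - cs * cs),
                     2.0 * M_PI * rng.unif());
        } else {
          // incoherent: Klein-Nishina energy loss + deflection
          double k = E * kmec2;
          double cs;
          double x = sample_kn(rng, k, cs);
          if (estimator == 1) {
            double dep = E * (1.0 - x) * inv_mass[m];
            batch[v] += dep;
            if (sb >= 0) shcol[sb] += dep;
          }
          E *= x;
          if (E < cutoff_mev) {
            double dep = E * inv_mass[m];
            batch[v] += dep;
            if (sb >= 0) shcol[sb] += dep;
            alive = false;
          } else {
            double ss = 1.0 - cs * cs;
            rotate_dir(dir, cs, ss > 0 ? std::sqrt(ss) : 0.0,
                       2.0 * M_PI * rng.unif());
          }
        }
      }
    }

    // fold this batch into the running per-voxel moments
    double inv_nb = 1.0 / static_cast<double>(nb);
    for (R_xlen_t v = 0; v < nvox; ++v) {
      double mday = batch[v] * inv_nb;
      sum[v] += mday;
      sumsq[v] += mday * mday;
      if (keep_batch_dose) batch_dose(v, b) = mday;
    }
    for (int s = 0; s < n_shell; ++s) {
      shcol[s] *= inv_nb; // mean deposited per history, per shell
    }
    done += nb;
    Rcpp::checkUserInterrupt();
  }

  NumericVector dose(nvox), relunc(nvox);
  double invB = 1.0 / n_batch;
  for (R_xlen_t v = 0; v < nvox; ++v) {
    double mean = sum[v] * invB;
    dose[v] = mean;
    if (mean > 0 && n_batch > 1) {
      double var_b = (sumsq[v] * invB - mean * mean) *
                     n_batch / (n_batch - 1.0);
      relunc[v] = std::sqrt(var_b / n_batch) / mean;
    } else {
      relunc[v] = NA_REAL;
    }
  }

  return List::create(
    _["dose"] = dose, _["rel_uncertainty"] = relunc,
    _["shell_batch"] = shell_batch,
    _["shell_count"] = NumericVector(shell_count.begin(), shell_count.end()),
    _["batch_dose"] = keep_batch_dose ? batch_dose : NumericMatrix(0, 0));
}
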