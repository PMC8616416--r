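#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Photon transport in a depth-voxelized semi-infinite slab with a refractive
// top boundary. Properties may vary per depth voxel (mu_a includes any
// photosensitizer contribution); scattering is Henyey-Greenstein. Absorption
// is deposited continuously along each sub-step (exact Beer attenuation),
// which keeps the depth-resolved dose exact for depth-varying mu_a while the
// scattering free path is sampled from the local mu_s via optical-depth
// accounting. Randomness comes from a self-contained xoshiro256++ stream
// seeded from the caller-supplied integer, so the seed passed from R fully
// determines a run, bit-for-bit, on any platform.

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed into the full state
    for (int i = 0; i < 4; ++i) {
      seed += 0x9E3779B97f4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on the open interval (0, 1)
  inline double u01() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

struct Tallies {
  double escaped = 0.0;     // diffuse weight out through the top boundary
  double transmitted = 0.0; // weight past max depth
  double lateral = 0.0;     // weight lost through the lateral faces
  double residual = 0.0;    // weight discarded at the hard floor (no roulette)
};

inline double fresnel_R(double cosi, double n_in, double n_out) {
  // unpolarized Fresnel reflectance, photon inside medium n_in hitting
  // interface with n_out at incidence cosine cosi (>0)
  double sint2 = (n_in / n_out) * (n_in / n_out) * (1.0 - cosi * cosi);
  if (sint2 >= 1.0) return 1.0; // total internal reflection
  double cost = std::sqrt(1.0 - sint2);
  double rs = (n_in * cosi - n_out * cost) / (n_in * cosi + n_out * cost);
  double rp = (n_in * cost - n_out * cosi) / (n_in * cost + n_out * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

inline void hg_scatter(Xoshiro &rng, double g, double &ux, double &uy, double &uz) {
  double cost;
  if (std::fabs(g) < 1e-6) {
    cost = 2.0 * rng.u01() - 1.0;
  } else {
    double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.u01());
    cost = (1.0 + g * g - f * f) / (2.0 * g);
    if (cost > 1.0) cost = 1.0;
    if (cost < -1.0) cost = -1.0;
  }
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double phi = 2.0 * M_PI * rng.u01();
  double cosp = std::cos(phi), sinp = std::sin(phi);
  double ux1, uy1, uz1;
  if (std::fabs(uz) > 0.99999) {
    ux1 = sint * cosp;
    uy1 = sint * sinp;
    uz1 = cost * (uz > 0 ? 1.0 : -1.0);
  } else {
    double denom = std::sqrt(1.0 - uz * uz);
    ux1 = sint * (ux * uz * cosp - uy * sinp) / denom + ux * cost;
    uy1 = sint * (uy * uz * cosp + ux * sinp) / denom + uy * cost;
    uz1 = -sint * cosp * denom + uz * cost;
  }
  double norm = std::sqrt(ux1 * ux1 + uy1 * uy1 + uz1 * uz1);
  ux = ux1 / norm; uy = uy1 / norm; uz = uz1 / norm;
}

// Track one photon until it dies; deposits absorption into `absorbed`
// (column `batch` of a n_vox x n_batch matrix stored column-major).
inline void track_photon(Xoshiro &rng, double x, double y, double z, int iz,
                         double ux, double uy, double uz, double w,
                         const double *mu_a, const double *mu_s,
                         const double *g, int n_vox, double dz,
                         double n_med, double half_x, double half_y,
                         bool roulette, double rl_thresh, double rl_surv,
                         double *absorbed_col, Tallies &tl) {
  const double BIG = 1e30;
  const double W_FLOOR = 1e-12;
  // one-entry attenuation cache: successive full-voxel crossings at fixed
  // direction and mu_a share the same exp(-mu_a * s)
  double cache_mua = -1.0, cache_s = -1.0, cache_f = 1.0;
  while (true) {
    double tau = -std::log(rng.u01());
    // propagate until the sampled scattering optical depth is consumed
    while (true) {
      double mus_v = mu_s[iz];
      double mua_v = mu_a[iz];
      double s_b;
      if (uz > 1e-12) {
        s_b = ((double)(iz + 1) * dz - z) / uz;
      } else if (uz < -1e-12) {
        s_b = ((double)iz * dz - z) / uz;
      } else {
        s_b = BIG;
      }
      if (s_b < 0) s_b = 0; // numeric guard at voxel faces
      double s_sc = (mus_v > 0) ? tau / mus_v : BIG;
      bool hits_boundary = s_b < s_sc;
      double s = hits_boundary ? s_b : s_sc;
      if (mua_v > 0 && s > 0) {
        double f;
        if (mua_v == cache_mua && std::fabs(s - cache_s) < 1e-12 * (s + dz)) {
          f = cache_f;
        } else {
          f = std::exp(-mua_v * s);
          cache_mua = mua_v; cache_s = s; cache_f = f;
        }
        double dw = w * (1.0 - f);
        absorbed_col[iz] += dw;
        w -= dw;
      }
      x += ux * s; y += uy * s; z += uz * s;
      tau -= mus_v * s;
      if (std::fabs(x) > half_x || std::fabs(y) > half_y) {
        tl.lateral += w;
        return;
      }
      if (hits_boundary) {
        if (uz < 0 && iz == 0) {
          // top boundary: partial escape, partial internal reflection
          double cosi = -uz;
          double R = fresnel_R(cosi, n_med, 1.0);
          tl.escaped += w * (1.0 - R);
          w *= R;
          uz = -uz;
          z = 0.0;
          if (w < W_FLOOR) { tl.residual += w; return; }
        } else if (uz > 0 && iz == n_vox - 1) {
          tl.transmitted += w;
          return;
        } else {
          iz += (uz > 0) ? 1 : -1;
          z = (uz > 0) ? (double)iz * dz : (double)(iz + 1) * dz;
        }
        if (tau <= 0) break;
      } else {
        break; // scattering event at current position
      }
    }
    hg_scatter(rng, g[iz], ux, uy, uz);
    if (w < W_FLOOR) { tl.residual += w; return; }
    if (roulette && w < rl_thresh) {
      if (rng.u01() < rl_surv) {
        w /= rl_surv;
      } else {
        return;
      }
    }
  }
}

// Fast path for a homogeneous medium when no absorption map is needed
// (emission step in a uniform base tissue): identical physics, no voxel
// traversal -- one attenuation factor per free path.
inline void track_photon_uniform(Xoshiro &rng, double x, double y, double z,
                                 double ux, double uy, double uz, double w,
                                 double mu_a, double mu_s, double g,
                                 double z_max, double n_med,
                                 double half_x, double half_y,
                                 bool roulette, double rl_thresh, double rl_surv,
                                 Tallies &tl) {
  const double BIG = 1e30;
  const double W_FLOOR = 1e-12;
  while (true) {
    double tau = -std::log(rng.u01());
    while (true) {
      double s_b;
      if (uz > 1e-12) {
        s_b = (z_max - z) / uz;
      } else if (uz < -1e-12) {
        s_b = z / (-uz);
      } else {
        s_b = BIG;
      }
      if (s_b < 0) s_b = 0;
      double s_sc = (mu_s > 0) ? tau / mu_s : BIG;
      bool hits_boundary = s_b < s_sc;
      double s = hits_boundary ? s_b : s_sc;
      w *= std::exp(-mu_a * s);
      x += ux * s; y += uy * s; z += uz * s;
      tau -= mu_s * s;
      if (std::fabs(x) > half_x || std::fabs(y) > half_y) {
        tl.lateral += w;
        return;
      }
      if (hits_boundary) {
        if (uz < 0) {
          double cosi = -uz;
          double R = fresnel_R(cosi, n_med, 1.0);
          tl.escaped += w * (1.0 - R);
          w *= R;
          uz = -uz;
          z = 0.0;
          if (w < W_FLOOR) { tl.residual += w; return; }
        } else {
          tl.transmitted += w;
          return;
        }
        if (tau <= 0) break;
      } else {
        break;
      }
    }
    hg_scatter(rng, g, ux, uy, uz);
    if (w < W_FLOOR) { tl.residual += w; return; }
    if (roulette && w < rl_thresh) {
      if (rng.u01() < rl_surv) {
        w /= rl_surv;
      } else {
        return;
      }
    }
  }
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".mc_excitation_cpp")]]
List mc_excitation_cpp(int n_photons, int n_batches, double seed,
                       NumericVector mu_a, NumericVector mu_s, NumericVector g,
                       double n_med, double dz,
                       double half_x, double half_y,
                       bool roulette, double rl_thresh, double rl_surv) {
  Xoshiro rng((uint64_t)seed);
  int n_vox = mu_a.size();
  NumericMatrix absorbed(n_vox, n_batches);
  NumericVector launched(n_batches);
  Tallies tl;
  double r_sp = (n_med - 1.0) / (n_med + 1.0);
  r_sp *= r_sp; // normal-incidence specular reflectance at entry
  double specular = 0.0;
  int per_batch = n_photons / n_batches;
  int extra = n_photons - per_batch * n_batches;
  for (int b = 0; b < n_batches; ++b) {
    int nb = per_batch + (b < extra ? 1 : 0);
    launched[b] = nb;
    double *col = &absorbed(0, b);
    for (int i = 0; i < nb; ++i) {
      // flat normal-incidence beam filling the lateral extent: the study
      // geometry (finite box, photons leaving the lateral faces are lost)
      double x = (2.0 * rng.u01() - 1.0) * half_x;
      double y = (2.0 * rng.u01() - 1.0) * half_y;
      specular += r_sp;
      track_photon(rng, x, y, 0.0, 0, 0.0, 0.0, 1.0, 1.0 - r_sp,
                   mu_a.begin(), mu_s.begin(), g.begin(), n_vox, dz,
                   n_med, half_x, half_y, roulette, rl_thresh, rl_surv,
                   col, tl);
    }
  }
  return List::create(_["absorbed"] = absorbed,
                      _["launched"] = launched,
                      _["specular"] = specular,
                      _["escaped"] = tl.escaped,
                      _["transmitted"] = tl.transmitted,
                      _["lateral_lost"] = tl.lateral,
                      _["residual"] = tl.residual);
}

//' @noRd
// [[Rcpp::export(name = ".mc_emission_cpp")]]
List mc_emission_cpp(IntegerVector src_iz, NumericMatrix src_w, int k_per_voxel,
                     double seed,
                     NumericVector mu_a, NumericVector mu_s, NumericVector g,
                     double n_med, double dz,
                     double half_x, double half_y,
                     bool roulette, double rl_thresh, double rl_surv) {
  Xoshiro rng((uint64_t)seed);
  int n_vox = mu_a.size();
  int n_src = src_iz.size();
  int n_batches = src_w.ncol();
  NumericVector escaped(n_batches);
  NumericMatrix absorbed(n_vox, 1); // emission-step dose sink (not returned per batch)
  bool uniform = true;
  for (int i = 1; i < n_vox; ++i) {
    if (mu_a[i] != mu_a[0] || mu_s[i] != mu_s[0] || g[i] != g[0]) {
      uniform = false;
      break;
    }
  }
  double z_max = (double)n_vox * dz;
  for (int b = 0; b < n_batches; ++b) {
    Tallies tl;
    for (int j = 0; j < n_src; ++j) {
      double w0 = src_w(j, b) / (double)k_per_voxel;
      if (w0 <= 0) continue;
      int iz0 = src_iz[j];
      for (int k = 0; k < k_per_voxel; ++k) {
        double z = ((double)iz0 + rng.u01()) * dz;
        double cost = 2.0 * rng.u01() - 1.0; // isotropic source
        double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
        double phi = 2.0 * M_PI * rng.u01();
        if (uniform) {
          track_photon_uniform(rng, 0.0, 0.0, z,
                               sint * std::cos(phi), sint * std::sin(phi),
                               cost, w0, mu_a[0], mu_s[0], g[0], z_max,
                               n_med, half_x, half_y,
                               roulette, rl_thresh, rl_surv, tl);
        } else {
          track_photon(rng, 0.0, 0.0, z, iz0,
                       sint * std::cos(phi), sint * std::sin(phi), cost, w0,
                       mu_a.begin(), mu_s.begin(), g.begin(), n_vox, dz,
                       n_med, half_x, half_y, roulette, rl_thresh, rl_surv,
                       &absorbed(0, 0), tl);
        }
      }
    }
    escaped[b] = tl.escaped;
  }
  return List::create(_["escaped"] = escaped,
                      _["k_per_voxel"] = k_per_voxel);
}
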