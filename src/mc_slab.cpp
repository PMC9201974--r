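#include <Rcpp.h>
#include <cstdint>
#include <cmath>

// Photon-packet Monte Carlo for a homogeneous slab, pencil beam at normal
// incidence, time-resolved transmittance through a coaxial detector disc on
// the exit face.  Trajectories are simulated at zero absorption (white Monte
// Carlo); absorption is applied analytically per arrival-time bin via
// exp(-mu_a * c_M * t), which is exact because every packet travels at speed
// c_M = c0 / n_in inside the medium.

static const double C0_CM_PER_PS = 0.0299792458; // vacuum speed of light

// ---- counter-based RNG -----------------------------------------------------
// SplitMix64-style bijective mix applied to (key, counter).  Photon i always
// sees the same substream regardless of execution order, so runs are
// reproducible bit-for-bit for a given (seed, substream, photon index).

static inline uint64_t mix64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct CounterRNG {
  uint64_t key;
  uint64_t ctr;
  CounterRNG(uint64_t seed, uint64_t substream, uint64_t photon) {
    uint64_t k = mix64(seed + 0x9E3779B97F4A7C15ULL * (substream + 1));
    key = mix64(k ^ (0xD2B74407B1CE6E93ULL * (photon + 1)));
    ctr = 0;
  }
  // uniform in [0, 1)
  double u() {
    uint64_t x = mix64(key + (++ctr) * 0x9E3779B97F4A7C15ULL);
    return (double)(x >> 11) * (1.0 / 9007199254740992.0);
  }
  // uniform in (0, 1]
  double u_open0() { return 1.0 - u(); }
};

// unpolarized Fresnel reflectance, incidence from n1 into n2
static double fresnel_R(double n1, double n2, double cos_i) {
  if (cos_i > 1.0) cos_i = 1.0;
  if (n1 == n2) return 0.0;
  double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
  double sin_t = n1 / n2 * sin_i;
  if (sin_t >= 1.0) return 1.0; // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t * sin_t);
  if (cos_i > 0.999999) { // normal incidence limit
    double r = (n1 - n2) / (n1 + n2);
    return r * r;
  }
  double rs = (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t);
  double rp = (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export(name = ".mc_slab_cpp")]]
Rcpp::List mc_slab_cpp(double mu_s, double g, double thickness,
                       double n_in, double n_out,
                       double det_radius, double det_half_angle_deg,
                       double lateral_radius, // <= 0: laterally unbounded
                       double n_photons_d, double bin_width_ps, double t_max_ps,
                       double mu_a, double seed_d, double substream_d) {
  const uint64_t n_photons = (uint64_t)n_photons_d;
  const uint64_t seed = (uint64_t)seed_d;
  const uint64_t substream = (uint64_t)substream_d;
  const double v = C0_CM_PER_PS / n_in;      // packet speed, cm/ps
  const double L_max = v * t_max_ps;         // path-length cap, cm
  const int n_bins = (int)std::ceil(t_max_ps / bin_width_ps - 1e-9);
  const double cos_acc = std::cos(det_half_angle_deg * M_PI / 180.0);
  const bool bounded = lateral_radius > 0.0;

  std::vector<double> counts(n_bins, 0.0);
  double w_detected = 0.0, w_trans_other = 0.0, w_reflected = 0.0;
  double w_side = 0.0, w_residual = 0.0;

  const double R_specular = fresnel_R(n_out, n_in, 1.0);

  for (uint64_t i = 0; i < n_photons; ++i) {
    CounterRNG rng(seed, substream, i);

    // specular reflection at the entry face (probabilistic, unit weight)
    if (rng.u() < R_specular) { w_reflected += 1.0; continue; }

    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double L = 0.0;     // path length inside the medium
    int fate = -1;      // 0 detected, 1 trans-other, 2 reflected, 3 side, 4 residual
    double t_arr = 0.0;

    double s = -std::log(rng.u_open0()) / mu_s; // first free path

    for (;;) {
      // distance to the z boundary along current direction
      double db = 1e300;
      int face = -1; // 0: entry face z=0, 1: exit face z=thickness
      if (uz > 0.0)      { db = (thickness - z) / uz; face = 1; }
      else if (uz < 0.0) { db = -z / uz;              face = 0; }

      if (s < db) {
        // interior move + scatter
        if (L + s > L_max) { fate = 4; break; }
        x += ux * s; y += uy * s; z += uz * s; L += s;
        if (bounded && (x * x + y * y) > lateral_radius * lateral_radius) {
          fate = 3; break;
        }
        // scatter: Henyey-Greenstein (isotropic when g == 0)
        double ct;
        if (g == 0.0) {
          ct = 2.0 * rng.u() - 1.0;
        } else {
          double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.u());
          ct = (1.0 + g * g - f * f) / (2.0 * g);
          if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
        }
        double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
        double phi = 2.0 * M_PI * rng.u();
        double cp = std::cos(phi), sp = std::sin(phi);
        if (std::fabs(uz) > 0.99999) {
          ux = st * cp; uy = st * sp; uz = (uz >= 0.0 ? ct : -ct);
        } else {
          double den = std::sqrt(1.0 - uz * uz);
          double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
          double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
          double nuz = -st * cp * den + uz * ct;
          ux = nux; uy = nuy; uz = nuz;
        }
        s = -std::log(rng.u_open0()) / mu_s;
      } else {
        // hit a z boundary
        if (L + db > L_max) { fate = 4; break; }
        x += ux * db; y += uy * db; z += uz * db; L += db;
        s -= db;
        if (bounded && (x * x + y * y) > lateral_radius * lateral_radius) {
          fate = 3; break;
        }
        double cos_i = std::fabs(uz);
        double R = fresnel_R(n_in, n_out, cos_i);
        if (rng.u() < R) {
          uz = -uz; // internal reflection, continue remaining step
          z = (face == 1) ? thickness : 0.0;
        } else {
          // transmitted out through this face
          if (face == 0) { fate = 2; break; }
          t_arr = L / v;
          // refraction: exit polar angle measured outside the medium
          double sin_t = n_in / n_out *
            std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
          double cos_t = std::sqrt(std::max(0.0, 1.0 - sin_t * sin_t));
          bool in_disc = (det_radius <= 0.0) ||
            ((x * x + y * y) <= det_radius * det_radius);
          bool in_cone = cos_t >= cos_acc - 1e-12;
          fate = (in_disc && in_cone) ? 0 : 1;
          break;
        }
      }
    }

    switch (fate) {
      case 0: {
        int b = (int)(t_arr / bin_width_ps);
        if (b >= n_bins) b = n_bins - 1;
        counts[b] += 1.0;
        w_detected += 1.0;
        break;
      }
      case 1: w_trans_other += 1.0; break;
      case 2: w_reflected += 1.0; break;
      case 3: w_side += 1.0; break;
      default: w_residual += 1.0; break;
    }
  }

  // analytic absorption per bin centre (path length quantized to c_M * t_c)
  Rcpp::NumericVector values(n_bins);
  for (int b = 0; b < n_bins; ++b) {
    double tc = (b + 0.5) * bin_width_ps;
    values[b] = (mu_a > 0.0) ? counts[b] * std::exp(-mu_a * v * tc) : counts[b];
  }
  Rcpp::NumericVector raw(counts.begin(), counts.end());

  return Rcpp::List::create(
    Rcpp::Named("values") = values,
    Rcpp::Named("counts") = raw,
    Rcpp::Named("detected") = w_detected,
    Rcpp::Named("transmitted_other") = w_trans_other,
    Rcpp::Named("reflected") = w_reflected,
    Rcpp::Named("side_loss") = w_side,
    Rcpp::Named("residual") = w_residual);
}

// [[Rcpp::export(name = ".fresnel_cpp")]]
double fresnel_cpp(double n_from, double n_to, double angle_deg) {
  double cos_i = std::cos(angle_deg * M_PI / 180.0);
  return fresnel_R(n_from, n_to, cos_i);
}
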