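#include <Rcpp.h>
#include <cmath>
#include <cstdint>

// Self-contained xoshiro256++ generator with Box-Muller normals.
// Used instead of R's RNG inside the hot loops so that traces are
// reproducible from an explicit integer seed independently of the
// caller's R RNG state (R-level Poisson emission still uses R's RNG).

namespace {

struct Xoshiro {
  uint64_t s[4];

  // 128-layer ziggurat tables for the standard normal (Marsaglia-Tsang /
  // Doornik constants), built once per generator
  double zx[129], zf[129], zr[128];
  static constexpr double ZIG_R = 3.442619855899;
  static constexpr double ZIG_V = 9.91256303526217e-3;

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }

  explicit Xoshiro(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
    zx[0] = ZIG_V / std::exp(-0.5 * ZIG_R * ZIG_R);
    zx[1] = ZIG_R;
    for (int i = 2; i <= 127; ++i) {
      zx[i] = std::sqrt(-2.0 * std::log(ZIG_V / zx[i - 1] +
                                        std::exp(-0.5 * zx[i - 1] * zx[i - 1])));
    }
    zx[128] = 0.0;
    for (int i = 0; i <= 128; ++i) zf[i] = std::exp(-0.5 * zx[i] * zx[i]);
    for (int i = 0; i < 128; ++i) zr[i] = zx[i + 1] / zx[i];
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0, 1)
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }

  // uniform in (-1, 1)
  double unif_signed() {
    return (static_cast<int64_t>(next() >> 11) - 4503599627370496LL + 0.5) *
           (1.0 / 4503599627370496.0);
  }

  double norm() {
    for (;;) {
      uint64_t bits = next();
      int i = static_cast<int>(bits & 127u);
      double u = (static_cast<int64_t>(bits >> 11) - 4503599627370496LL + 0.5) *
                 (1.0 / 4503599627370496.0);
      if (std::fabs(u) < zr[i]) return u * zx[i]; // inside inner rectangle
      if (i == 0) {
        // tail beyond ZIG_R (Marsaglia tail algorithm)
        double x, y;
        do {
          x = -std::log(unif()) / ZIG_R;
          y = -std::log(unif());
        } while (y + y < x * x);
        return u > 0 ? ZIG_R + x : -(ZIG_R + x);
      }
      double x = u * zx[i];
      if (zf[i] + unif() * (zf[i + 1] - zf[i]) < std::exp(-0.5 * x * x)) {
        return x;
      }
    }
  }
};

// membrane-like PMF: steep exponential wall + Gaussian well + Gaussian barrier
inline double pmf_u(double z, double wall_pos, double wall_amp, double wall_steep,
                    double well_depth, double well_pos, double well_width,
                    double barrier_height, double barrier_pos, double barrier_width) {
  double az = std::fabs(z);
  double u = wall_amp * std::exp(-(az - wall_pos) / wall_steep);
  double dw = (az - well_pos) / well_width;
  u -= well_depth * std::exp(-0.5 * dw * dw);
  double db = (az - barrier_pos) / barrier_width;
  u += barrier_height * std::exp(-0.5 * db * db);
  return u;
}

inline double pmf_du(double z, double wall_pos, double wall_amp, double wall_steep,
                     double well_depth, double well_pos, double well_width,
                     double barrier_height, double barrier_pos, double barrier_width) {
  double az = std::fabs(z);
  double s = (z >= 0) ? 1.0 : -1.0;
  double d = -wall_amp / wall_steep * std::exp(-(az - wall_pos) / wall_steep);
  double dw = (az - well_pos) / well_width;
  d += well_depth * dw / well_width * std::exp(-0.5 * dw * dw);
  double db = (az - barrier_pos) / barrier_width;
  d -= barrier_height * db / barrier_width * std::exp(-0.5 * db * db);
  return s * d;
}

inline double wrap1(double x, double L) {
  // wrap into [-L/2, L/2); one diffusion step never exceeds one box length
  if (x >= 0.5 * L) x -= L;
  else if (x < -0.5 * L) x += L;
  return x;
}

} // namespace

// draws from the internal generator, exposed for statistical validation
// [[Rcpp::export]]
Rcpp::NumericVector cpp_rng_normals(int n, double seed) {
  Xoshiro rng(static_cast<uint64_t>(seed));
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.norm();
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_sample_pmf_metropolis(int n_samples, double kT, double step,
                                     double box_half, int burnin, double seed,
                                     double wall_pos, double wall_amp, double wall_steep,
                                     double well_depth, double well_pos, double well_width,
                                     double barrier_height, double barrier_pos,
                                     double barrier_width) {
  Xoshiro rng(static_cast<uint64_t>(seed));
  Rcpp::NumericVector z(n_samples);
  double cur = (rng.unif() * 2.0 - 1.0) * box_half;
  double ucur = pmf_u(cur, wall_pos, wall_amp, wall_steep, well_depth, well_pos,
                      well_width, barrier_height, barrier_pos, barrier_width);
  long accepted = 0, total = 0;
  for (int i = -burnin; i < n_samples; ++i) {
    // occasional sign-flip move: the potential is even in z, so the flip is
    // always accepted; it restores ergodicity across the (impassable)
    // membrane core between the two leaflets
    if (rng.unif() < 0.1) {
      cur = -cur;
      ++accepted;
      ++total;
      if (i >= 0) z[i] = cur;
      continue;
    }
    double prop = cur + (rng.unif() * 2.0 - 1.0) * step;
    if (prop >= -box_half && prop <= box_half) {
      double uprop = pmf_u(prop, wall_pos, wall_amp, wall_steep, well_depth, well_pos,
                           well_width, barrier_height, barrier_pos, barrier_width);
      if (uprop <= ucur || rng.unif() < std::exp(-(uprop - ucur) / kT)) {
        cur = prop; ucur = uprop; ++accepted;
      }
    }
    ++total;
    if (i >= 0) z[i] = cur;
  }
  return Rcpp::List::create(Rcpp::Named("z") = z,
                            Rcpp::Named("acceptance") = double(accepted) / double(total));
}

// [[Rcpp::export]]
Rcpp::List cpp_sample_pmf_overdamped(int n_samples, double kT, double dt,
                                     double box_half, int burnin, double seed,
                                     double wall_pos, double wall_amp, double wall_steep,
                                     double well_depth, double well_pos, double well_width,
                                     double barrier_height, double barrier_pos,
                                     double barrier_width) {
  // overdamped Langevin in reduced units (D = 1 nm^2 per unit time),
  // reflecting boundaries at +/- box_half
  Xoshiro rng(static_cast<uint64_t>(seed));
  Rcpp::NumericVector z(n_samples);
  double cur = (rng.unif() * 2.0 - 1.0) * box_half;
  double noise = std::sqrt(2.0 * dt);
  for (int i = -burnin; i < n_samples; ++i) {
    double f = -pmf_du(cur, wall_pos, wall_amp, wall_steep, well_depth, well_pos,
                       well_width, barrier_height, barrier_pos, barrier_width) / kT;
    cur += f * dt + noise * rng.norm();
    // reflect
    while (cur > box_half || cur < -box_half) {
      if (cur > box_half) cur = 2.0 * box_half - cur;
      if (cur < -box_half) cur = -2.0 * box_half - cur;
    }
    if (i >= 0) z[i] = cur;
  }
  return Rcpp::List::create(Rcpp::Named("z") = z, Rcpp::Named("acceptance") = 1.0);
}

// Brownian-dynamics confocal photon-trace simulator.
// Returns the 2 x n_bins matrix of *expected* photon counts per bin
// (row 1 blue, row 2 red); Poisson emission is added at the R level.
// Vesicles (slow, red-labeled) carry `bound` labeled peptides each, which
// co-diffuse at the vesicle position; `n_free` labeled free peptides
// diffuse independently. Periodic box centered on the focus.
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_fccs_expected(int n_bins, double dt,
                                      Rcpp::IntegerVector bound,
                                      int n_free,
                                      double d_ves, double d_pep,
                                      Rcpp::NumericVector box,
                                      double omega_b, double omega_r,
                                      double wz_b, double wz_r,
                                      double brightness_blue, double brightness_red,
                                      double seed) {
  const int n_ves = bound.size();
  Xoshiro rng(static_cast<uint64_t>(seed));
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  std::vector<double> vx(n_ves), vy(n_ves), vz(n_ves);
  std::vector<double> px(n_free), py(n_free), pz(n_free);
  for (int i = 0; i < n_ves; ++i) {
    vx[i] = (rng.unif() - 0.5) * Lx; vy[i] = (rng.unif() - 0.5) * Ly;
    vz[i] = (rng.unif() - 0.5) * Lz;
  }
  for (int i = 0; i < n_free; ++i) {
    px[i] = (rng.unif() - 0.5) * Lx; py[i] = (rng.unif() - 0.5) * Ly;
    pz[i] = (rng.unif() - 0.5) * Lz;
  }
  const double sv = std::sqrt(2.0 * d_ves * dt);
  const double sp = std::sqrt(2.0 * d_pep * dt);
  const double ib2 = 2.0 / (omega_b * omega_b), ibz2 = 2.0 / (wz_b * wz_b);
  const double ir2 = 2.0 / (omega_r * omega_r), irz2 = 2.0 / (wz_r * wz_r);
  const double eb = brightness_blue * dt, er = brightness_red * dt;
  Rcpp::NumericMatrix out(2, n_bins);
  for (int t = 0; t < n_bins; ++t) {
    double blue = 0.0, red = 0.0;
    for (int i = 0; i < n_ves; ++i) {
      double x = wrap1(vx[i] + sv * rng.norm(), Lx);
      double y = wrap1(vy[i] + sv * rng.norm(), Ly);
      double z = wrap1(vz[i] + sv * rng.norm(), Lz);
      vx[i] = x; vy[i] = y; vz[i] = z;
      double r2 = x * x + y * y;
      double exr = -(r2 * ir2 + z * z * irz2);
      if (exr > -30.0) red += er * std::exp(exr);
      if (bound[i] > 0) {
        double exb = -(r2 * ib2 + z * z * ibz2);
        if (exb > -30.0) blue += bound[i] * eb * std::exp(exb);
      }
    }
    for (int i = 0; i < n_free; ++i) {
      double x = wrap1(px[i] + sp * rng.norm(), Lx);
      double y = wrap1(py[i] + sp * rng.norm(), Ly);
      double z = wrap1(pz[i] + sp * rng.norm(), Lz);
      px[i] = x; py[i] = y; pz[i] = z;
      double exb = -((x * x + y * y) * ib2 + z * z * ibz2);
      if (exb > -30.0) blue += eb * std::exp(exb);
    }
    out(0, t) = blue;
    out(1, t) = red;
  }
  return out;
}
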