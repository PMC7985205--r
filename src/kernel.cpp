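// Time-resolved Monte Carlo photon transport in a homogeneous slab.
//
// Conventions: z = 0 at the illuminated face, z increases into the slab;
// units are mm, ps and mm^-1 throughout. Free paths are sampled from the
// scattering coefficient alone and absorption is applied as continuous
// Beer-Lambert attenuation along every traversed segment. Each photon owns
// an RNG substream derived from (master seed, absolute photon index), so
// results are independent of batching order.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-seeded RNG: splitmix64 expands (seed, photon index) into a state
// for xoshiro256++, whose 53-bit output is mapped into the open interval
// (0, 1) so that log(u) is always finite.

static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256 {
  uint64_t s[4];

  Xoshiro256(uint64_t seed, uint64_t stream) {
    uint64_t sm = seed ^ (0x6A09E667F3BCC909ULL + stream * 0x9E3779B97F4A7C15ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
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

  // uniform deviate strictly inside (0, 1)
  inline double unif() {
    return (static_cast<double>(next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// ---------------------------------------------------------------------------
// Elementary physics, shared by the exported helpers and the transport loop.

static inline double free_path(double mu_s, double u) {
  return -std::log(u) / mu_s;
}

static inline double hg_cosine(double g, double u) {
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  const double s = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - s * s) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

static inline double fresnel_unpolarized(double n_i, double n_t, double cos_i) {
  if (n_i == n_t) return 0.0;
  const double sin_i2 = 1.0 - cos_i * cos_i;
  const double sin_t2 = (n_i / n_t) * (n_i / n_t) * sin_i2;
  if (sin_t2 >= 1.0) return 1.0;  // total internal reflection
  const double cos_t = std::sqrt(1.0 - sin_t2);
  const double rs = (n_i * cos_i - n_t * cos_t) / (n_i * cos_i + n_t * cos_t);
  const double rp = (n_t * cos_i - n_i * cos_t) / (n_t * cos_i + n_i * cos_t);
  return 0.5 * (rs * rs + rp * rp);
}

// Deflect a unit vector by polar angle acos(ct) and azimuth with cosine cp
// and sine sp (MCML rotation); a dedicated formula handles near-axial
// directions where the generic one loses precision.
static inline void deflect_cs(double &ux, double &uy, double &uz,
                              double ct, double cp, double sp) {
  const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double nx, ny, nz;
  if (std::fabs(uz) > 1.0 - 1e-6) {
    nx = st * cp;
    ny = st * sp;
    nz = (uz >= 0.0 ? ct : -ct);
  } else {
    const double tmp = std::sqrt(1.0 - uz * uz);
    nx = st * (ux * uz * cp - uy * sp) / tmp + ux * ct;
    ny = st * (uy * uz * cp + ux * sp) / tmp + uy * ct;
    nz = -st * cp * tmp + uz * ct;
  }
  const double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
  ux = nx / norm;
  uy = ny / norm;
  uz = nz / norm;
}

static inline void deflect(double &ux, double &uy, double &uz,
                           double ct, double phi) {
  deflect_cs(ux, uy, uz, ct, std::cos(phi), std::sin(phi));
}

// ---------------------------------------------------------------------------
// Exported vectorised helpers (pure functions of explicit uniform deviates).

// [[Rcpp::export]]
NumericVector cpp_sample_free_path(double mu_s, NumericVector u) {
  const R_xlen_t n = u.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = free_path(mu_s, u[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_scatter_cosine(double g, NumericVector u) {
  const R_xlen_t n = u.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = hg_cosine(g, u[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fresnel_reflectance(double n_i, double n_t,
                                      NumericVector cos_theta_i) {
  const R_xlen_t n = cos_theta_i.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = fresnel_unpolarized(n_i, n_t, cos_theta_i[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_new_direction(NumericVector direction, double cos_theta,
                                double phi) {
  double ux = direction[0], uy = direction[1], uz = direction[2];
  deflect(ux, uy, uz, cos_theta, phi);
  return NumericVector::create(ux, uy, uz);
}

// Deterministic uniforms from a named substream of the master seed; used to
// derive per-run seeds and parameter draws independent of R's global RNG.

// [[Rcpp::export]]
NumericVector cpp_derive_uniforms(double seed, int k, double stream) {
  Xoshiro256 rng(static_cast<uint64_t>(seed),
                 0xD1B54A32D192ED03ULL + static_cast<uint64_t>(stream));
  NumericVector out(k);
  for (int i = 0; i < k; ++i) out[i] = rng.unif();
  return out;
}

// ---------------------------------------------------------------------------
// Full transport run.
//
// photon_offset gives the absolute index of the first launched photon, so a
// run split into batches reproduces the monolithic run record for record.

// [[Rcpp::export]]
List cpp_run_simulation(double n, double g, double mu_s, double mu_a,
                        double thickness, double n_amb_top, double n_amb_bottom,
                        int n_photons, double roulette_threshold, int roulette_m,
                        double seed, double c_vacuum, double max_events,
                        double photon_offset) {
  const uint64_t master = static_cast<uint64_t>(seed);
  const double inv_m = 1.0 / static_cast<double>(roulette_m);
  const bool roulette_on = roulette_threshold > 0.0;
  const double vinv = n / c_vacuum;  // ps per mm of geometric path

  // deterministic specular deduction at the entry face
  const double r_sp = fresnel_unpolarized(n_amb_top, n, 1.0);
  const double w0 = 1.0 - r_sp;

  std::vector<int> side;
  std::vector<double> xs, ys, uxs, uys, uzs, ws, ts;
  double absorbed = 0.0, lost = 0.0, roulette_boost = 0.0;
  long n_cap = 0;

  // The photon weight is never updated per segment; it is evaluated lazily
  // as w = mult * exp(-mu_a * path), where `path` is the accumulated
  // geometric path length and `mult` collects roulette boosts. The roulette
  // trigger (w < threshold) then becomes a precomputed path-length
  // comparison, and the absorbed weight follows by bookkeeping at
  // termination: absorbed = launched + boosts - exited - killed - capped.
  const double log_m = std::log(static_cast<double>(roulette_m));

  for (int ip = 0; ip < n_photons; ++ip) {
    Xoshiro256 rng(master, static_cast<uint64_t>(photon_offset) +
                               static_cast<uint64_t>(ip));
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double mult = w0, path = 0.0;
    double boosted = 0.0, removed = 0.0;  // per-photon tallies
    double path_kill = (roulette_on && mu_a > 0.0)
                           ? std::log(w0 / roulette_threshold) / mu_a
                           : R_PosInf;
    long events = 0;
    bool alive = true;

    while (alive) {
      double d = free_path(mu_s, rng.unif());

      // resolve boundary crossings; after an internal reflection the
      // remaining step is re-sampled (memoryless exponential)
      bool at_interior = true;
      for (;;) {
        double db;
        if (uz > 0.0)
          db = (thickness - z) / uz;
        else if (uz < 0.0)
          db = -z / uz;
        else
          db = R_PosInf;

        if (d < db) break;  // step ends inside the slab

        // advance to the boundary
        x += db * ux;
        y += db * uy;
        z = (uz > 0.0) ? thickness : 0.0;
        path += db;

        if (path > path_kill) {  // weight dipped below the threshold
          const double w = mult * std::exp(-mu_a * path);
          if (rng.unif() < inv_m) {
            boosted += (roulette_m - 1.0) * w;
            mult *= roulette_m;
            path_kill += log_m / mu_a;
          } else {
            lost += w;
            removed = w;
            alive = false;
            at_interior = false;
            break;
          }
        }

        const bool top = (uz < 0.0);
        const double n_t = top ? n_amb_top : n_amb_bottom;
        const double cos_i = std::fabs(uz);
        const double refl = fresnel_unpolarized(n, n_t, cos_i);
        if (rng.unif() < refl) {
          uz = -uz;                           // internal reflection
          d = free_path(mu_s, rng.unif());    // fresh step
        } else {
          // transmit with Snell refraction and log the exit
          const double ratio = n / n_t;
          const double sin_t2 =
              ratio * ratio * std::max(0.0, 1.0 - cos_i * cos_i);
          const double cos_t = std::sqrt(std::max(0.0, 1.0 - sin_t2));
          const double w = mult * std::exp(-mu_a * path);
          side.push_back(top ? 1 : 2);
          xs.push_back(x);
          ys.push_back(y);
          uxs.push_back(ux * ratio);
          uys.push_back(uy * ratio);
          uzs.push_back(top ? -cos_t : cos_t);
          ws.push_back(w);
          ts.push_back(path * vinv);
          removed = w;
          alive = false;
          at_interior = false;
          break;
        }
      }
      if (!at_interior) break;

      // interior step: move, then scatter
      x += d * ux;
      y += d * uy;
      z += d * uz;
      path += d;

      if (path > path_kill) {
        const double w = mult * std::exp(-mu_a * path);
        if (rng.unif() < inv_m) {
          boosted += (roulette_m - 1.0) * w;
          mult *= roulette_m;
          path_kill += log_m / mu_a;
        } else {
          lost += w;
          removed = w;
          break;
        }
      }

      if (++events > static_cast<long>(max_events)) {
        const double w = mult * std::exp(-mu_a * path);
        lost += w;
        removed = w;
        ++n_cap;
        break;
      }

      const double ct = hg_cosine(g, rng.unif());
      // azimuth by Marsaglia polar sampling (no trig calls)
      double cp, sp;
      for (;;) {
        const double v1 = 2.0 * rng.unif() - 1.0;
        const double v2 = 2.0 * rng.unif() - 1.0;
        const double s = v1 * v1 + v2 * v2;
        if (s > 0.0 && s < 1.0) {
          cp = (v1 * v1 - v2 * v2) / s;
          sp = 2.0 * v1 * v2 / s;
          break;
        }
      }
      deflect_cs(ux, uy, uz, ct, cp, sp);
    }

    absorbed += w0 + boosted - removed;
    roulette_boost += boosted;
  }

  return List::create(
      _["side"] = wrap(side), _["x"] = wrap(xs), _["y"] = wrap(ys),
      _["ux"] = wrap(uxs), _["uy"] = wrap(uys), _["uz"] = wrap(uzs),
      _["weight"] = wrap(ws), _["time"] = wrap(ts),
      _["absorbed_weight"] = absorbed, _["lost_weight"] = lost,
      _["roulette_boost"] = roulette_boost,
      _["specular_weight"] = static_cast<double>(n_photons) * r_sp,
      _["launch_weight"] = static_cast<double>(n_photons) * w0,
      _["n_cap_terminations"] = static_cast<double>(n_cap));
}
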