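#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic counter-seeded RNG (xoshiro256**), independent of R's RNG so
// that fluence grids are bit-identical for a fixed seed regardless of the
// caller's RNG state.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256 {
  uint64_t s[4];
  explicit Xoshiro256(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  static inline uint64_t rotl(const uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1); never exactly 0 (safe for log())
  inline double runif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// Unpolarized Fresnel reflectance for a ray inside medium n1 hitting an
// interface with exterior n2 at incidence cosine ci (>0).
static inline double fresnel_R(double n1, double n2, double ci) {
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = n1 / n2 * si;
  if (st >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(1.0 - st * st);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein deflection cosine.
static inline double hg_cost(double g, double u) {
  if (std::fabs(g) < 1e-8) return 1.0 - 2.0 * u;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  return (1.0 + g * g - f * f) / (2.0 * g);
}

// Random azimuth as a unit 2-vector by rejection (avoids sin/cos calls).
static inline void rand_azimuth(Xoshiro256 &rng, double &cp, double &sp) {
  double a, b, r2;
  do {
    a = 2.0 * rng.runif() - 1.0;
    b = 2.0 * rng.runif() - 1.0;
    r2 = a * a + b * b;
  } while (r2 > 1.0 || r2 < 1e-12);
  double inv = 1.0 / std::sqrt(r2);
  cp = a * inv;
  sp = b * inv;
}

// Rotate unit vector (ux,uy,uz) by polar angle acos(ct), azimuth (cp,sp).
static inline void spin(double &ux, double &uy, double &uz,
                        double ct, double cp, double sp) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -st * cp * den + uz * ct;
    double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
    ux = nx / norm; uy = ny / norm; uz = nz / norm;
  }
}

// ---------------------------------------------------------------------------
// Voxel Monte-Carlo fluence kernel.
//
// Geometry: slab occupying x,y in [-ex/2, ex/2], z in [0, ez]; optode on the
// z = 0 face. z = 0 carries a Fresnel (n_in vs n_out) boundary; the other
// five faces are absorbing (photons crossing them are terminated and their
// weight tallied as escaped).
//
// Scoring: collision estimator — at each collision a photon of weight w
// contributes w / (mu_t * V) to the fluence of the voxel containing the
// collision, which equals the absorbed-weight deposition w * (mu_a/mu_t)
// divided by (mu_a * V) and stays finite as mu_a -> 0. Gated values are
// stored per unit time (divided by the gate width), so the CW integral is
// sum(value * dt). All values are per launched photon, i.e. Green's
// functions per unit source power (mm^-2).
//
// Beams: type 0 — pencil, normal incidence, initial weight reduced by the
// normal-incidence Fresnel transmittance; type 1 — cone, direction sampled
// uniformly in solid angle within the exterior acceptance half-angle
// asin(NA/n_out), refracted into the medium, weight reduced by the
// angle-dependent Fresnel transmittance.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List mc_fluence_cpp(double mu_a, double mu_s, double g,
                    double n_in, double n_out,
                    NumericVector extent, double voxel,
                    NumericVector origin,      // optode (x, y) on z = 0, mm
                    int beam_type,             // 0 pencil, 1 cone
                    double na,                 // numerical aperture (cone)
                    double n_photons,
                    int n_gates, double t_end_ns,
                    double seed,
                    double roulette_w, double roulette_m) {
  const double mu_t = mu_a + mu_s;
  const double albedo = mu_s / mu_t;
  const double ex = extent[0], ey = extent[1], ez = extent[2];
  const int nx = (int)std::lround(ex / voxel);
  const int ny = (int)std::lround(ey / voxel);
  const int nz = (int)std::lround(ez / voxel);
  const double V = voxel * voxel * voxel;
  const double hx = ex / 2.0, hy = ey / 2.0;
  const double c_mm_ns = 299.792458;          // speed of light in vacuum
  const double v_med = c_mm_ns / n_in;        // mm per ns inside the medium
  const double dt = t_end_ns / n_gates;
  const double x0 = origin[0], y0 = origin[1];
  const size_t nvox = (size_t)nx * ny * nz;

  NumericVector grid((R_xlen_t)(nvox * n_gates));
  std::fill(grid.begin(), grid.end(), 0.0);
  double *G = REAL(grid);

  Xoshiro256 rng((uint64_t)seed);

  double w_launched = 0.0, w_escaped_top = 0.0, w_escaped_side = 0.0;
  double w_absorbed = 0.0, w_roulette_net = 0.0, w_time_censored = 0.0;
  const long long N = (long long)n_photons;

  // reflectance of normal incidence, used for the pencil launch
  const double R_norm = fresnel_R(n_out, n_in, 1.0);

  // tabulated internal Fresnel reflectance vs incidence cosine for the
  // z = 0 boundary (linear interpolation on a fine grid)
  const int NTAB = 4096;
  std::vector<double> ftab(NTAB + 1);
  for (int i = 0; i <= NTAB; ++i)
    ftab[i] = fresnel_R(n_in, n_out, (double)i / NTAB);
  auto fresnel_internal = [&](double ci) {
    double u = ci * NTAB;
    int i = (int)u;
    if (i >= NTAB) return ftab[NTAB];
    double f = u - i;
    return ftab[i] * (1.0 - f) + ftab[i + 1] * f;
  };

  for (long long ip = 0; ip < N; ++ip) {
    double x = x0, y = y0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0;

    if (beam_type == 0) {
      w = 1.0 - R_norm;
    } else {
      // exterior direction uniform in solid angle within the NA cone
      double sin_max = na / n_out;
      double cos_min = std::sqrt(std::max(0.0, 1.0 - sin_max * sin_max));
      double cos_o = cos_min + (1.0 - cos_min) * rng.runif();
      double sin_o = std::sqrt(std::max(0.0, 1.0 - cos_o * cos_o));
      double phi = 2.0 * M_PI * rng.runif();
      // Snell refraction into the medium
      double sin_i = sin_o * n_out / n_in;
      double cos_i = std::sqrt(std::max(0.0, 1.0 - sin_i * sin_i));
      ux = sin_i * std::cos(phi);
      uy = sin_i * std::sin(phi);
      uz = cos_i;
      w = 1.0 - fresnel_R(n_out, n_in, cos_o);
    }
    w_launched += w;

    double path = 0.0;                 // optical path length inside medium, mm
    const double path_max = v_med * t_end_ns;
    bool alive = true;

    while (alive) {
      double s = -std::log(rng.runif()) / mu_t;

      // advance through (possibly several) boundary interactions
      while (s > 0.0 && alive) {
        // distance to nearest face along the current direction
        double d = 1e30; int face = -1;   // 0:z=0, 1:z=ez, 2..5 lateral
        if (uz < 0.0) { double t = -z / uz;        if (t < d) { d = t; face = 0; } }
        if (uz > 0.0) { double t = (ez - z) / uz;  if (t < d) { d = t; face = 1; } }
        if (ux > 0.0) { double t = (hx - x) / ux;  if (t < d) { d = t; face = 2; } }
        if (ux < 0.0) { double t = (-hx - x) / ux; if (t < d) { d = t; face = 3; } }
        if (uy > 0.0) { double t = (hy - y) / uy;  if (t < d) { d = t; face = 4; } }
        if (uy < 0.0) { double t = (-hy - y) / uy; if (t < d) { d = t; face = 5; } }

        if (s < d) {
          x += s * ux; y += s * uy; z += s * uz;
          path += s;
          s = 0.0;
        } else {
          x += d * ux; y += d * uy; z += d * uz;
          path += d;
          s -= d;
          if (face == 0) {
            double R = fresnel_internal(-uz);
            if (rng.runif() < R) {
              uz = -uz;
              z = 0.0;
            } else {
              w_escaped_top += w;
              alive = false;
            }
          } else {
            // absorbing faces: bottom and the four lateral faces
            w_escaped_side += w;
            alive = false;
          }
        }
        if (alive && path > path_max) {
          w_time_censored += w;
          alive = false;
        }
      }
      if (!alive) break;

      // collision: score, absorb, scatter
      int ix = (int)((x + hx) / voxel);
      int iy = (int)((y + hy) / voxel);
      int iz = (int)(z / voxel);
      if (ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz) {
        int ig = (int)(path / v_med / dt);
        if (ig >= 0 && ig < n_gates) {
          size_t idx = (size_t)ig * nvox +
            (size_t)iz * nx * ny + (size_t)iy * nx + (size_t)ix;
          G[idx] += w / (mu_t * V * dt);
        }
      }
      w_absorbed += w * (mu_a / mu_t);
      w *= albedo;

      if (w < roulette_w) {
        if (rng.runif() < 1.0 / roulette_m) {
          w_roulette_net -= w * (roulette_m - 1.0);
          w *= roulette_m;
        } else {
          w_roulette_net += w;
          alive = false;
          break;
        }
      }

      double ct = hg_cost(g, rng.runif());
      double cp, sp;
      rand_azimuth(rng, cp, sp);
      spin(ux, uy, uz, ct, cp, sp);
    }
  }

  // per launched unit power
  double nscale = (double)N;
  for (R_xlen_t i = 0; i < grid.size(); ++i) G[i] /= nscale;

  grid.attr("dim") = IntegerVector::create(nx, ny, nz, n_gates);
  return List::create(
    _["gated"] = grid,
    _["tallies"] = NumericVector::create(
      _["launched"] = w_launched / nscale,
      _["escaped_top"] = w_escaped_top / nscale,
      _["escaped_side"] = w_escaped_side / nscale,
      _["absorbed"] = w_absorbed / nscale,
      _["roulette_net"] = w_roulette_net / nscale,
      _["time_censored"] = w_time_censored / nscale));
}
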