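#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Photon random walk in a rectangular slab containing one spherical target.
//
// Geometry: z points into the slab (top surface z = 0, bottom z = slab_z),
// x and y centred on the source-detector midpoint. A pencil beam enters
// normally at (src_x, 0, 0); a photon is detected if it leaves through the
// top surface inside a disc of radius det_radius centred at (det_x, 0, 0).
// Boundaries are refractive-index matched (no internal reflection).
//
// Absorption is handled entirely at replay time, so the walk itself is
// absorption-free: per step we sample an exponential free path at rate
// mu_s, deflect by a Henyey-Greenstein angle, and accumulate the path
// length inside (L_in) and outside (L_out) the sphere analytically per
// segment. Photons are terminated on geometric exit or at a total path
// cap (a guard against pathological trajectories).

// Fast internal RNG (xoshiro256++), seeded from R's RNG so that set.seed()
// fully determines a run; R's unif_rand is too slow for ~1e9 draws.
static uint64_t rng_s[4];

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static void rng_seed_from_R() {
  uint64_t seed = (uint64_t)(unif_rand() * 4294967296.0) ^
                  ((uint64_t)(unif_rand() * 4294967296.0) << 32);
  for (int i = 0; i < 4; ++i) rng_s[i] = splitmix64(seed);
}

static inline uint64_t rotl64(uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

static inline double rng_unif() {
  const uint64_t result = rotl64(rng_s[0] + rng_s[3], 23) + rng_s[0];
  const uint64_t t = rng_s[1] << 17;
  rng_s[2] ^= rng_s[0];
  rng_s[3] ^= rng_s[1];
  rng_s[1] ^= rng_s[2];
  rng_s[0] ^= rng_s[3];
  rng_s[2] ^= t;
  rng_s[3] = rotl64(rng_s[3], 45);
  // (0, 1): 53-bit mantissa, offset by half an ulp to avoid exact 0
  return ((result >> 11) + 0.5) * 1.1102230246251565e-16;
}

static inline double hg_cosine(double g) {
  double u = rng_unif();
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  double frac = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - frac * frac) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// length of [0, seg] (along unit dir from pos) lying inside the sphere
static inline double sphere_overlap(const double pos[3], const double dir[3],
                                    double seg,
                                    double cx, double cy, double cz,
                                    double r) {
  double ox = pos[0] - cx, oy = pos[1] - cy, oz = pos[2] - cz;
  double b = ox * dir[0] + oy * dir[1] + oz * dir[2];
  double c = ox * ox + oy * oy + oz * oz - r * r;
  double disc = b * b - c;
  if (disc <= 0.0) return 0.0;
  double sq = std::sqrt(disc);
  double t0 = -b - sq, t1 = -b + sq;
  if (t0 < 0.0) t0 = 0.0;
  if (t1 > seg) t1 = seg;
  return (t1 > t0) ? (t1 - t0) : 0.0;
}

// [[Rcpp::export]]
List simulate_paths_cpp(int n_photons,
                        double slab_x, double slab_y, double slab_z,
                        double src_x, double det_x, double det_radius,
                        double sph_x, double sph_y, double sph_z, double sph_r,
                        double mus, double g, double max_path) {
  rng_seed_from_R();
  std::vector<double> out_Lout, out_Lin;
  out_Lout.reserve(1024);
  out_Lin.reserve(1024);
  const double hx = slab_x / 2.0, hy = slab_y / 2.0;
  const double det_r2 = det_radius * det_radius;

  for (int ph = 0; ph < n_photons; ++ph) {
    double pos[3] = {src_x, 0.0, 0.0};
    double dir[3] = {0.0, 0.0, 1.0};
    double L_in = 0.0, L_out = 0.0, total = 0.0;

    for (;;) {
      double s = -std::log(rng_unif()) / mus;

      // distance to the nearest slab boundary along dir
      double t_bound = R_PosInf;
      int face = -1; // 0 = top
      if (dir[2] < 0.0) {
        double t = -pos[2] / dir[2];
        if (t < t_bound) { t_bound = t; face = 0; }
      } else if (dir[2] > 0.0) {
        double t = (slab_z - pos[2]) / dir[2];
        if (t < t_bound) { t_bound = t; face = 1; }
      }
      if (dir[0] > 0.0) {
        double t = (hx - pos[0]) / dir[0];
        if (t < t_bound) { t_bound = t; face = 2; }
      } else if (dir[0] < 0.0) {
        double t = (-hx - pos[0]) / dir[0];
        if (t < t_bound) { t_bound = t; face = 2; }
      }
      if (dir[1] > 0.0) {
        double t = (hy - pos[1]) / dir[1];
        if (t < t_bound) { t_bound = t; face = 3; }
      } else if (dir[1] < 0.0) {
        double t = (-hy - pos[1]) / dir[1];
        if (t < t_bound) { t_bound = t; face = 3; }
      }

      bool exits = (t_bound <= s);
      double seg = exits ? t_bound : s;
      double lin = sphere_overlap(pos, dir, seg, sph_x, sph_y, sph_z, sph_r);
      L_in += lin;
      L_out += seg - lin;
      total += seg;

      pos[0] += seg * dir[0];
      pos[1] += seg * dir[1];
      pos[2] += seg * dir[2];

      if (exits) {
        if (face == 0) {
          double dx = pos[0] - det_x, dy = pos[1];
          if (dx * dx + dy * dy <= det_r2) {
            out_Lout.push_back(L_out);
            out_Lin.push_back(L_in);
          }
        }
        break;
      }
      if (total >= max_path) break;

      // Henyey-Greenstein deflection about the current direction
      double ct = hg_cosine(g);
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double phi = 2.0 * M_PI * rng_unif();
      double cp = std::cos(phi), sp = std::sin(phi);
      double ux = dir[0], uy = dir[1], uz = dir[2];
      if (std::fabs(uz) > 0.999999) {
        dir[0] = st * cp;
        dir[1] = st * sp;
        dir[2] = (uz > 0.0 ? ct : -ct);
      } else {
        double denom = std::sqrt(1.0 - uz * uz);
        dir[0] = st * (ux * uz * cp - uy * sp) / denom + ux * ct;
        dir[1] = st * (uy * uz * cp + ux * sp) / denom + uy * ct;
        dir[2] = -st * cp * denom + uz * ct;
      }
      double nrm = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] + dir[2] * dir[2]);
      dir[0] /= nrm; dir[1] /= nrm; dir[2] /= nrm;
    }
    if ((ph & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["L_out"] = NumericVector(out_Lout.begin(), out_Lout.end()),
    _["L_in"] = NumericVector(out_Lin.begin(), out_Lin.end()),
    _["n_injected"] = n_photons);
}

// [[Rcpp::export]]
NumericVector sample_step_cpp(int n, double mus) {
  rng_seed_from_R();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = -std::log(rng_unif()) / mus;
  return out;
}

// [[Rcpp::export]]
NumericVector sample_hg_cpp(int n, double g) {
  rng_seed_from_R();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cosine(g);
  return out;
}
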