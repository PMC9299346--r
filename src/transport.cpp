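#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Photon transport through a layered slab for diffuse correlation
// spectroscopy. Scattering only: absorption is applied analytically
// afterwards from the recorded per-layer pathlengths, so a single
// transport run serves every flow / absorption combination. Photons
// terminate on escape through the top surface or on reaching the
// lateral / depth bounds. Henyey-Greenstein phase function; Fresnel
// reflection at the top surface (internal index n_rel vs 1); internal
// interfaces are index-matched. Per-layer pathlength L_i and
// dimensionless momentum transfer Y_i = sum(1 - cos theta) are recorded
// for photons escaping within one of the detector annuli.

// xoshiro256+ with splitmix64 seeding: fast, reproducible across
// platforms independent of R's RNG.
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]: never returns 0 (safe for log())
  inline double runif() {
    return ((next() >> 11) + 1) * (1.0 / 9007199254740993.0);
  }
};

static inline double fresnel_internal(double cosi, double n_rel) {
  // unpolarized reflectance for a photon inside medium n_rel hitting the
  // boundary with outside index 1 at incidence cosine cosi (> 0)
  double sini = std::sqrt(std::max(0.0, 1.0 - cosi * cosi));
  double sint = n_rel * sini;
  if (sint >= 1.0) return 1.0;
  double cost = std::sqrt(1.0 - sint * sint);
  double rs = (n_rel * cosi - cost) / (n_rel * cosi + cost);
  double rp = (n_rel * cost - cosi) / (n_rel * cost + cosi);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export]]
List transport_kernel(double n_photons, NumericVector mus, NumericVector g_hg,
                      NumericVector boundaries, double n_rel,
                      NumericVector det_rmin, NumericVector det_rmax,
                      double lateral_halfwidth, double depth_bound,
                      double seed) {
  const int nl = mus.size();
  const int nd = det_rmin.size();
  if ((int)boundaries.size() != nl - 1)
    stop("boundaries must have one entry per finite layer");
  const int64_t np = (int64_t)n_photons;
  Rng rng((uint64_t)seed);

  std::vector<double> zlow(nl), zhigh(nl);
  for (int i = 0; i < nl; ++i) {
    zlow[i] = (i == 0) ? 0.0 : boundaries[i - 1];
    zhigh[i] = (i == nl - 1) ? depth_bound : boundaries[i];
  }

  std::vector<int> det_id;
  std::vector<double> recL, recY;   // row-major nl per record
  std::vector<int64_t> det_count(nd, 0);

  std::vector<double> L(nl), Y(nl);

  for (int64_t n = 0; n < np; ++n) {
    if ((n & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    int layer = 0;
    std::fill(L.begin(), L.end(), 0.0);
    std::fill(Y.begin(), Y.end(), 0.0);
    bool alive = true;

    while (alive) {
      double sleft = -std::log(rng.runif());   // optical scattering depths
      // propagate, possibly across layer boundaries
      for (;;) {
        double step = sleft / mus[layer];
        double db;
        if (uz > 0.0) db = (zhigh[layer] - z) / uz;
        else if (uz < 0.0) db = (zlow[layer] - z) / uz;
        else db = 1e30;
        if (step < db) {
          x += ux * step; y += uy * step; z += uz * step;
          L[layer] += step;
          break;                               // scatter here
        }
        // move to the boundary
        x += ux * db; y += uy * db; z += uz * db;
        L[layer] += db;
        sleft -= db * mus[layer];
        if (std::fabs(x) > lateral_halfwidth ||
            std::fabs(y) > lateral_halfwidth) { alive = false; break; }
        if (uz < 0.0 && layer == 0) {
          // top surface: Fresnel reflect or escape
          z = 0.0;
          double R = fresnel_internal(-uz, n_rel);
          if (rng.runif() < R) {
            uz = -uz;                          // specular re-entry
          } else {
            double rho = std::sqrt(x * x + y * y);
            for (int d = 0; d < nd; ++d) {
              if (rho >= det_rmin[d] && rho < det_rmax[d]) {
                det_id.push_back(d + 1);
                for (int i = 0; i < nl; ++i) recL.push_back(L[i]);
                for (int i = 0; i < nl; ++i) recY.push_back(Y[i]);
                det_count[d]++;
                break;
              }
            }
            alive = false; break;              // escaped
          }
        } else if (uz > 0.0 && layer == nl - 1) {
          alive = false; break;                // depth bound
        } else {
          layer += (uz > 0.0) ? 1 : -1;        // index-matched interface
          z = (uz > 0.0) ? zlow[layer] : zhigh[layer];
        }
      }
      if (!alive) break;
      if (std::fabs(x) > lateral_halfwidth ||
          std::fabs(y) > lateral_halfwidth) break;

      // Henyey-Greenstein scatter
      double g = g_hg[layer];
      double ct;
      if (g > 1e-6) {
        double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.runif());
        ct = (1.0 + g * g - f * f) / (2.0 * g);
      } else {
        ct = 2.0 * rng.runif() - 1.0;
      }
      if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
      Y[layer] += 1.0 - ct;
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      // uniform azimuth without trig: rejection-sample the unit disk
      double cp, sp;
      for (;;) {
        double a1 = 2.0 * rng.runif() - 1.0;
        double a2 = 2.0 * rng.runif() - 1.0;
        double rr = a1 * a1 + a2 * a2;
        if (rr > 0.0 && rr <= 1.0) {
          cp = (a1 * a1 - a2 * a2) / rr;   // cos(2a), sin(2a): uniform angle
          sp = 2.0 * a1 * a2 / rr;
          break;
        }
      }
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp; uy = st * sp; uz = ct * (uz >= 0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        double nz = -st * cp * den + uz * ct;
        double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
        ux = nx / norm; uy = ny / norm; uz = nz / norm;
      }
    }
  }

  const R_xlen_t nrec = det_id.size();
  IntegerVector out_id(nrec);
  NumericMatrix out_L(nrec, nl), out_Y(nrec, nl);
  for (R_xlen_t r = 0; r < nrec; ++r) {
    out_id[r] = det_id[r];
    for (int i = 0; i < nl; ++i) {
      out_L(r, i) = recL[r * nl + i];
      out_Y(r, i) = recY[r * nl + i];
    }
  }
  NumericVector counts(nd);
  for (int d = 0; d < nd; ++d) counts[d] = (double)det_count[d];
  return List::create(_["detector_id"] = out_id, _["L"] = out_L,
                      _["Y"] = out_Y, _["detected_per_detector"] = counts,
                      _["n_launched"] = (double)np);
}
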