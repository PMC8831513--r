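// Voxel Monte Carlo photon-packet transport with a track-length fluence
// estimator, plus small geometry kernels (ball dilation, 6-connected
// component labelling) used by the phantom generator.
//
// Conventions: lengths in cm, labels index rows of the optics matrix
// (mu_a, mu_s, g, n per row), R column-major voxel order
// idx = ix + nx*(iy + ny*iz), voxel i spanning
// [corner + i*h, corner + (i+1)*h) with corner = origin - h/2.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoroshiro128+ with splitmix64 seeding, one independent substream per
// photon keyed by (seed, photon index) so results do not depend on execution
// order.
// ---------------------------------------------------------------------------
static inline uint64_t splitmix64_next(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s0, s1;
  Rng(uint64_t seed, uint64_t stream) {
    uint64_t x = (seed + 1ULL) * 0x9E3779B97F4A7C15ULL ^
                 (stream + 0x632BE59BD9B4E019ULL) * 0xD1342543DE82EF95ULL;
    s0 = splitmix64_next(x);
    s1 = splitmix64_next(x);
    if (!(s0 | s1)) s1 = 0x9E3779B97F4A7C15ULL;
  }
  inline uint64_t next() {
    uint64_t a = s0, b = s1, r = a + b;
    b ^= a;
    s0 = ((a << 55) | (a >> 9)) ^ b ^ (b << 14);
    s1 = (b << 36) | (b >> 28);
    return r;
  }
  // uniform in [0,1)
  inline double u01() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform in (0,1), safe for log()
  inline double u01open() {
    double u;
    do { u = u01(); } while (u <= 0.0);
    return u;
  }
};

// ---------------------------------------------------------------------------
// Elementary samplers / boundary physics
// ---------------------------------------------------------------------------

// Henyey-Greenstein inverse-CDF sample of the deflection cosine.
static inline double hg_cost(double g, double u) {
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
  if (ct < -1.0) ct = -1.0;
  if (ct > 1.0) ct = 1.0;
  return ct;
}

// Unpolarized Fresnel reflectance; cost receives the transmitted cosine.
// Returns 1 beyond the critical angle (total internal reflection).
static inline double fresnel_R(double ni, double nt, double cosi, double &cost) {
  if (cosi > 1.0) cosi = 1.0;
  if (cosi < 0.0) cosi = 0.0;
  if (ni == nt) { cost = cosi; return 0.0; }
  double sini2 = 1.0 - cosi * cosi;
  double sint2 = (ni / nt) * (ni / nt) * sini2;
  if (sint2 >= 1.0) { cost = 0.0; return 1.0; }
  cost = std::sqrt(1.0 - sint2);
  double rs = (ni * cosi - nt * cost) / (ni * cosi + nt * cost);
  double rp = (nt * cosi - ni * cost) / (nt * cosi + ni * cost);
  return 0.5 * (rs * rs + rp * rp);
}

// Rotate direction d by deflection cosine ct and uniform azimuth (MCML form).
static inline void scatter_dir(double ct, double phi, double *d) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  double ux = d[0], uy = d[1], uz = d[2];
  if (std::fabs(uz) > 0.99999) {
    d[0] = st * cp;
    d[1] = st * sp;
    d[2] = (uz >= 0.0 ? ct : -ct);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    d[0] = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    d[1] = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    d[2] = -st * cp * den + uz * ct;
  }
  double inv = 1.0 / std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  d[0] *= inv; d[1] *= inv; d[2] *= inv;
}

// ---------------------------------------------------------------------------
// Source model
// ---------------------------------------------------------------------------
struct Source {
  bool is_fiber;
  double pos[3];
  double axis[3];   // unit
  double e1[3], e2[3];
  double radius;    // core radius, cm
  double cos_max;   // cos of acceptance half-angle in the launch medium
};

static Source parse_source(const List &src) {
  Source s;
  std::string type = as<std::string>(src["type"]);
  s.is_fiber = (type == "fiber");
  NumericVector p = src["position"];
  for (int a = 0; a < 3; ++a) s.pos[a] = p[a];
  if (s.is_fiber) {
    NumericVector ax = src["direction"];
    double nrm = std::sqrt(ax[0]*ax[0] + ax[1]*ax[1] + ax[2]*ax[2]);
    for (int a = 0; a < 3; ++a) s.axis[a] = ax[a] / nrm;
    s.radius = as<double>(src["radius"]);
    double na = as<double>(src["na"]);
    double nmed = as<double>(src["n_medium"]);
    double sin_max = na / nmed;
    if (sin_max > 1.0) sin_max = 1.0;
    s.cos_max = std::sqrt(1.0 - sin_max * sin_max);
    // orthonormal basis perpendicular to the axis
    double k[3] = {0.0, 0.0, 1.0};
    if (std::fabs(s.axis[2]) > 0.9) { k[0] = 1.0; k[2] = 0.0; }
    s.e1[0] = s.axis[1]*k[2] - s.axis[2]*k[1];
    s.e1[1] = s.axis[2]*k[0] - s.axis[0]*k[2];
    s.e1[2] = s.axis[0]*k[1] - s.axis[1]*k[0];
    double n1 = std::sqrt(s.e1[0]*s.e1[0] + s.e1[1]*s.e1[1] + s.e1[2]*s.e1[2]);
    for (int a = 0; a < 3; ++a) s.e1[a] /= n1;
    s.e2[0] = s.axis[1]*s.e1[2] - s.axis[2]*s.e1[1];
    s.e2[1] = s.axis[2]*s.e1[0] - s.axis[0]*s.e1[2];
    s.e2[2] = s.axis[0]*s.e1[1] - s.axis[1]*s.e1[0];
  } else {
    s.axis[0] = s.axis[1] = 0.0; s.axis[2] = 1.0;
    s.radius = 0.0; s.cos_max = -1.0; // full sphere
  }
  return s;
}

static inline void launch_one(const Source &s, Rng &rng, double *p, double *d) {
  if (s.is_fiber) {
    // position uniform over the core disk
    double r = s.radius * std::sqrt(rng.u01());
    double psi = 2.0 * M_PI * rng.u01();
    double c = std::cos(psi), sn = std::sin(psi);
    for (int a = 0; a < 3; ++a)
      p[a] = s.pos[a] + r * (c * s.e1[a] + sn * s.e2[a]);
    // direction uniform in solid angle within the acceptance cone
    double ct = 1.0 - rng.u01() * (1.0 - s.cos_max);
    double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
    double phi = 2.0 * M_PI * rng.u01();
    double cp = std::cos(phi), sp = std::sin(phi);
    for (int a = 0; a < 3; ++a)
      d[a] = ct * s.axis[a] + st * (cp * s.e1[a] + sp * s.e2[a]);
  } else {
    for (int a = 0; a < 3; ++a) p[a] = s.pos[a];
    double ct = 2.0 * rng.u01() - 1.0;
    double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
    double phi = 2.0 * M_PI * rng.u01();
    d[0] = st * std::cos(phi);
    d[1] = st * std::sin(phi);
    d[2] = ct;
  }
}

// ---------------------------------------------------------------------------
// Exported samplers (unit-testable pieces of the transport kernel)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector sample_hg_cpp(double g, NumericVector u) {
  if (std::fabs(g) >= 1.0) stop("anisotropy factor g must satisfy |g| < 1");
  R_xlen_t n = u.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (u[i] < 0.0 || u[i] >= 1.0) stop("u must lie in [0, 1)");
    out[i] = hg_cost(g, u[i]);
  }
  return out;
}

// [[Rcpp::export]]
List fresnel_cpp(double n_i, double n_t, NumericVector cos_i) {
  R_xlen_t n = cos_i.size();
  NumericVector R(n), ct(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double c;
    R[i] = fresnel_R(n_i, n_t, cos_i[i], c);
    ct[i] = c;
  }
  return List::create(_["reflectance"] = R, _["cos_t"] = ct);
}

// [[Rcpp::export]]
NumericMatrix mc_launch_cpp(List source, int n, int seed) {
  Source s = parse_source(source);
  NumericMatrix out(n, 6);
  for (int i = 0; i < n; ++i) {
    Rng rng((uint64_t)(uint32_t)seed, (uint64_t)i);
    double p[3], d[3];
    launch_one(s, rng, p, d);
    out(i, 0) = p[0]; out(i, 1) = p[1]; out(i, 2) = p[2];
    out(i, 3) = d[0]; out(i, 4) = d[1]; out(i, 5) = d[2];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Main transport kernel
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List mc_simulate_cpp(IntegerVector labels, IntegerVector dims,
                     NumericVector spacing, NumericVector origin,
                     NumericMatrix optics, List source,
                     int n_photons, int seed,
                     double w_min, double p_survive) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  const double corner[3] = {origin[0] - 0.5 * hx,
                            origin[1] - 0.5 * hy,
                            origin[2] - 0.5 * hz};
  const double h[3] = {hx, hy, hz};
  const int nlab = optics.nrow();
  const double INF = 1e30;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (labels.size() != nvox) stop("labels length does not match dims");

  std::vector<double> flu(nvox, 0.0);
  double absorbed = 0.0, escaped = 0.0;
  Source src = parse_source(source);

  // flat copies: the inner loop must not pay Rcpp accessor costs
  const int *labp = INTEGER(labels);
  std::vector<double> o_mua(nlab), o_mus(nlab), o_g(nlab), o_n(nlab);
  for (int l = 0; l < nlab; ++l) {
    o_mua[l] = optics(l, 0); o_mus[l] = optics(l, 1);
    o_g[l] = optics(l, 2);   o_n[l] = optics(l, 3);
  }

  for (int ip = 0; ip < n_photons; ++ip) {
    if ((ip & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
    Rng rng((uint64_t)(uint32_t)seed, (uint64_t)ip);
    double p[3], d[3], w = 1.0;
    launch_one(src, rng, p, d);

    int iv[3];
    bool out = false;
    for (int a = 0; a < 3; ++a) {
      iv[a] = (int)std::floor((p[a] - corner[a]) / h[a]);
      if (iv[a] < 0 || iv[a] >= dims[a]) out = true;
    }
    if (out) { escaped += w; continue; }

    double tau = -std::log(rng.u01open());
    long it = 0;
    while (true) {
      if (++it > 100000000L) { absorbed += w; break; }  // safety net
      R_xlen_t idx = iv[0] + (R_xlen_t)nx * (iv[1] + (R_xlen_t)ny * iv[2]);
      int lab = labp[idx];
      if (lab < 0 || lab >= nlab) stop("label value outside optics table");
      double mua = o_mua[lab], mus = o_mus[lab];
      double g = o_g[lab], nref = o_n[lab];

      // distance to the nearest voxel face along d
      double db = INF; int ax = 0;
      for (int a = 0; a < 3; ++a) {
        double t;
        if (d[a] > 0.0)
          t = (corner[a] + (iv[a] + 1) * h[a] - p[a]) / d[a];
        else if (d[a] < 0.0)
          t = (corner[a] + iv[a] * h[a] - p[a]) / d[a];
        else
          t = INF;
        if (t < db) { db = t; ax = a; }
      }
      if (db < 0.0) db = 0.0;

      double di = (mus > 0.0) ? tau / mus : INF;
      double ell = (di < db) ? di : db;

      // expected track-length tally with continuous absorption weighting
      if (mua > 0.0) {
        double e = std::exp(-mua * ell);
        flu[idx] += w * (1.0 - e) / mua;
        absorbed += w * (1.0 - e);
        w *= e;
      } else {
        flu[idx] += w * ell;
      }
      for (int a = 0; a < 3; ++a) p[a] += ell * d[a];

      if (di < db) {
        // scattering event inside the voxel
        tau = -std::log(rng.u01open());
        double ct = hg_cost(g, rng.u01());
        scatter_dir(ct, 2.0 * M_PI * rng.u01(), d);
        if (w < w_min) {  // Russian roulette
          if (rng.u01() < p_survive) {
            absorbed -= w * (1.0 / p_survive - 1.0);
            w /= p_survive;
          } else {
            absorbed += w;
            break;
          }
        }
      } else {
        // voxel-face crossing; carry the unconsumed optical depth over
        tau -= mus * db;
        if (tau < 0.0) tau = 0.0;
        int step = (d[ax] > 0.0) ? 1 : -1;
        p[ax] = corner[ax] + (iv[ax] + (step > 0 ? 1 : 0)) * h[ax];  // snap
        int jv[3] = {iv[0], iv[1], iv[2]};
        jv[ax] += step;
        if (jv[ax] < 0 || jv[ax] >= dims[ax]) { escaped += w; break; }
        R_xlen_t jdx = jv[0] + (R_xlen_t)nx * (jv[1] + (R_xlen_t)ny * jv[2]);
        double n2 = o_n[labp[jdx]];
        if (n2 != nref) {
          double cost;
          double R = fresnel_R(nref, n2, std::fabs(d[ax]), cost);
          if (rng.u01() < R) {
            d[ax] = -d[ax];  // specular reflection, stay in current voxel
          } else {
            double ratio = nref / n2;  // Snell: scale tangential components
            for (int a = 0; a < 3; ++a) if (a != ax) d[a] *= ratio;
            d[ax] = (d[ax] > 0.0) ? cost : -cost;
            double inv = 1.0 / std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
            d[0] *= inv; d[1] *= inv; d[2] *= inv;
            iv[0] = jv[0]; iv[1] = jv[1]; iv[2] = jv[2];
          }
        } else {
          iv[0] = jv[0]; iv[1] = jv[1]; iv[2] = jv[2];
        }
      }
    }
  }

  // fluence per unit delivered power: sum(w*l) / (V_voxel * N)  [cm^-2]
  const double norm = 1.0 / (hx * hy * hz * (double)n_photons);
  NumericVector flout(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) flout[i] = flu[i] * norm;
  return List::create(_["fluence"] = flout,
                      _["absorbed"] = absorbed / n_photons,
                      _["escaped"] = escaped / n_photons);
}

// ---------------------------------------------------------------------------
// Geometry kernels
// ---------------------------------------------------------------------------

// Mark all voxels whose center lies within Euclidean distance `thickness`
// (cm) of the center of any voxel set in `mask` (anisotropic ball
// dilation; equivalent to thresholding the Euclidean distance transform of
// the mask centers at `thickness`).
// [[Rcpp::export]]
LogicalVector dilate_ball_cpp(LogicalVector mask, IntegerVector dims,
                              NumericVector spacing, double thickness) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  const double t2 = thickness * thickness;
  const int rx = (int)std::floor(thickness / hx);
  const int ry = (int)std::floor(thickness / hy);
  const int rz = (int)std::floor(thickness / hz);
  std::vector<int> off;
  for (int dz = -rz; dz <= rz; ++dz)
    for (int dy = -ry; dy <= ry; ++dy)
      for (int dx = -rx; dx <= rx; ++dx) {
        double d2 = dx*hx*dx*hx + dy*hy*dy*hy + dz*hz*dz*hz;
        if (d2 <= t2 + 1e-12) { off.push_back(dx); off.push_back(dy); off.push_back(dz); }
      }
  LogicalVector out((R_xlen_t)nx * ny * nz);
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        R_xlen_t idx = ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        if (!mask[idx]) continue;
        for (size_t k = 0; k < off.size(); k += 3) {
          int jx = ix + off[k], jy = iy + off[k+1], jz = iz + off[k+2];
          if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
            continue;
          out[jx + (R_xlen_t)nx * (jy + (R_xlen_t)ny * jz)] = true;
        }
      }
  return out;
}

// 6-connected component labelling (1..K, 0 = background), BFS flood fill.
// [[Rcpp::export]]
IntegerVector label_components6_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  IntegerVector comp(nvox);  // zero-initialized
  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t s = 0; s < nvox; ++s) {
    if (!mask[s] || comp[s] != 0) continue;
    ++next_label;
    comp[s] = next_label;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int ix = (int)(cur % nx);
      int iy = (int)((cur / nx) % ny);
      int iz = (int)(cur / ((R_xlen_t)nx * ny));
      const int nb[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int jx = ix + nb[k][0], jy = iy + nb[k][1], jz = iz + nb[k][2];
        if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
          continue;
        R_xlen_t j = jx + (R_xlen_t)nx * (jy + (R_xlen_t)ny * jz);
        if (mask[j] && comp[j] == 0) { comp[j] = next_label; stack.push_back(j); }
      }
    }
  }
  return comp;
}
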