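// Voxelated photon-packet Monte Carlo transport kernel.
//
// Photons carry a continuous weight; absorption attenuates the weight along
// each ray segment (exp(-mua*l)) and the deposited energy is scored into the
// traversed voxel.  Fluence is recovered in R as deposited/(mua*V*Nphotons);
// the kernel already stores deposited/mua (path-length estimator in the
// mua -> 0 limit), so the R side only divides by V*Nphotons.
//
// Each photon owns a splitmix64 stream derived from (run seed, photon index),
// so results are independent of scheduling/order and fully reproducible.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double C0_MM_NS = 299.792458; // speed of light in vacuum, mm/ns

static inline uint64_t splitmix64(uint64_t& s) {
  s += 0x9E3779B97F4A7C15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// murmur3-style 64-bit finalizer
static inline uint64_t fmix64(uint64_t z) {
  z ^= z >> 33;
  z *= 0xFF51AFD7ED558CCDULL;
  z ^= z >> 33;
  z *= 0xC4CEB9FE1A85EC53ULL;
  z ^= z >> 33;
  return z;
}

struct PhotonRng {
  uint64_t state;
  PhotonRng(uint64_t seed, uint64_t idx) {
    // hash (seed, photon index) to a pseudo-random stream offset; photon
    // streams must NOT sit on an arithmetic progression with the splitmix64
    // increment or consecutive photons would replay shifted draw sequences
    state = fmix64(fmix64(seed ^ 0xD2B74407B1CE6E93ULL) ^
                   (idx + 0x632BE59BD9B4E019ULL));
  }
  // uniform in [0, 1)
  double u() { return (splitmix64(state) >> 11) * (1.0 / 9007199254740992.0); }
};

// Henyey-Greenstein inverse-CDF sample of the deflection cosine.
static inline double hg_cost(double g, double u) {
  if (std::fabs(g) < 1e-8) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// [[Rcpp::export(name = ".hg_sample_cpp")]]
NumericVector hg_sample_cpp(double g, NumericVector u) {
  if (!(g > -1.0 && g < 1.0)) stop("anisotropy g must lie in (-1, 1)");
  R_xlen_t n = u.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (u[i] < 0.0 || u[i] >= 1.0) stop("uniform deviates must lie in [0, 1)");
    out[i] = hg_cost(g, u[i]);
  }
  return out;
}

// unpolarized Fresnel reflectance for incidence cosine ci, indices n1 -> n2
static inline double fresnel_R(double n1, double n2, double ci, double& ct) {
  double s2t = (n1 / n2) * (n1 / n2) * (1.0 - ci * ci);
  if (s2t >= 1.0) { ct = 0.0; return 1.0; } // total internal reflection
  ct = std::sqrt(1.0 - s2t);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

static inline void scatter_dir(double* d, double g, PhotonRng& rng) {
  double ct = hg_cost(g, rng.u());
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * rng.u();
  double cp = std::cos(phi), sp = std::sin(phi);
  double dx = d[0], dy = d[1], dz = d[2];
  if (std::fabs(dz) > 0.999999) {
    d[0] = st * cp;
    d[1] = st * sp;
    d[2] = ct * (dz > 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - dz * dz);
    d[0] = st * (dx * dz * cp - dy * sp) / den + dx * ct;
    d[1] = st * (dy * dz * cp + dx * sp) / den + dy * ct;
    d[2] = -st * cp * den + dz * ct;
  }
  double nrm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  d[0] /= nrm; d[1] /= nrm; d[2] /= nrm;
}

// [[Rcpp::export(name = ".mc_simulate_cpp")]]
List mc_simulate_cpp(IntegerVector label, IntegerVector dims, double h,
                     NumericVector mua, NumericVector mus,
                     NumericVector gv, NumericVector nv,
                     NumericVector src_pos, int src_isotropic,
                     NumericVector src_dir,
                     double nphoton, double tgate_ns, int fresnel_boundary,
                     int roulette_on, double roulette_thresh,
                     double roulette_p, double seed) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (label.size() != nvox) stop("label grid size mismatch");
  NumericVector flu(nvox); // sum of w*(1-exp(-mua l))/mua  (units: weight*mm)
  double launched = 0.0, absorbed = 0.0, escaped = 0.0, gated = 0.0,
         residual = 0.0;
  const long long np = (long long)nphoton;
  const uint64_t useed = (uint64_t)((int64_t)seed);
  const long long max_events = 50000000LL; // safety cap per photon

  for (long long ip = 0; ip < np; ++ip) {
    PhotonRng rng(useed, (uint64_t)ip);
    double p[3] = {src_pos[0], src_pos[1], src_pos[2]};
    double d[3];
    if (src_isotropic) {
      double cz = 2.0 * rng.u() - 1.0;
      double sz = std::sqrt(std::max(0.0, 1.0 - cz * cz));
      double ph = 2.0 * M_PI * rng.u();
      d[0] = sz * std::cos(ph); d[1] = sz * std::sin(ph); d[2] = cz;
    } else {
      d[0] = src_dir[0]; d[1] = src_dir[1]; d[2] = src_dir[2];
    }
    int iv[3] = {(int)std::floor(p[0] / h), (int)std::floor(p[1] / h),
                 (int)std::floor(p[2] / h)};
    for (int a = 0; a < 3; ++a) {
      if (iv[a] < 0) iv[a] = 0;
      if (iv[a] >= dims[a]) iv[a] = dims[a] - 1;
    }
    double w = 1.0, t = 0.0;
    launched += 1.0;
    bool alive = true;
    long long events = 0;
    double tau = -std::log(1.0 - rng.u()); // scattering optical depth to go

    while (alive) {
      if (++events > max_events) { residual += w; break; }
      R_xlen_t vidx = (R_xlen_t)iv[0] + nx * ((R_xlen_t)iv[1] + (R_xlen_t)ny * iv[2]);
      int lab = label[vidx];
      double va = mua[lab], vs = mus[lab], vg = gv[lab], vn = nv[lab];

      // candidate distances: voxel boundary, scattering site, time gate
      double db = 1e300; int baxis = -1; int bstep = 0;
      for (int a = 0; a < 3; ++a) {
        if (d[a] > 1e-12) {
          double dist = ((iv[a] + 1) * h - p[a]) / d[a];
          if (dist < db) { db = dist; baxis = a; bstep = 1; }
        } else if (d[a] < -1e-12) {
          double dist = (iv[a] * h - p[a]) / d[a];
          if (dist < db) { db = dist; baxis = a; bstep = -1; }
        }
      }
      if (db < 0.0) db = 0.0;
      double ds = (vs > 0.0) ? tau / vs : 1e300;
      double dt = (tgate_ns - t) * C0_MM_NS / vn;
      if (dt < 0.0) dt = 0.0;

      double step = db; int what = 0; // 0 boundary, 1 scatter, 2 gate
      if (ds < step) { step = ds; what = 1; }
      if (dt <= step) { step = dt; what = 2; }

      // score the segment and attenuate the packet weight
      if (step > 0.0) {
        if (va > 1e-12) {
          double att = std::exp(-va * step);
          double dep = w * (1.0 - att);
          flu[vidx] += dep / va;
          absorbed += dep;
          w *= att;
        } else {
          flu[vidx] += w * step;
        }
        t += step * vn / C0_MM_NS;
        p[0] += step * d[0]; p[1] += step * d[1]; p[2] += step * d[2];
        if (vs > 0.0) tau -= vs * step;
      }

      if (what == 2) { gated += w; break; }
      if (what == 1) {
        scatter_dir(d, vg, rng);
        tau = -std::log(1.0 - rng.u());
        if (roulette_on && w < roulette_thresh) {
          if (rng.u() < roulette_p) w /= roulette_p;
          else { absorbed += w; break; }
        }
        continue;
      }

      // voxel face crossing: pin position to the face for robustness
      p[baxis] = (bstep > 0 ? (iv[baxis] + 1) : iv[baxis]) * h;
      int nxt = iv[baxis] + bstep;
      bool outside = (nxt < 0 || nxt >= dims[baxis]);
      double n2;
      if (outside) {
        if (!fresnel_boundary) { escaped += w; break; }
        n2 = 1.0; // external medium
      } else {
        int jv[3] = {iv[0], iv[1], iv[2]};
        jv[baxis] = nxt;
        R_xlen_t widx = (R_xlen_t)jv[0] + nx * ((R_xlen_t)jv[1] + (R_xlen_t)ny * jv[2]);
        n2 = nv[label[widx]];
      }
      if (n2 != vn) {
        double ci = std::fabs(d[baxis]);
        double ct;
        double R = fresnel_R(vn, n2, ci, ct);
        if (rng.u() < R) {
          d[baxis] = -d[baxis]; // specular reflection, stay in voxel
          continue;
        }
        // refraction across the axis-aligned face
        double ratio = vn / n2;
        for (int a = 0; a < 3; ++a)
          if (a != baxis) d[a] *= ratio;
        d[baxis] = (d[baxis] > 0 ? ct : -ct);
        double nrm = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
        d[0] /= nrm; d[1] /= nrm; d[2] /= nrm;
      }
      if (outside) { escaped += w; break; }
      iv[baxis] = nxt;
    }
  }

  return List::create(_["fluence_raw"] = flu,
                      _["launched"] = launched,
                      _["absorbed"] = absorbed,
                      _["escaped"] = escaped,
                      _["gated"] = gated,
                      _["residual"] = residual);
}
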