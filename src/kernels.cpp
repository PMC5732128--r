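// Monte Carlo photon transport (forward projector) and analytical
// ray-tracing back-projector kernels.
//
// The RNG is counter-based: every (history, unit) pair gets its own
// splitmix64 substream keyed on the master seed, so results are bit-for-bit
// reproducible and independent of execution order.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline uint64_t mix64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct RNG {
  uint64_t s;
  explicit RNG(uint64_t seed) : s(seed) { next(); next(); }
  uint64_t next() { s += 0x9E3779B97F4A7C15ULL; return mix64(s); }
  // uniform in [0, 1)
  double u() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform in (0, 1]
  double u01() { double v = 1.0 - u(); return v; }
  double gauss() {
    double a = u01(), b = u();
    return std::sqrt(-2.0 * std::log(a)) * std::cos(2.0 * M_PI * b);
  }
};

static inline uint64_t streamKey(uint64_t seed, uint64_t h, uint64_t k) {
  return mix64(seed * 0x9E3779B97F4A7C15ULL ^
               (h + 1) * 0xD1B54A32D192ED03ULL ^
               (k + 1) * 0x8CB92BA72F3D8DD7ULL);
}

struct Vec3 { double x, y, z; };

static inline Vec3 vadd(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline Vec3 vscale(Vec3 a, double s) { return {a.x * s, a.y * s, a.z * s}; }
static inline double vdot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline double vnorm(Vec3 a) { return std::sqrt(vdot(a, a)); }

// orthonormal basis perpendicular to unit vector w
static inline void basis(Vec3 w, Vec3 &u, Vec3 &v) {
  if (std::fabs(w.x) < 0.9) u = {0.0, -w.z, w.y};
  else u = {-w.z, 0.0, w.x};
  double n = vnorm(u);
  u = vscale(u, 1.0 / n);
  v = {w.y * u.z - w.z * u.y, w.z * u.x - w.x * u.z, w.x * u.y - w.y * u.x};
}

struct Unit {
  double rot[9];        // world -> pinhole frame rotation (row-major)
  double R, H, apRadius, pitch, colMu, tilt;
  int nPix;
  Vec3 pinhole;         // world position of the pinhole centre
};

static inline Vec3 toFrame(const Unit &u, Vec3 p) {
  return {u.rot[0] * p.x + u.rot[1] * p.y + u.rot[2] * p.z,
          u.rot[3] * p.x + u.rot[4] * p.y + u.rot[5] * p.z,
          u.rot[6] * p.x + u.rot[7] * p.y + u.rot[8] * p.z};
}

struct Tables {
  int nE;
  double e0;            // first tabulated energy (keV), 1-keV spacing
  const double *peAir, *peWater, *incAir, *incWater;
  // total mass attenuation (cm^2/g); fPE = photoelectric fraction of total
  double muRho(double E, int material, double &fPE) const {
    double t = E - e0;
    int i = (int)std::floor(t);
    if (i < 0) { i = 0; t = 0.0; }
    if (i > nE - 2) { i = nE - 2; t = nE - 1.0; }
    double w = t - i;
    const double *pe = material == 0 ? peAir : peWater;
    const double *inc = material == 0 ? incAir : incWater;
    double peV = pe[i] * (1 - w) + pe[i + 1] * w;
    double incV = inc[i] * (1 - w) + inc[i + 1] * w;
    double tot = peV + incV;
    fPE = tot > 0 ? peV / tot : 0.0;
    return tot;
  }
};

struct Phantom {
  int N;
  double m;             // voxel side (mm)
  const double *dens;   // g/cm^3
  const int *mat;       // 0 air, 1 water, 2 other(water-like)
  double rhoMax;        // majorant density for delta tracking
  double half() const { return 0.5 * N * m; }
  bool inside(Vec3 p) const {
    double h = half();
    return p.x > -h && p.x < h && p.y > -h && p.y < h && p.z > -h && p.z < h;
  }
  // linear attenuation (1/mm) at energy E in the voxel containing p
  double mu(Vec3 p, double E, const Tables &tab, double &fPE) const {
    int ix = (int)std::floor(p.x / m + 0.5 * N);
    int iy = (int)std::floor(p.y / m + 0.5 * N);
    int iz = (int)std::floor(p.z / m + 0.5 * N);
    if (ix < 0 || ix >= N || iy < 0 || iy >= N || iz < 0 || iz >= N) {
      fPE = 0.0; return 0.0;
    }
    size_t j = (size_t)ix + (size_t)N * (iy + (size_t)N * iz);
    double rho = dens[j];
    if (rho <= 0.0) { fPE = 0.0; return 0.0; }
    int mm = mat[j]; if (mm == 2) mm = 1;
    double mr = tab.muRho(E, mm, fPE);
    return rho * mr * 0.1;  // (cm^2/g * g/cm^3) = 1/cm -> 1/mm
  }
};

static inline double sampleComptonCos(double E, RNG &rng) {
  // rejection sampling of the Klein-Nishina angular distribution;
  // the ratio function is bounded by its forward value 2
  double k = E / 511.0;
  for (;;) {
    double c = 1.0 - 2.0 * rng.u();
    double eps = 1.0 / (1.0 + k * (1.0 - c));
    double f = eps * eps * (eps + 1.0 / eps - (1.0 - c * c));
    if (2.0 * rng.u() <= f) return c;
  }
}

// Track a photon through the voxel phantom by Woodcock (delta) tracking:
// free paths are sampled against the majorant attenuation and collisions
// are accepted with probability mu(x)/mu_max, which reproduces the exact
// heterogeneous free-path distribution. Returns false when absorbed; on
// return pos/dir/E hold the exit state. nScatter counts Compton events.
static bool tracePhoton(Vec3 &pos, Vec3 &dir, double &E, int &nScatter,
                        const Phantom &ph, const Tables &tab, RNG &rng,
                        int maxOrder, double eMin) {
  if (ph.rhoMax <= 0.0) return true;   // non-attenuating medium
  double fPEw;
  double muMax = ph.rhoMax * tab.muRho(E, 1, fPEw) * 0.1;  // water majorant
  for (;;) {
    if (!ph.inside(pos)) return true;
    double s = -std::log(rng.u01()) / muMax;
    Vec3 prev = pos;
    pos = vadd(pos, vscale(dir, s));
    if (!ph.inside(pos)) {
      // exited: report a point on the exit ray that is still inside the
      // grid so downstream plane intersections see the full ray ahead
      pos = prev;
      return true;
    }
    double fPE;
    double mu = ph.mu(pos, E, tab, fPE);
    if (rng.u() * muMax >= mu) continue;          // null collision
    if (rng.u() < fPE) return false;              // photoelectric absorption
    ++nScatter;
    if (nScatter > maxOrder) return false;        // beyond modelled order
    double c = sampleComptonCos(E, rng);
    E = E / (1.0 + (E / 511.0) * (1.0 - c));
    if (E < eMin) return false;
    double sa = std::sqrt(std::max(0.0, 1.0 - c * c));
    double phi = 2.0 * M_PI * rng.u();
    Vec3 u, v;
    basis(dir, u, v);
    dir = vadd(vscale(dir, c),
               vadd(vscale(u, sa * std::cos(phi)),
                    vscale(v, sa * std::sin(phi))));
    muMax = ph.rhoMax * tab.muRho(E, 1, fPEw) * 0.1;
  }
}

// Aperture test on the pinhole plane of a unit. Returns the transmission
// factor (1 inside the aperture, exp-attenuated knife-edge path outside when
// penetration is on, else 0) and fills the frame-space state at the plane.
static double apertureTransmission(const Unit &un, Vec3 posF, Vec3 dirF,
                                   bool penetration) {
  if (dirF.z <= 1e-12) return 0.0;
  double t = (un.R - posF.z) / dirF.z;
  if (t <= 0) return 0.0;
  double xi = posF.x + dirF.x * t;
  double yi = posF.y + dirF.y * t;
  double rho = std::sqrt(xi * xi + yi * yi);
  if (rho <= un.apRadius) return 1.0;
  if (!penetration) return 0.0;
  // knife-edge wedge, 90-degree opening: chord length ~ 2 * miss distance
  double chord = 2.0 * (rho - un.apRadius);
  double f = std::exp(-un.colMu * chord);
  return f < 1e-12 ? 0.0 : f;
}

// Detector intercept in frame coordinates; returns false when the ray
// misses the detector plane. Supports a detector tilted about the frame
// x-axis through the axis point at z' = R + H.
static bool detectorHit(const Unit &un, Vec3 posF, Vec3 dirF,
                        double &xd, double &yd) {
  if (un.tilt == 0.0) {
    if (dirF.z <= 1e-12) return false;
    double t = (un.R + un.H - posF.z) / dirF.z;
    if (t <= 0) return false;
    xd = posF.x + dirF.x * t;
    yd = posF.y + dirF.y * t;
    return true;
  }
  double st = std::sin(un.tilt), ct = std::cos(un.tilt);
  // plane through (0, 0, R+H) with normal (0, sin t, cos t)
  double denom = dirF.y * st + dirF.z * ct;
  if (std::fabs(denom) < 1e-12) return false;
  double t = ((un.R + un.H) * ct - (posF.y * st + posF.z * ct)) / denom;
  if (t <= 0) return false;
  double px = posF.x + dirF.x * t;
  double py = posF.y + dirF.y * t;
  double pz = posF.z + dirF.z * t;
  xd = px;
  yd = py * ct - (pz - (un.R + un.H)) * st;
  return true;
}

static std::vector<Unit> buildUnits(const NumericMatrix &geom) {
  // columns: theta phi R H aperture nPix pitch tilt colMu
  std::vector<Unit> units(geom.nrow());
  for (int k = 0; k < geom.nrow(); ++k) {
    double th = geom(k, 0), phi = geom(k, 1);
    Unit &u = units[k];
    double ct = std::cos(th), st = std::sin(th);
    double cp = std::cos(phi), sp = std::sin(phi);
    double r[9] = {cp, sp * st, sp * ct,
                   0,  ct,     -st,
                   -sp, cp * st, cp * ct};
    for (int i = 0; i < 9; ++i) u.rot[i] = r[i];
    u.R = geom(k, 2); u.H = geom(k, 3);
    u.apRadius = 0.5 * geom(k, 4);
    u.nPix = (int)geom(k, 5);
    u.pitch = geom(k, 6);
    u.tilt = geom(k, 7);
    u.colMu = geom(k, 8);
    u.pinhole = {-sp * u.R, cp * st * u.R, cp * ct * u.R};
  }
  return units;
}

// [[Rcpp::export(name = ".mcForwardCpp")]]
List mcForwardCpp(IntegerVector historyMap, int N, double m,
                  NumericVector density, IntegerVector material,
                  NumericMatrix geom, NumericVector peAir,
                  NumericVector peWater, NumericVector incAir,
                  NumericVector incWater, double e0, double emissionEnergy,
                  double baseWeight, double seed, int maxOrder,
                  bool penetration, double eResFWHM, double windowLow,
                  double windowHigh, double forcedDiscFactor, bool analog,
                  int nSpecBins) {
  int K = geom.nrow();
  std::vector<Unit> units = buildUnits(geom);
  double rhoMax = 0.0;
  for (R_xlen_t i = 0; i < density.size(); ++i)
    if (density[i] > rhoMax) rhoMax = density[i];
  Phantom ph{N, m, REAL(density), INTEGER(material), rhoMax};
  Tables tab{(int)peAir.size(), e0, REAL(peAir), REAL(peWater),
             REAL(incAir), REAL(incWater)};
  int nPix = units.empty() ? 0 : units[0].nPix;
  NumericVector cnt(Dimension(nPix, nPix, K));
  NumericVector spectrum(nSpecBins);
  double *cp = REAL(cnt);
  double eMin = 2.0;  // photons below 2 keV are locally absorbed
  uint64_t useed = (uint64_t)seed;
  double sigmaRef = eResFWHM / 100.0 * 140.5 / 2.35482;

  uint64_t h = 0;
  size_t nvox = (size_t)N * N * N;
  for (size_t j = 0; j < nvox; ++j) {
    int nh = historyMap[j];
    if (nh <= 0) continue;
    int ix = (int)(j % (size_t)N);
    int iy = (int)((j / (size_t)N) % (size_t)N);
    int iz = (int)(j / ((size_t)N * N));
    double x0 = (ix - 0.5 * (N - 1)) * m;
    double y0 = (iy - 0.5 * (N - 1)) * m;
    double z0 = (iz - 0.5 * (N - 1)) * m;
    for (int hh = 0; hh < nh; ++hh, ++h) {
      RNG prng(streamKey(useed, h, 0xFFFFFFULL));
      Vec3 origin = {x0 + (prng.u() - 0.5) * m,
                     y0 + (prng.u() - 0.5) * m,
                     z0 + (prng.u() - 0.5) * m};
      if (analog) {
        RNG rng(streamKey(useed, h, 0xABCDEFULL));
        double c = 1.0 - 2.0 * rng.u();
        double s = std::sqrt(std::max(0.0, 1.0 - c * c));
        double az = 2.0 * M_PI * rng.u();
        Vec3 dir = {s * std::cos(az), s * std::sin(az), c};
        Vec3 pos = origin;
        double E = emissionEnergy;
        int nsc = 0;
        if (!tracePhoton(pos, dir, E, nsc, ph, tab, rng, maxOrder, eMin))
          continue;
        for (int k = 0; k < K; ++k) {
          const Unit &un = units[k];
          Vec3 pF = toFrame(un, pos), dF = toFrame(un, dir);
          double trans = apertureTransmission(un, pF, dF, penetration);
          if (trans <= 0) continue;
          double xd, yd;
          if (!detectorHit(un, pF, dF, xd, yd)) continue;
          int col = (int)std::floor(xd / un.pitch + 0.5 * un.nPix);
          int row = (int)std::floor(yd / un.pitch + 0.5 * un.nPix);
          if (col < 0 || col >= un.nPix || row < 0 || row >= un.nPix)
            continue;
          double Eobs = E;
          if (sigmaRef > 0)
            Eobs += sigmaRef * std::sqrt(E / 140.5) * rng.gauss();
          double w = baseWeight * trans;
          int sb = (int)std::floor(Eobs);
          if (sb >= 0 && sb < nSpecBins) spectrum[sb] += w;
          if (Eobs < windowLow || Eobs > windowHigh) continue;
          cp[row + nPix * (col + (size_t)nPix * k)] += w;
        }
      } else {
        for (int k = 0; k < K; ++k) {
          const Unit &un = units[k];
          RNG rng(streamKey(useed, h, (uint64_t)k));
          Vec3 axis = {un.pinhole.x - origin.x, un.pinhole.y - origin.y,
                       un.pinhole.z - origin.z};
          double r = vnorm(axis);
          if (r < 1e-9) continue;
          axis = vscale(axis, 1.0 / r);
          double discR = forcedDiscFactor * un.apRadius; // diam 4d -> radius 2d
          double cosMax = r / std::sqrt(r * r + discR * discR);
          double wSolid = 0.5 * (1.0 - cosMax);
          if (wSolid <= 0) continue;
          double c = 1.0 - rng.u() * (1.0 - cosMax);
          double s = std::sqrt(std::max(0.0, 1.0 - c * c));
          double az = 2.0 * M_PI * rng.u();
          Vec3 b1, b2;
          basis(axis, b1, b2);
          Vec3 dir = vadd(vscale(axis, c),
                          vadd(vscale(b1, s * std::cos(az)),
                               vscale(b2, s * std::sin(az))));
          Vec3 pos = origin;
          double E = emissionEnergy;
          int nsc = 0;
          if (!tracePhoton(pos, dir, E, nsc, ph, tab, rng, maxOrder, eMin))
            continue;
          Vec3 pF = toFrame(un, pos), dF = toFrame(un, dir);
          double trans = apertureTransmission(un, pF, dF, penetration);
          if (trans <= 0) continue;
          double xd, yd;
          if (!detectorHit(un, pF, dF, xd, yd)) continue;
          int col = (int)std::floor(xd / un.pitch + 0.5 * un.nPix);
          int row = (int)std::floor(yd / un.pitch + 0.5 * un.nPix);
          if (col < 0 || col >= un.nPix || row < 0 || row >= un.nPix)
            continue;
          double Eobs = E;
          if (sigmaRef > 0)
            Eobs += sigmaRef * std::sqrt(E / 140.5) * rng.gauss();
          double w = baseWeight * wSolid * trans;
          int sb = (int)std::floor(Eobs);
          if (sb >= 0 && sb < nSpecBins) spectrum[sb] += w;
          if (Eobs < windowLow || Eobs > windowHigh) continue;
          cp[row + nPix * (col + (size_t)nPix * k)] += w;
        }
      }
    }
  }
  return List::create(_["counts"] = cnt, _["spectrum"] = spectrum,
                      _["historiesUsed"] = (double)h);
}

// [[Rcpp::export(name = ".traceBatchCpp")]]
List traceBatchCpp(int nPhotons, NumericVector start, NumericVector dir0,
                   double energy, int N, double m, NumericVector density,
                   IntegerVector material, NumericVector peAir,
                   NumericVector peWater, NumericVector incAir,
                   NumericVector incWater, double e0, double seed,
                   int maxOrder) {
  double rhoMax = 0.0;
  for (R_xlen_t i = 0; i < density.size(); ++i)
    if (density[i] > rhoMax) rhoMax = density[i];
  Phantom ph{N, m, REAL(density), INTEGER(material), rhoMax};
  Tables tab{(int)peAir.size(), e0, REAL(peAir), REAL(peWater),
             REAL(incAir), REAL(incWater)};
  LogicalVector alive(nPhotons);
  NumericVector eOut(nPhotons);
  IntegerVector nsc(nPhotons);
  NumericMatrix posOut(nPhotons, 3), dirOut(nPhotons, 3);
  for (int i = 0; i < nPhotons; ++i) {
    RNG rng(streamKey((uint64_t)seed, (uint64_t)i, 7ULL));
    Vec3 pos = {start[0], start[1], start[2]};
    Vec3 dir = {dir0[0], dir0[1], dir0[2]};
    double E = energy;
    int ns = 0;
    bool ok = tracePhoton(pos, dir, E, ns, ph, tab, rng, maxOrder, 2.0);
    alive[i] = ok;
    eOut[i] = E;
    nsc[i] = ns;
    posOut(i, 0) = pos.x; posOut(i, 1) = pos.y; posOut(i, 2) = pos.z;
    dirOut(i, 0) = dir.x; dirOut(i, 1) = dir.y; dirOut(i, 2) = dir.z;
  }
  return List::create(_["alive"] = alive, _["energy"] = eOut,
                      _["nScatter"] = nsc, _["position"] = posOut,
                      _["direction"] = dirOut);
}

// [[Rcpp::export(name = ".backprojectCpp")]]
List backprojectCpp(NumericVector ratios, NumericMatrix geom, int N,
                    double m, double distScale, int denomMode) {
  int K = geom.nrow();
  std::vector<Unit> units = buildUnits(geom);
  int nPix = units.empty() ? 0 : units[0].nPix;
  NumericVector vol(Dimension(N, N, N));
  NumericVector den(Dimension(N, N, N));
  const double *rp = REAL(ratios);
  double *vp = REAL(vol), *dp = REAL(den);

  for (int iz = 0; iz < N; ++iz) {
    double z = (iz - 0.5 * (N - 1)) * m;
    for (int iy = 0; iy < N; ++iy) {
      double y = (iy - 0.5 * (N - 1)) * m;
      for (int ix = 0; ix < N; ++ix) {
        double x = (ix - 0.5 * (N - 1)) * m;
        double num = 0.0, denom = 0.0;
        for (int k = 0; k < K; ++k) {
          const Unit &u = units[k];
          double zp = u.rot[6] * x + u.rot[7] * y + u.rot[8] * z;
          double dist = u.R - zp;
          if (dist <= 0) continue;                 // behind the pinhole: skip
          double xp = u.rot[0] * x + u.rot[1] * y + u.rot[2] * z;
          double yp = u.rot[3] * x + u.rot[4] * y + u.rot[5] * z;
          double M = u.H / dist;
          double xd = -M * xp, yd = -M * yp;
          int ng = (int)std::floor(
              2.0 + 60.0 / (1.0 + std::pow(dist * distScale, 0.8)) + 0.5);
          double G = m * M;
          double invPitch = 1.0 / u.pitch;
          int onDet = 0;
          double acc = 0.0;
          for (int gi = 0; gi < ng; ++gi) {
            double px = xd + ((gi + 0.5) / ng - 0.5) * G;
            int col = (int)std::floor(px * invPitch + 0.5 * u.nPix);
            if (col < 0 || col >= u.nPix) continue;
            for (int gj = 0; gj < ng; ++gj) {
              double py = yd + ((gj + 0.5) / ng - 0.5) * G;
              int row = (int)std::floor(py * invPitch + 0.5 * u.nPix);
              if (row < 0 || row >= u.nPix) continue;
              acc += rp[row + (size_t)nPix * (col + (size_t)nPix * k)];
              ++onDet;
            }
          }
          num += acc;
          denom += denomMode == 0 ? (double)ng * ng : (double)onDet;
        }
        size_t j = (size_t)ix + (size_t)N * (iy + (size_t)N * iz);
        dp[j] = denom;
        vp[j] = denom > 0 ? num / denom : 0.0;
      }
    }
  }
  return List::create(_["volume"] = vol, _["denominator"] = den);
}
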