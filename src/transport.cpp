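// Monte Carlo photon transport through stacked elliptical-slab phantoms.
//
// Physics: photoelectric absorption (local energy deposit, kerma
// approximation) and incoherent (Compton) scattering sampled from the
// Klein-Nishina differential cross section; coherent scattering excluded.
// Geometry handled by Woodcock (delta) tracking against the majorant linear
// attenuation, so no surface-intersection code is needed. Energies in keV,
// lengths in mm. Single RNG stream per call (mt19937_64, splitmix-mixed
// seed), bit-identical results for identical seeds.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double ELECTRON_REST_KEV = 510.998950;

struct Rng {
  std::mt19937_64 gen;
  std::uniform_real_distribution<double> unif;
  Rng(uint64_t seed) : unif(0.0, 1.0) {
    // splitmix64 scramble so that nearby seeds give unrelated streams
    uint64_t z = seed + 0x9e3779b97f4a7c15ULL;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    gen.seed(z ^ (z >> 31));
  }
  double u() { return unif(gen); }
};

// Klein-Nishina energy-ratio sampling (Butcher & Messel style rejection).
// Returns eps = E'/E; cos(theta) = 1 - (1-eps)/(alpha*eps).
static double sample_kn_eps(double alpha, Rng& rng) {
  const double eps0 = 1.0 / (1.0 + 2.0 * alpha);
  const double a1 = std::log(1.0 / eps0);
  const double a2 = 0.5 * (1.0 - eps0 * eps0);
  double eps, sint2, greject;
  do {
    if (rng.u() * (a1 + a2) < a1) {
      eps = eps0 * std::exp(a1 * rng.u());
    } else {
      eps = std::sqrt(eps0 * eps0 + (1.0 - eps0 * eps0) * rng.u());
    }
    double t = (1.0 - eps) / (alpha * eps);
    sint2 = t * (2.0 - t);
    greject = 1.0 - eps * sint2 / (1.0 + eps * eps);
  } while (rng.u() > greject);
  return eps;
}

// polynomial rolling hash mod 2^31 - 1 (same definition as the R fallback);
// used to derive reproducible sub-stream seeds from string keys
// [[Rcpp::export]]
int cpp_hash_seed(std::string key) {
  uint64_t h = 17;
  for (unsigned char c : key) h = (h * 131 + c) % 2147483647ULL;
  return static_cast<int>(h);
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_compton(double energy_kev, int n, int seed) {
  if (energy_kev < 1.0 || energy_kev > 200.0)
    stop("photon energy must be in [1, 200] keV");
  Rng rng(static_cast<uint64_t>(seed));
  double alpha = energy_kev / ELECTRON_REST_KEV;
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double eps = sample_kn_eps(alpha, rng);
    double ct = 1.0 - (1.0 - eps) / (alpha * eps);
    if (ct > 1.0) ct = 1.0; if (ct < -1.0) ct = -1.0;
    out(i, 0) = energy_kev * eps;
    out(i, 1) = std::acos(ct);
  }
  colnames(out) = CharacterVector::create("energy_kev", "theta");
  return out;
}

struct Geometry {
  int n_slab;
  const double *slab_z;            // n_slab + 1 boundaries
  const double *slab_a, *slab_b;
  const int *slab_mat, *slab_tally;
  const int *reg_start, *reg_count; // per-slab index into region arrays
  const double *reg_cx, *reg_cy, *reg_a, *reg_b;
  const int *reg_mat, *reg_tally;
  int air_mat;
  double xmax, ymax;

  // material + tally at a point; material -1 = outside bounding box
  inline void locate(double x, double y, double z, int& mat, int& tally) const {
    if (z < slab_z[0] || z >= slab_z[n_slab] ||
        std::fabs(x) > xmax || std::fabs(y) > ymax) {
      mat = -1; tally = -1; return;
    }
    // linear scan is fine: slab count is ~10
    int s = n_slab - 1;
    for (int i = 0; i < n_slab; ++i) {
      if (z < slab_z[i + 1]) { s = i; break; }
    }
    for (int r = reg_start[s]; r < reg_start[s] + reg_count[s]; ++r) {
      double dx = (x - reg_cx[r]) / reg_a[r], dy = (y - reg_cy[r]) / reg_b[r];
      if (dx * dx + dy * dy <= 1.0) { mat = reg_mat[r]; tally = reg_tally[r]; return; }
    }
    double dx = x / slab_a[s], dy = y / slab_b[s];
    if (dx * dx + dy * dy <= 1.0) { mat = slab_mat[s]; tally = slab_tally[s]; return; }
    mat = air_mat; tally = -1;
  }
};

struct MuTable {
  const double *mu_pe, *mu_inc;  // [nE x nMat], column-major
  int nE, nMat;
  double e0;                     // first grid energy (keV), step 1 keV
  std::vector<double> mu_maj;    // majorant total mu per grid point

  void build_majorant() {
    mu_maj.assign(nE, 0.0);
    for (int j = 0; j < nMat; ++j)
      for (int i = 0; i < nE; ++i) {
        double t = mu_pe[i + j * nE] + mu_inc[i + j * nE];
        if (t > mu_maj[i]) mu_maj[i] = t;
      }
  }
  inline void at(double E, int mat, double& pe, double& inc) const {
    double f = E - e0;
    if (f < 0) f = 0;
    int i = static_cast<int>(f);
    if (i >= nE - 1) { i = nE - 2; }
    double w = f - i; if (w > 1) w = 1;
    const double *cpe = mu_pe + mat * nE, *cin = mu_inc + mat * nE;
    pe = cpe[i] * (1 - w) + cpe[i + 1] * w;
    inc = cin[i] * (1 - w) + cin[i + 1] * w;
  }
  inline double majorant(double E) const {
    double f = E - e0;
    if (f < 0) f = 0;
    int i = static_cast<int>(f);
    if (i >= nE - 1) i = nE - 2;
    double w = f - i; if (w > 1) w = 1;
    return mu_maj[i] * (1 - w) + mu_maj[i + 1] * w;
  }
};

// advance the ray to the bounding box (axis-aligned), return false if it
// misses; t is the entry distance (0 if already inside)
static bool enter_box(double px, double py, double pz,
                      double dx, double dy, double dz,
                      double xmax, double ymax, double z0, double z1,
                      double& t) {
  double tmin = 0.0, tmax = 1e30;
  const double lo[3] = {-xmax, -ymax, z0}, hi[3] = {xmax, ymax, z1};
  const double p[3] = {px, py, pz}, d[3] = {dx, dy, dz};
  for (int k = 0; k < 3; ++k) {
    if (std::fabs(d[k]) < 1e-12) {
      if (p[k] < lo[k] || p[k] > hi[k]) return false;
    } else {
      double t1 = (lo[k] - p[k]) / d[k], t2 = (hi[k] - p[k]) / d[k];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) tmin = t1;
      if (t2 < tmax) tmax = t2;
    }
  }
  if (tmin > tmax) return false;
  t = tmin > 0 ? tmin + 1e-9 : 0.0;
  return true;
}

// rotate direction (ux,uy,uz) by polar angle theta (cos ct) and uniform
// azimuth about itself
static void rotate_direction(double& ux, double& uy, double& uz,
                             double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cphi = std::cos(phi), sphi = std::sin(phi);
  double wx, wy, wz;
  if (std::fabs(uz) < 0.99999) {
    // w = u x zhat etc. build orthonormal frame
    double norm = std::sqrt(ux * ux + uy * uy);
    double vx = -uy / norm, vy = ux / norm, vz = 0.0;
    wx = uy * vz - uz * vy; wy = uz * vx - ux * vz; wz = ux * vy - uy * vx;
    double nx = ux * ct + st * (cphi * vx + sphi * wx);
    double ny = uy * ct + st * (cphi * vy + sphi * wy);
    double nz = uz * ct + st * (cphi * vz + sphi * wz);
    ux = nx; uy = ny; uz = nz;
  } else {
    double sgn = uz > 0 ? 1.0 : -1.0;
    ux = st * cphi; uy = st * sphi; uz = sgn * ct;
  }
  double n = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= n; uy /= n; uz /= n;
}

// [[Rcpp::export]]
List cpp_simulate_rotation(
    NumericVector slab_z, NumericVector slab_a, NumericVector slab_b,
    IntegerVector slab_mat, IntegerVector slab_tally,
    IntegerVector reg_slab, NumericVector reg_cx, NumericVector reg_cy,
    NumericVector reg_a, NumericVector reg_b,
    IntegerVector reg_mat, IntegerVector reg_tally,
    NumericMatrix mu_pe, NumericMatrix mu_inc, double e_first,
    int air_mat, int n_tally,
    NumericVector spectrum_e, NumericVector spectrum_w,
    double fan_deg, double coll_mm, double src_radius,
    double z_center, bool rotate_source, double fixed_angle,
    bool scatter_on, double cutoff_kev,
    int n_photons, int seed) {

  int n_slab = slab_a.size();
  // per-slab region index (regions must be sorted by slab, priority)
  std::vector<int> rstart(n_slab, 0), rcount(n_slab, 0);
  for (int r = 0; r < reg_slab.size(); ++r) rcount[reg_slab[r]]++;
  for (int s = 1; s < n_slab; ++s) rstart[s] = rstart[s - 1] + rcount[s - 1];

  Geometry g;
  g.n_slab = n_slab;
  g.slab_z = REAL(slab_z); g.slab_a = REAL(slab_a); g.slab_b = REAL(slab_b);
  g.slab_mat = INTEGER(slab_mat); g.slab_tally = INTEGER(slab_tally);
  g.reg_start = rstart.data(); g.reg_count = rcount.data();
  g.reg_cx = REAL(reg_cx); g.reg_cy = REAL(reg_cy);
  g.reg_a = REAL(reg_a); g.reg_b = REAL(reg_b);
  g.reg_mat = INTEGER(reg_mat); g.reg_tally = INTEGER(reg_tally);
  g.air_mat = air_mat;
  g.xmax = 0; g.ymax = 0;
  for (int s = 0; s < n_slab; ++s) {
    if (slab_a[s] > g.xmax) g.xmax = slab_a[s];
    if (slab_b[s] > g.ymax) g.ymax = slab_b[s];
  }

  MuTable mu;
  mu.mu_pe = REAL(mu_pe); mu.mu_inc = REAL(mu_inc);
  mu.nE = mu_pe.nrow(); mu.nMat = mu_pe.ncol(); mu.e0 = e_first;
  mu.build_majorant();

  Rng rng(static_cast<uint64_t>(seed));

  // cumulative spectrum weights
  int nsp = spectrum_e.size();
  std::vector<double> cumw(nsp);
  double wsum = 0;
  for (int i = 0; i < nsp; ++i) { wsum += spectrum_w[i]; cumw[i] = wsum; }

  std::vector<double> tally_e(n_tally, 0.0), tally_e2(n_tally, 0.0);
  std::vector<double> photon_dep(n_tally, 0.0);
  std::vector<int> touched; touched.reserve(16);

  double emitted = 0.0, deposited = 0.0, escaped = 0.0, cutoff_bank = 0.0;
  double fan_rad = fan_deg * M_PI / 180.0;
  long n_intact = 0;  // photons escaping without any interaction

  double z0 = slab_z[0], z1 = slab_z[n_slab];

  for (int ip = 0; ip < n_photons; ++ip) {
    // source energy
    double E;
    if (nsp == 1) E = spectrum_e[0];
    else {
      double u = rng.u() * wsum;
      int k = 0; while (k < nsp - 1 && cumw[k] < u) ++k;
      E = spectrum_e[k];
    }
    emitted += E;

    // source position and direction
    double phi_s = rotate_source ? 2.0 * M_PI * rng.u() : fixed_angle;
    double sx = src_radius * std::cos(phi_s), sy = src_radius * std::sin(phi_s);
    double sz = z_center;
    // target point at isocenter plane: fan spread in-plane, collimation in z
    double alpha = fan_rad > 0 ? (rng.u() - 0.5) * fan_rad : 0.0;
    double zeta = coll_mm > 0 ? (rng.u() - 0.5) * coll_mm : 0.0;
    double perp = src_radius * std::tan(alpha);
    double tx = -std::sin(phi_s) * perp, ty = std::cos(phi_s) * perp;
    double dx = tx - sx, dy = ty - sy, dz = (z_center + zeta) - sz;
    double dn = std::sqrt(dx * dx + dy * dy + dz * dz);
    dx /= dn; dy /= dn; dz /= dn;

    double t;
    if (!enter_box(sx, sy, sz, dx, dy, dz, g.xmax, g.ymax, z0, z1, t)) {
      escaped += E; ++n_intact; continue;
    }
    double px = sx + dx * t, py = sy + dy * t, pz = sz + dz * t;

    bool interacted = false;
    bool alive = true;
    for (int it = 0; alive && it < 100000; ++it) {
      double mmaj = mu.majorant(E);
      double s = -std::log(rng.u() + 1e-300) / mmaj;
      px += dx * s; py += dy * s; pz += dz * s;
      int mat, tal;
      g.locate(px, py, pz, mat, tal);
      if (mat < 0) { escaped += E; if (!interacted) ++n_intact; break; }
      double mpe, minc;
      mu.at(E, mat, mpe, minc);
      double mtot = mpe + minc;
      if (rng.u() * mmaj > mtot) continue;  // virtual collision
      // real interaction
      interacted = true;
      if (!scatter_on) {
        // attenuation-only mode: every interaction terminates the photon
        deposited += E;
        if (tal >= 0) { photon_dep[tal] += E; touched.push_back(tal); }
        break;
      }
      if (rng.u() * mtot < mpe) {
        deposited += E;
        if (tal >= 0) { photon_dep[tal] += E; touched.push_back(tal); }
        break;
      }
      // Compton scatter
      double a = E / ELECTRON_REST_KEV;
      double eps = sample_kn_eps(a, rng);
      double Enew = E * eps;
      double edep = E - Enew;
      deposited += edep;
      if (tal >= 0) { photon_dep[tal] += edep; touched.push_back(tal); }
      double ct = 1.0 - (1.0 - eps) / (a * eps);
      if (ct > 1.0) ct = 1.0; if (ct < -1.0) ct = -1.0;
      rotate_direction(dx, dy, dz, ct, 2.0 * M_PI * rng.u());
      E = Enew;
      if (E < cutoff_kev) {
        // residual deposited locally
        deposited += E; cutoff_bank += E;
        if (tal >= 0) photon_dep[tal] += E;
        break;
      }
    }
    // accumulate per-photon tallies (squared sums for MC standard errors)
    if (!touched.empty()) {
      std::sort(touched.begin(), touched.end());
      touched.erase(std::unique(touched.begin(), touched.end()), touched.end());
      for (int tal : touched) {
        tally_e[tal] += photon_dep[tal];
        tally_e2[tal] += photon_dep[tal] * photon_dep[tal];
        photon_dep[tal] = 0.0;
      }
      touched.clear();
    }
  }

  return List::create(
    _["tally_energy"] = NumericVector(tally_e.begin(), tally_e.end()),
    _["tally_energy_sq"] = NumericVector(tally_e2.begin(), tally_e2.end()),
    _["emitted"] = emitted, _["deposited"] = deposited,
    _["escaped"] = escaped, _["cutoff_bank"] = cutoff_bank,
    _["n_intact"] = static_cast<double>(n_intact),
    _["n_photons"] = n_photons, _["seed"] = seed);
}
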