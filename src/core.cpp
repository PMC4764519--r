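// Compiled core: pairwise/bonded energetics and the BAOAB Langevin propagator.
// Units: nm, ps, Da, kJ/mol, K.  kB = 0.0083145 kJ/mol/K.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <unordered_set>
using namespace Rcpp;

static const double KB = 0.0083145;          // kJ mol^-1 K^-1
static const double COULOMB = 138.935458;    // kJ mol^-1 nm e^-2 (1/4 pi eps0)

// ---------------------------------------------------------------------------
// deterministic RNG (xoshiro256++, splitmix64 seeding) with Box-Muller cache
// ---------------------------------------------------------------------------
struct Rng {
  uint64_t s[4];
  bool has_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // unit normal via the 12-uniform sum (Irwin-Hall): exact mean/variance,
  // Gaussian to ~1e-3 in the bulk, tails truncated at +/-6 sigma -- standard
  // practice for Langevin thermostat noise, and ~10x faster than Box-Muller
  inline double norm() {
    double s = 0;
    for (int k = 0; k < 12; ++k) s += unif();
    return s - 6.0;
  }
};

// ---------------------------------------------------------------------------
// C1 cubic-Hermite table on a uniform grid (finite-difference slopes)
// ---------------------------------------------------------------------------
struct Table {
  double x0 = 0, dx = 1;
  int n = 0;
  bool periodic = false;
  std::vector<double> y, m;
  void init(const NumericVector& xs, const NumericVector& ys, bool per) {
    n = xs.size(); x0 = xs[0]; dx = xs[1] - xs[0]; periodic = per;
    y.assign(ys.begin(), ys.end());
    m.resize(n);
    for (int i = 0; i < n; ++i) {
      double yp, ym;
      if (periodic) {
        yp = y[(i + 1) % n]; ym = y[(i - 1 + n) % n];
        m[i] = (yp - ym) / (2 * dx);
      } else if (i == 0) m[i] = (y[1] - y[0]) / dx;
      else if (i == n - 1) m[i] = (y[n - 1] - y[n - 2]) / dx;
      else m[i] = (y[i + 1] - y[i - 1]) / (2 * dx);
    }
  }
  // value and derivative; clamps outside domain (non-periodic)
  inline void eval(double x, double& val, double& der) const {
    double span = dx * (periodic ? n : (n - 1));
    if (periodic) {
      x = x - span * std::floor((x - x0) / span);  // wrap into [x0, x0+span)
      if (x >= x0 + span) x -= span;
      if (x < x0) x += span;
    } else {
      if (x <= x0) { val = y[0]; der = 0; return; }
      if (x >= x0 + span) { val = y[n - 1]; der = 0; return; }
    }
    double u = (x - x0) / dx;
    int i = (int)std::floor(u);
    if (i < 0) i = 0;
    int i1 = periodic ? (i + 1) % n : std::min(i + 1, n - 1);
    double t = u - i;
    double h00 = (1 + 2 * t) * (1 - t) * (1 - t), h10 = t * (1 - t) * (1 - t);
    double h01 = t * t * (3 - 2 * t), h11 = t * t * (t - 1);
    val = h00 * y[i] + h10 * dx * m[i] + h01 * y[i1] + h11 * dx * m[i1];
    double d00 = 6 * t * (t - 1), d10 = (1 - t) * (1 - 3 * t);
    double d01 = -d00, d11 = t * (3 * t - 2);
    der = (d00 * y[i] + d01 * y[i1]) / dx + d10 * m[i] + d11 * m[i1];
  }
};

// ---------------------------------------------------------------------------
// topology / force-field containers unpacked from R lists
// ---------------------------------------------------------------------------
struct Topo {
  int n = 0;
  std::vector<double> x, yy, z;   // positions
  std::vector<int> kind;          // 0 FG residue, 1 binding spot, 2 scaffold, 3 cargo EV bead
  std::vector<double> hyd, q, evr, mass;
  std::vector<int> mobile;        // 0 fixed, 1 flexible, 2 rigid-cargo member
  IntegerMatrix bonds;            // B x 2 (1-based from R)
  NumericVector bond_k, bond_r0;
  IntegerMatrix angles;           // A x 3
  IntegerMatrix dihedrals;        // D x 4
  std::unordered_set<int64_t> excl;
  // cargo rigid body
  bool has_cargo = false;
  std::vector<int> cmember;
  std::vector<double> cref;       // 3*m reference coords (body frame)
  double cmass = 0, cinertia = 0;
  bool free_rotate = true;
};

struct FF {
  double eps_max = 5.2, vdw_cut = 2.5, coul_cut = 5.0;
  double debye = 0.8, dielectric = 80.0, wca_eps = 5.0;
  Table bend, tors;
  bool has_bend = false, has_tors = false;
  int terms = 0xFF;               // bit mask: 1 bond, 2 angle, 4 torsion, 8 nonbonded
};

static Topo unpackTopo(const List& tl) {
  Topo t;
  NumericMatrix pos = tl["pos"];
  t.n = pos.nrow();
  t.x.resize(t.n); t.yy.resize(t.n); t.z.resize(t.n);
  for (int i = 0; i < t.n; ++i) { t.x[i] = pos(i, 0); t.yy[i] = pos(i, 1); t.z[i] = pos(i, 2); }
  IntegerVector kind = tl["kind"], mobile = tl["mobile"];
  NumericVector hyd = tl["hyd"], q = tl["charge"], evr = tl["evr"], mass = tl["mass"];
  t.kind.assign(kind.begin(), kind.end());
  t.mobile.assign(mobile.begin(), mobile.end());
  t.hyd.assign(hyd.begin(), hyd.end());
  t.q.assign(q.begin(), q.end());
  t.evr.assign(evr.begin(), evr.end());
  t.mass.assign(mass.begin(), mass.end());
  t.bonds = as<IntegerMatrix>(tl["bonds"]);
  t.bond_k = as<NumericVector>(tl["bond_k"]);
  t.bond_r0 = as<NumericVector>(tl["bond_r0"]);
  t.angles = as<IntegerMatrix>(tl["angles"]);
  t.dihedrals = as<IntegerMatrix>(tl["dihedrals"]);
  IntegerMatrix ex = tl["exclusions"];
  for (int r = 0; r < ex.nrow(); ++r) {
    int i = ex(r, 0) - 1, j = ex(r, 1) - 1;
    if (i > j) std::swap(i, j);
    t.excl.insert((int64_t)i * t.n + j);
  }
  if (tl.containsElementNamed("cargo") && !Rf_isNull(tl["cargo"])) {
    List cg = tl["cargo"];
    t.has_cargo = true;
    IntegerVector mem = cg["members"];
    for (int k = 0; k < mem.size(); ++k) t.cmember.push_back(mem[k] - 1);
    NumericMatrix ref = cg["ref"];
    t.cref.resize(3 * ref.nrow());
    for (int r = 0; r < ref.nrow(); ++r)
      for (int c = 0; c < 3; ++c) t.cref[3 * r + c] = ref(r, c);
    t.cmass = as<double>(cg["mass"]);
    t.cinertia = as<double>(cg["inertia"]);
    t.free_rotate = as<bool>(cg["free_rotate"]);
  }
  return t;
}

static FF unpackFF(const List& fl) {
  FF f;
  f.eps_max = as<double>(fl["eps_max"]);
  f.vdw_cut = as<double>(fl["vdw_cutoff"]);
  f.coul_cut = as<double>(fl["coulomb_cutoff"]);
  f.debye = as<double>(fl["debye_length"]);
  f.dielectric = as<double>(fl["dielectric"]);
  f.wca_eps = as<double>(fl["wca_eps"]);
  if (fl.containsElementNamed("terms")) f.terms = as<int>(fl["terms"]);
  if (fl.containsElementNamed("bend_table") && !Rf_isNull(fl["bend_table"])) {
    List bt = fl["bend_table"];
    f.bend.init(bt["x"], bt["y"], false);
    f.has_bend = true;
  }
  if (fl.containsElementNamed("torsion_table") && !Rf_isNull(fl["torsion_table"])) {
    List tt = fl["torsion_table"];
    f.tors.init(tt["x"], tt["y"], true);
    f.has_tors = true;
  }
  return f;
}

// ---------------------------------------------------------------------------
// pair potentials (energy-shifted to zero at their cutoff)
// ---------------------------------------------------------------------------
// split LJ: repulsive core of strength eps_rep, attractive well of depth eps,
// energy-shifted to zero at rc; linearized below 0.8 sigma for robustness
static inline double pow6(double x) { double x2 = x * x; return x2 * x2 * x2; }
static const double RMIN_FAC = 1.1224620483089301;   // 2^(1/6)


static inline double dh_shifted(double r, double qq, double C, double lam, double rc, double& dUdr) {
  if (r >= rc || qq == 0) { dUdr = 0; return 0; }
  double u = C * qq * std::exp(-r / lam) / r;
  double us = C * qq * std::exp(-rc / lam) / rc;
  dUdr = -u * (1.0 / r + 1.0 / lam);
  return u - us;
}


// pair cutoff for neighbor listing (0 = non-interacting pair)
static inline double pairCutoff(const Topo& t, const FF& f, int i, int j) {
  int a = t.kind[i], b = t.kind[j];
  if (a <= 1 && b <= 1) {
    double c = f.vdw_cut;
    if (t.q[i] != 0 && t.q[j] != 0) c = std::max(c, f.coul_cut);
    return c;
  }
  if (a == 2 && b == 2) return 0;              // scaffold-scaffold: rigid, skip
  return t.evr[i] + t.evr[j];                  // excluded volume contact
}

// ---------------------------------------------------------------------------
// Verlet neighbor list (O(N^2) rebuild, per-pair cutoffs + skin).
// Pair parameters are resolved at build time so the force loop needs no
// lookups: every listed pair evaluates the split-LJ form with depth eps
// (zero => pure repulsion), core strength eps_rep and contact scale sigma,
// plus optional Debye-Hueckel when qq != 0.
// ---------------------------------------------------------------------------
// pair list kept as struct-of-arrays with single-precision parameters:
// the force loop is memory-bound and the parameters never need full precision
// at the list level (energies are accumulated in double)
struct NList {
  std::vector<int> pi, pj;
  std::vector<signed char> comp;  // energy component: 3 hydrophobic, 5 excl vol
  std::vector<float> cut2, sigma2, eps, eps_rep, shift, qq;
  size_t npairs = 0;
  std::vector<double> x0, y0, z0;
  double skin = 1.0;
  double coul_cut2 = 25.0;
  long n_rebuilds = 0;
  void build(const Topo& t, const FF& f) {
    pi.clear(); pj.clear(); comp.clear(); cut2.clear(); sigma2.clear();
    eps.clear(); eps_rep.clear(); shift.clear(); qq.clear();
    ++n_rebuilds;
    coul_cut2 = f.coul_cut * f.coul_cut;
    // coarse global bound for a distance-first quick reject
    double maxevr = 0;
    for (int i = 0; i < t.n; ++i) maxevr = std::max(maxevr, t.evr[i]);
    double maxrl = std::max(f.coul_cut, std::max(f.vdw_cut, 2 * maxevr)) + skin;
    double maxrl2 = maxrl * maxrl;
    for (int i = 0; i < t.n; ++i) {
      double xi = t.x[i], yi = t.yy[i], zi = t.z[i];
      for (int j = i + 1; j < t.n; ++j) {
        double dx = xi - t.x[j], dy = yi - t.yy[j], dz = zi - t.z[j];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= maxrl2) continue;
        if (t.mobile[i] == 0 && t.mobile[j] == 0) continue;
        if (t.mobile[i] == 2 && t.mobile[j] == 2) continue;  // same rigid body
        double c = pairCutoff(t, f, i, j);
        if (c <= 0) continue;
        double rl = c + skin;
        if (r2 >= rl * rl) continue;
        if (t.excl.count((int64_t)i * t.n + j)) continue;
        pi.push_back(i); pj.push_back(j);
        if (t.kind[i] <= 1 && t.kind[j] <= 1) {
          double sigma = t.evr[i] + t.evr[j];
          double e = f.eps_max * t.hyd[i] * t.hyd[j];
          double sc6 = pow6(sigma / f.vdw_cut);
          comp.push_back(3);
          sigma2.push_back((float)(sigma * sigma));
          eps.push_back((float)e);
          eps_rep.push_back((float)f.eps_max);
          shift.push_back((float)(4 * e * (sc6 * sc6 - sc6)));
          cut2.push_back((float)(f.vdw_cut * f.vdw_cut));
          qq.push_back((t.q[i] != 0 && t.q[j] != 0) ? (float)(t.q[i] * t.q[j]) : 0.0f);
        } else {
          double contact = t.evr[i] + t.evr[j];
          double sigma = contact / RMIN_FAC;
          comp.push_back(5);
          sigma2.push_back((float)(sigma * sigma));
          eps.push_back(0.0f);
          eps_rep.push_back((float)f.wca_eps);
          shift.push_back(0.0f);
          cut2.push_back((float)(contact * contact));
          qq.push_back(0.0f);
        }
      }
    }
    npairs = pi.size();
    x0 = t.x; y0 = t.yy; z0 = t.z;
  }
  bool stale(const Topo& t) const {
    double thr2 = 0.25 * skin * skin;
    for (int i = 0; i < t.n; ++i) {
      if (t.mobile[i] == 0) continue;
      double dx = t.x[i] - x0[i], dy = t.yy[i] - y0[i], dz = t.z[i] - z0[i];
      if (dx * dx + dy * dy + dz * dz > thr2) return true;
    }
    return false;
  }
};

// ---------------------------------------------------------------------------
// forces & energy
// ecomp: 0 bond, 1 bend, 2 torsion, 3 hydrophobic, 4 electrostatic, 5 excl.vol
// ---------------------------------------------------------------------------
static void computeForces(const Topo& t, const FF& f, const NList& nl,
                          std::vector<double>& fx, std::vector<double>& fy,
                          std::vector<double>& fz, double* ecomp) {
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  for (int k = 0; k < 6; ++k) ecomp[k] = 0;

  if (f.terms & 1) {
    for (int b = 0; b < t.bonds.nrow(); ++b) {
      int i = t.bonds(b, 0) - 1, j = t.bonds(b, 1) - 1;
      double dx = t.x[i] - t.x[j], dy = t.yy[i] - t.yy[j], dz = t.z[i] - t.z[j];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double k0 = t.bond_k[b], r0 = t.bond_r0[b];
      ecomp[0] += 0.5 * k0 * (r - r0) * (r - r0);
      double g = -k0 * (r - r0) / std::max(r, 1e-12);
      fx[i] += g * dx; fy[i] += g * dy; fz[i] += g * dz;
      fx[j] -= g * dx; fy[j] -= g * dy; fz[j] -= g * dz;
    }
  }

  if ((f.terms & 2) && f.has_bend) {
    for (int a = 0; a < t.angles.nrow(); ++a) {
      int i = t.angles(a, 0) - 1, j = t.angles(a, 1) - 1, k = t.angles(a, 2) - 1;
      double ux = t.x[i] - t.x[j], uy = t.yy[i] - t.yy[j], uz = t.z[i] - t.z[j];
      double vx = t.x[k] - t.x[j], vy = t.yy[k] - t.yy[j], vz = t.z[k] - t.z[j];
      double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
      double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
      double ct = (ux * vx + uy * vy + uz * vz) / (nu * nv);
      ct = std::max(-1.0, std::min(1.0, ct));
      double th = std::acos(ct);
      double e, dEdth;
      f.bend.eval(th, e, dEdth);
      ecomp[1] += e;
      double st = std::sqrt(std::max(1.0 - ct * ct, 1e-12));
      double pref = dEdth / st;
      // grad_i cos = (v_hat - cos*u_hat)/|u| ; F_i = pref * grad_i cos
      double gix = pref * (vx / nv - ct * ux / nu) / nu;
      double giy = pref * (vy / nv - ct * uy / nu) / nu;
      double giz = pref * (vz / nv - ct * uz / nu) / nu;
      double gkx = pref * (ux / nu - ct * vx / nv) / nv;
      double gky = pref * (uy / nu - ct * vy / nv) / nv;
      double gkz = pref * (uz / nu - ct * vz / nv) / nv;
      fx[i] += gix; fy[i] += giy; fz[i] += giz;
      fx[k] += gkx; fy[k] += gky; fz[k] += gkz;
      fx[j] -= gix + gkx; fy[j] -= giy + gky; fz[j] -= giz + gkz;
    }
  }

  if ((f.terms & 4) && f.has_tors) {
    for (int d = 0; d < t.dihedrals.nrow(); ++d) {
      int i1 = t.dihedrals(d, 0) - 1, i2 = t.dihedrals(d, 1) - 1;
      int i3 = t.dihedrals(d, 2) - 1, i4 = t.dihedrals(d, 3) - 1;
      double b1x = t.x[i2] - t.x[i1], b1y = t.yy[i2] - t.yy[i1], b1z = t.z[i2] - t.z[i1];
      double b2x = t.x[i3] - t.x[i2], b2y = t.yy[i3] - t.yy[i2], b2z = t.z[i3] - t.z[i2];
      double b3x = t.x[i4] - t.x[i3], b3y = t.yy[i4] - t.yy[i3], b3z = t.z[i4] - t.z[i3];
      double n1x = b1y * b2z - b1z * b2y, n1y = b1z * b2x - b1x * b2z, n1z = b1x * b2y - b1y * b2x;
      double n2x = b2y * b3z - b2z * b3y, n2y = b2z * b3x - b2x * b3z, n2z = b2x * b3y - b2y * b3x;
      double nb2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
      double n1s = n1x * n1x + n1y * n1y + n1z * n1z;
      double n2s = n2x * n2x + n2y * n2y + n2z * n2z;
      if (n1s < 1e-12 || n2s < 1e-12 || nb2 < 1e-12) continue;
      double cx = n1y * n2z - n1z * n2y, cy = n1z * n2x - n1x * n2z, cz = n1x * n2y - n1y * n2x;
      double sphi = (cx * b2x + cy * b2y + cz * b2z) / nb2;
      double cphi = n1x * n2x + n1y * n2y + n1z * n2z;
      double phi = std::atan2(sphi, cphi);
      double e, dEdphi;
      f.tors.eval(phi, e, dEdphi);
      ecomp[2] += e;
      // Blondel-Karplus dihedral gradients
      double g1x = -nb2 / n1s * n1x, g1y = -nb2 / n1s * n1y, g1z = -nb2 / n1s * n1z;
      double g4x = nb2 / n2s * n2x, g4y = nb2 / n2s * n2y, g4z = nb2 / n2s * n2z;
      double s12 = (b1x * b2x + b1y * b2y + b1z * b2z) / (nb2 * nb2);
      double s32 = (b3x * b2x + b3y * b2y + b3z * b2z) / (nb2 * nb2);
      double t = -dEdphi;
      double F1x = t * g1x, F1y = t * g1y, F1z = t * g1z;
      double F4x = t * g4x, F4y = t * g4y, F4z = t * g4z;
      double F2x = t * (-(1 + s12) * g1x + s32 * g4x);
      double F2y = t * (-(1 + s12) * g1y + s32 * g4y);
      double F2z = t * (-(1 + s12) * g1z + s32 * g4z);
      double F3x = t * (s12 * g1x - (1 + s32) * g4x);
      double F3y = t * (s12 * g1y - (1 + s32) * g4y);
      double F3z = t * (s12 * g1z - (1 + s32) * g4z);
      fx[i1] += F1x; fy[i1] += F1y; fz[i1] += F1z;
      fx[i2] += F2x; fy[i2] += F2y; fz[i2] += F2z;
      fx[i3] += F3x; fy[i3] += F3y; fz[i3] += F3z;
      fx[i4] += F4x; fy[i4] += F4y; fz[i4] += F4z;
    }
  }

  if (f.terms & 8) {
    double C = COULOMB / f.dielectric;
    // branch thresholds in sr2 = (sigma/r)^2: r >= rmin <=> sr2 <= 2^(-1/3);
    // r >= 0.8 sigma <=> sr2 <= 1/0.64
    const double SR2_MIN = std::pow(2.0, -1.0 / 3.0);
    const double SR2_LIN = 1.0 / 0.64;
    for (size_t p = 0; p < nl.npairs; ++p) {
      int i = nl.pi[p], j = nl.pj[p];
      double dx = t.x[i] - t.x[j], dy = t.yy[i] - t.yy[j], dz = t.z[i] - t.z[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      double g = 0;                             // -(dU/dr)/r
      if (r2 < (double)nl.cut2[p]) {
        double peps = nl.eps[p], prep = nl.eps_rep[p], pshift = nl.shift[p];
        double inv_r2 = 1.0 / r2;
        double sr2 = (double)nl.sigma2[p] * inv_r2;
        double sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
        if (sr2 <= SR2_MIN) {
          if (peps != 0) {
            ecomp[nl.comp[p]] += 4 * peps * (sr12 - sr6) - pshift;
            g = -4 * peps * (-12 * sr12 + 6 * sr6) * inv_r2;
          }
        } else if (sr2 <= SR2_LIN) {
          ecomp[nl.comp[p]] += 4 * prep * (sr12 - sr6) + prep - peps - pshift;
          g = -4 * prep * (-12 * sr12 + 6 * sr6) * inv_r2;
        } else {                                // linearized core
          double sigma = std::sqrt((double)nl.sigma2[p]);
          double r = std::sqrt(r2);
          double rl = 0.8 * sigma;
          double s6 = pow6(sigma / rl), s12 = s6 * s6;
          double d0 = 4 * prep * (-12 * s12 + 6 * s6) / rl;
          double u0 = 4 * prep * (s12 - s6) + prep - peps - pshift;
          ecomp[nl.comp[p]] += u0 + d0 * (r - rl);
          g = -d0 / r;
        }
      }
      if (nl.qq[p] != 0 && r2 < nl.coul_cut2) {
        double r = std::sqrt(r2);
        double du;
        ecomp[4] += dh_shifted(r, (double)nl.qq[p], C, f.debye, f.coul_cut, du);
        g += -du / r;
      }
      if (g != 0) {
        fx[i] += g * dx; fy[i] += g * dy; fz[i] += g * dz;
        fx[j] -= g * dx; fy[j] -= g * dy; fz[j] -= g * dz;
      }
    }
  }
}

// ---------------------------------------------------------------------------
// exported: energy + forces of a configuration
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cpp_energy")]]
List cpp_energy(List topo, List ff) {
  Topo t = unpackTopo(topo);
  FF f = unpackFF(ff);
  NList nl;
  nl.skin = 0.0;
  nl.build(t, f);
  std::vector<double> fx(t.n), fy(t.n), fz(t.n);
  double ec[6];
  computeForces(t, f, nl, fx, fy, fz, ec);
  NumericMatrix F(t.n, 3);
  for (int i = 0; i < t.n; ++i) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i]; }
  double tot = 0;
  for (int k = 0; k < 6; ++k) tot += ec[k];
  return List::create(
    _["total"] = tot,
    _["components"] = NumericVector::create(
      _["bond"] = ec[0], _["bend"] = ec[1], _["torsion"] = ec[2],
      _["hydrophobic"] = ec[3], _["electrostatic"] = ec[4], _["excluded_volume"] = ec[5]),
    _["forces"] = F);
}

// ---------------------------------------------------------------------------
// restraints & external potentials acting on the tracked object's center
// type 1: bias_z   (k, ref)           0.5 k (z-ref)^2
// type 2: lateral  (k)                0.5 k (x^2+y^2)
// type 3: radial   (k, r0, theta, kt) 0.5 k (r_par-r0)^2 + 0.5 kt r_perp^2
//          r_par = projection on ray (cos th, sin th), r_perp = in-plane residual
// type 4: bias_zplane (k, zref)       same as 1 (used with radial runs)
// type 5: harm3d  (k, cx, cy, cz)     isotropic trap
// external type 1: doublewell (h)     h (z^2-1)^2 on z
// ---------------------------------------------------------------------------
struct Restraint { int type; double p1, p2, p3, p4; };

static double restraintForce(const std::vector<Restraint>& rs, int ext_type, double ext_p,
                             double cx, double cy, double cz,
                             double& Fx, double& Fy, double& Fz) {
  double e = 0;
  Fx = Fy = Fz = 0;
  for (const Restraint& r : rs) {
    switch (r.type) {
    case 1: case 4: {
      double d = cz - r.p2;
      e += 0.5 * r.p1 * d * d;
      Fz += -r.p1 * d;
    } break;
    case 2: {
      e += 0.5 * r.p1 * (cx * cx + cy * cy);
      Fx += -r.p1 * cx; Fy += -r.p1 * cy;
    } break;
    case 3: {
      double ux = std::cos(r.p3), uy = std::sin(r.p3);
      double rpar = cx * ux + cy * uy;
      double px = cx - rpar * ux, py = cy - rpar * uy;
      double d = rpar - r.p2;
      e += 0.5 * r.p1 * d * d + 0.5 * r.p4 * (px * px + py * py);
      Fx += -r.p1 * d * ux - r.p4 * px;
      Fy += -r.p1 * d * uy - r.p4 * py;
    } break;
    case 5: {
      double dx = cx - r.p2, dy = cy - r.p3, dz = cz - r.p4;
      e += 0.5 * r.p1 * (dx * dx + dy * dy + dz * dz);
      Fx += -r.p1 * dx; Fy += -r.p1 * dy; Fz += -r.p1 * dz;
    } break;
    }
  }
  if (ext_type == 1) {
    double z2 = cz * cz;
    e += ext_p * (z2 - 1) * (z2 - 1);
    Fz += -ext_p * 4 * cz * (z2 - 1);
  }
  return e;
}

static inline void quatRotate(const double q[4], const double v[3], double out[3]) {
  // rotate v by unit quaternion q = (w,x,y,z)
  double w = q[0], x = q[1], y = q[2], z = q[3];
  double t2 = w * x, t3 = w * y, t4 = w * z, t5 = -x * x, t6 = x * y;
  double t7 = x * z, t8 = -y * y, t9 = y * z, t10 = -z * z;
  out[0] = 2 * ((t8 + t10) * v[0] + (t6 - t4) * v[1] + (t3 + t7) * v[2]) + v[0];
  out[1] = 2 * ((t4 + t6) * v[0] + (t5 + t10) * v[1] + (t9 - t2) * v[2]) + v[1];
  out[2] = 2 * ((t7 - t3) * v[0] + (t2 + t9) * v[1] + (t5 + t8) * v[2]) + v[2];
}

static inline void quatAdvance(double q[4], const double w[3], double dt) {
  double wn = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  if (wn < 1e-14) return;
  double half = 0.5 * wn * dt;
  double s = std::sin(half) / wn, c = std::cos(half);
  double dq[4] = {c, s * w[0], s * w[1], s * w[2]};
  double r[4] = {
    dq[0] * q[0] - dq[1] * q[1] - dq[2] * q[2] - dq[3] * q[3],
    dq[0] * q[1] + dq[1] * q[0] + dq[2] * q[3] - dq[3] * q[2],
    dq[0] * q[2] - dq[1] * q[3] + dq[2] * q[0] + dq[3] * q[1],
    dq[0] * q[3] + dq[1] * q[2] - dq[2] * q[1] + dq[3] * q[0]};
  double n = std::sqrt(r[0] * r[0] + r[1] * r[1] + r[2] * r[2] + r[3] * r[3]);
  for (int i = 0; i < 4; ++i) q[i] = r[i] / n;
}

static void placeCargo(Topo& t, const double c[3], const double q[4]) {
  for (size_t m = 0; m < t.cmember.size(); ++m) {
    double v[3] = {t.cref[3 * m], t.cref[3 * m + 1], t.cref[3 * m + 2]}, o[3];
    quatRotate(q, v, o);
    int i = t.cmember[m];
    t.x[i] = c[0] + o[0]; t.yy[i] = c[1] + o[1]; t.z[i] = c[2] + o[2];
  }
}

// ---------------------------------------------------------------------------
// exported: BAOAB Langevin propagation
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cpp_run")]]
List cpp_run(List topo, List ff, List ld, List restraints, List external,
             int n_steps, int sample_every, int traj_every, int track_bead) {
  Topo t = unpackTopo(topo);
  FF f = unpackFF(ff);
  double T = as<double>(ld["temperature"]);
  double dt = as<double>(ld["timestep"]);
  double gamma = as<double>(ld["friction"]);
  uint64_t seed = (uint64_t)as<double>(ld["seed"]);
  Rng rng(seed);
  double kT = KB * T;

  std::vector<Restraint> rs;
  for (int i = 0; i < restraints.size(); ++i) {
    List r = restraints[i];
    Restraint rr;
    rr.type = as<int>(r["type"]);
    rr.p1 = r.containsElementNamed("p1") ? as<double>(r["p1"]) : 0;
    rr.p2 = r.containsElementNamed("p2") ? as<double>(r["p2"]) : 0;
    rr.p3 = r.containsElementNamed("p3") ? as<double>(r["p3"]) : 0;
    rr.p4 = r.containsElementNamed("p4") ? as<double>(r["p4"]) : 0;
    rs.push_back(rr);
  }
  int ext_type = 0; double ext_p = 0;
  if (external.size() > 0 && !Rf_isNull(external["type"])) {
    ext_type = as<int>(external["type"]);
    if (external.containsElementNamed("p1")) ext_p = as<double>(external["p1"]);
  }

  // velocities: flexible beads
  std::vector<double> vx(t.n, 0), vy(t.n, 0), vz(t.n, 0);
  bool have_vel = topo.containsElementNamed("vel") && !Rf_isNull(topo["vel"]);
  if (have_vel) {
    NumericMatrix V = topo["vel"];
    for (int i = 0; i < t.n; ++i) { vx[i] = V(i, 0); vy[i] = V(i, 1); vz[i] = V(i, 2); }
  } else if (T > 0) {
    for (int i = 0; i < t.n; ++i) {
      if (t.mobile[i] != 1) continue;
      double s = std::sqrt(kT / t.mass[i]);
      vx[i] = s * rng.norm(); vy[i] = s * rng.norm(); vz[i] = s * rng.norm();
    }
  }

  // cargo state
  double cc[3] = {0, 0, 0}, cq[4] = {1, 0, 0, 0}, cv[3] = {0, 0, 0}, cw[3] = {0, 0, 0};
  if (t.has_cargo) {
    List cg = topo["cargo"];
    NumericVector c0 = cg["center"];
    cc[0] = c0[0]; cc[1] = c0[1]; cc[2] = c0[2];
    if (cg.containsElementNamed("quat") && !Rf_isNull(cg["quat"])) {
      NumericVector q0 = cg["quat"];
      for (int k = 0; k < 4; ++k) cq[k] = q0[k];
    }
    if (T > 0 && !have_vel) {
      double s = std::sqrt(kT / t.cmass);
      for (int k = 0; k < 3; ++k) cv[k] = s * rng.norm();
      if (t.free_rotate && t.cinertia > 0) {
        double sw = std::sqrt(kT / t.cinertia);
        for (int k = 0; k < 3; ++k) cw[k] = sw * rng.norm();
      }
    } else if (have_vel && cg.containsElementNamed("vel")) {
      NumericVector cvv = cg["vel"], cww = cg["angvel"];
      for (int k = 0; k < 3; ++k) { cv[k] = cvv[k]; cw[k] = cww[k]; }
    }
    placeCargo(t, cc, cq);
  }

  NList nl;
  nl.build(t, f);
  std::vector<double> fx(t.n), fy(t.n), fz(t.n);
  double ec[6];
  computeForces(t, f, nl, fx, fy, fz, ec);

  // cargo net force/torque helper
  double cF[3] = {0, 0, 0}, cTq[3] = {0, 0, 0};
  auto cargoNet = [&]() {
    cF[0] = cF[1] = cF[2] = 0; cTq[0] = cTq[1] = cTq[2] = 0;
    for (size_t m = 0; m < t.cmember.size(); ++m) {
      int i = t.cmember[m];
      cF[0] += fx[i]; cF[1] += fy[i]; cF[2] += fz[i];
      double rx = t.x[i] - cc[0], ry = t.yy[i] - cc[1], rz = t.z[i] - cc[2];
      cTq[0] += ry * fz[i] - rz * fy[i];
      cTq[1] += rz * fx[i] - rx * fz[i];
      cTq[2] += rx * fy[i] - ry * fx[i];
    }
    double Rx, Ry, Rz;
    double rcx, rcy, rcz;
    restraintForce(rs, ext_type, ext_p,
                   t.has_cargo ? cc[0] : t.x[track_bead - 1],
                   t.has_cargo ? cc[1] : t.yy[track_bead - 1],
                   t.has_cargo ? cc[2] : t.z[track_bead - 1], rcx, rcy, rcz);
    Rx = rcx; Ry = rcy; Rz = rcz;
    if (t.has_cargo) { cF[0] += Rx; cF[1] += Ry; cF[2] += Rz; }
    else { int i = track_bead - 1; fx[i] += Rx; fy[i] += Ry; fz[i] += Rz; }
  };
  // apply restraint forces for bead-tracked case inside force recomputation
  auto recompute = [&]() {
    if (nl.stale(t)) nl.build(t, f);
    computeForces(t, f, nl, fx, fy, fz, ec);
    cargoNet();
  };
  cargoNet();

  double c1 = (gamma > 0) ? std::exp(-gamma * dt) : 1.0;
  double c2 = (gamma > 0) ? std::sqrt(std::max(0.0, 1.0 - c1 * c1)) : 0.0;
  double gr = gamma * 10.0 / 3.0;   // Stokes rotational friction rate
  double c1r = (gr > 0) ? std::exp(-gr * dt) : 1.0;
  double c2r = (gr > 0) ? std::sqrt(std::max(0.0, 1.0 - c1r * c1r)) : 0.0;

  int n_samples = (sample_every > 0) ? n_steps / sample_every : 0;
  NumericMatrix series(n_samples, 5);   // t, x, y, z, r
  NumericMatrix vseries(n_samples, 3);
  NumericVector ke_series(n_samples);
  int n_frames = (traj_every > 0) ? n_steps / traj_every + 1 : 0;
  List frames(n_frames);
  int fi = 0;
  if (traj_every > 0) {
    NumericMatrix fr(t.n, 3);
    for (int i = 0; i < t.n; ++i) { fr(i, 0) = t.x[i]; fr(i, 1) = t.yy[i]; fr(i, 2) = t.z[i]; }
    frames[fi++] = fr;
  }
  double bond_dev2_sum = 0;
  long bond_dev_n = 0;
  int dof = 0;
  for (int i = 0; i < t.n; ++i) if (t.mobile[i] == 1) dof += 3;

  int si = 0;
  for (int step = 1; step <= n_steps; ++step) {
    // B half
    for (int i = 0; i < t.n; ++i) {
      if (t.mobile[i] != 1) continue;
      double h = 0.5 * dt / t.mass[i];
      vx[i] += h * fx[i]; vy[i] += h * fy[i]; vz[i] += h * fz[i];
    }
    if (t.has_cargo) {
      double h = 0.5 * dt / t.cmass;
      for (int k = 0; k < 3; ++k) cv[k] += h * cF[k];
      if (t.free_rotate && t.cinertia > 0) {
        double hr = 0.5 * dt / t.cinertia;
        for (int k = 0; k < 3; ++k) cw[k] += hr * cTq[k];
      }
    }
    // A half
    for (int i = 0; i < t.n; ++i) {
      if (t.mobile[i] != 1) continue;
      t.x[i] += 0.5 * dt * vx[i]; t.yy[i] += 0.5 * dt * vy[i]; t.z[i] += 0.5 * dt * vz[i];
    }
    if (t.has_cargo) {
      for (int k = 0; k < 3; ++k) cc[k] += 0.5 * dt * cv[k];
      if (t.free_rotate) quatAdvance(cq, cw, 0.5 * dt);
    }
    // O
    if (gamma > 0 && T > 0) {
      for (int i = 0; i < t.n; ++i) {
        if (t.mobile[i] != 1) continue;
        double s = std::sqrt(kT / t.mass[i]);
        vx[i] = c1 * vx[i] + c2 * s * rng.norm();
        vy[i] = c1 * vy[i] + c2 * s * rng.norm();
        vz[i] = c1 * vz[i] + c2 * s * rng.norm();
      }
      if (t.has_cargo) {
        double s = std::sqrt(kT / t.cmass);
        for (int k = 0; k < 3; ++k) cv[k] = c1 * cv[k] + c2 * s * rng.norm();
        if (t.free_rotate && t.cinertia > 0) {
          double sw = std::sqrt(kT / t.cinertia);
          for (int k = 0; k < 3; ++k) cw[k] = c1r * cw[k] + c2r * sw * rng.norm();
        }
      }
    }
    // A half
    for (int i = 0; i < t.n; ++i) {
      if (t.mobile[i] != 1) continue;
      t.x[i] += 0.5 * dt * vx[i]; t.yy[i] += 0.5 * dt * vy[i]; t.z[i] += 0.5 * dt * vz[i];
    }
    if (t.has_cargo) {
      for (int k = 0; k < 3; ++k) cc[k] += 0.5 * dt * cv[k];
      if (t.free_rotate) quatAdvance(cq, cw, 0.5 * dt);
      placeCargo(t, cc, cq);
    }
    // force recompute + B half
    recompute();
    for (int i = 0; i < t.n; ++i) {
      if (t.mobile[i] != 1) continue;
      double h = 0.5 * dt / t.mass[i];
      vx[i] += h * fx[i]; vy[i] += h * fy[i]; vz[i] += h * fz[i];
      if (!std::isfinite(fx[i]) || !std::isfinite(fy[i]) || !std::isfinite(fz[i]))
        stop("non-finite force on bead %d at step %d", i + 1, step);
    }
    if (t.has_cargo) {
      double h = 0.5 * dt / t.cmass;
      for (int k = 0; k < 3; ++k) cv[k] += h * cF[k];
      if (t.free_rotate && t.cinertia > 0) {
        double hr = 0.5 * dt / t.cinertia;
        for (int k = 0; k < 3; ++k) cw[k] += hr * cTq[k];
      }
      if (!std::isfinite(cF[0]) || !std::isfinite(cF[2]))
        stop("non-finite cargo force at step %d", step);
    }

    if (sample_every > 0 && step % sample_every == 0 && si < n_samples) {
      double px, py, pz, pvx, pvy, pvz;
      if (t.has_cargo) {
        px = cc[0]; py = cc[1]; pz = cc[2];
        pvx = cv[0]; pvy = cv[1]; pvz = cv[2];
      } else {
        int i = track_bead - 1;
        px = t.x[i]; py = t.yy[i]; pz = t.z[i];
        pvx = vx[i]; pvy = vy[i]; pvz = vz[i];
      }
      series(si, 0) = step * dt; series(si, 1) = px; series(si, 2) = py;
      series(si, 3) = pz; series(si, 4) = std::sqrt(px * px + py * py);
      vseries(si, 0) = pvx; vseries(si, 1) = pvy; vseries(si, 2) = pvz;
      double ke = 0;
      for (int i = 0; i < t.n; ++i) {
        if (t.mobile[i] != 1) continue;
        ke += 0.5 * t.mass[i] * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
      }
      ke_series(si) = ke;
      for (int b = 0; b < t.bonds.nrow(); ++b) {
        int i = t.bonds(b, 0) - 1, j = t.bonds(b, 1) - 1;
        double dx = t.x[i] - t.x[j], dy = t.yy[i] - t.yy[j], dz = t.z[i] - t.z[j];
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        double dev = r - t.bond_r0[b];
        bond_dev2_sum += dev * dev;
        ++bond_dev_n;
      }
      ++si;
    }
    if (traj_every > 0 && step % traj_every == 0 && fi < n_frames) {
      NumericMatrix fr(t.n, 3);
      for (int i = 0; i < t.n; ++i) { fr(i, 0) = t.x[i]; fr(i, 1) = t.yy[i]; fr(i, 2) = t.z[i]; }
      frames[fi++] = fr;
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix P(t.n, 3), V(t.n, 3);
  for (int i = 0; i < t.n; ++i) {
    P(i, 0) = t.x[i]; P(i, 1) = t.yy[i]; P(i, 2) = t.z[i];
    V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i];
  }
  List cargo_state = R_NilValue;
  if (t.has_cargo) {
    cargo_state = List::create(
      _["center"] = NumericVector::create(cc[0], cc[1], cc[2]),
      _["quat"] = NumericVector::create(cq[0], cq[1], cq[2], cq[3]),
      _["vel"] = NumericVector::create(cv[0], cv[1], cv[2]),
      _["angvel"] = NumericVector::create(cw[0], cw[1], cw[2]));
  }
  return List::create(
    _["pos"] = P, _["vel"] = V, _["cargo_state"] = cargo_state,
    _["series"] = series, _["vseries"] = vseries, _["ke_series"] = ke_series,
    _["dof"] = dof,
    _["bond_rms"] = bond_dev_n > 0 ? std::sqrt(bond_dev2_sum / bond_dev_n) : NA_REAL,
    _["n_rebuilds"] = (double)nl.n_rebuilds,
    _["frames"] = frames);
}
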