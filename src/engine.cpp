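// Core simulation engine: Langevin (BAOAB) integration in a periodic box,
// truncated-LJ / harmonic-bond / cosine-angle force field, shifted-harmonic
// reversible sticker bonds with strict valency 1, Verlet neighbour list.
//
// Units follow the "real" convention: length in Angstrom, time in fs,
// energy in kcal/mol, mass in g/mol, temperature in Kelvin.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <sstream>
using namespace Rcpp;

// (g/mol)(A/fs)^2 expressed in kcal/mol: 1e7 J/mol / 4184 J/kcal
static const double MVV2E = 2390.05736137667;
static const double KB    = 0.0019872041; // kcal/mol/K

// ---------------------------------------------------------------------------
// Counter-based randomness: one SplitMix64 stream per (seed, step) pair so a
// resumed run draws exactly the numbers the uninterrupted run would have.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  inline uint64_t next() {
    s += 0x9e3779b97f4a7c15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // zero-mean unit-variance kick (uniform, as in the reference engine)
  inline double kick() { return 1.7320508075688772 * (2.0 * unif() - 1.0); }
  inline int below(int n) { return (int)(next() % (uint64_t)n); }
};

static inline uint64_t stream_seed(uint64_t seed, uint64_t ctr) {
  uint64_t z = seed * 0x9e3779b97f4a7c15ULL + ctr * 0xbf58476d1ce4e5b9ULL
             + 0x6a09e667f3bcc909ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Engine {
  int N = 0;
  // state (struct-of-arrays)
  std::vector<double> x, y, z, vx, vy, vz, fx, fy, fz;
  std::vector<int> ix, iy, iz;
  std::vector<int> partner; // -1 = unpaired
  double Lx = 0, Ly = 0, Lz = 0, iLx = 0, iLy = 0, iLz = 0;

  // topology
  std::vector<int> b1, b2;       // permanent bonds
  std::vector<int> a1, a2, a3;   // angles (a2 = centre)
  std::vector<int> stype;        // 0 spacer, >=1 sticker type
  std::vector<int> chain;
  std::vector<int> stickers;     // indices with stype > 0
  std::vector<std::vector<int>> excl; // permanent 1-2 exclusions
  std::vector<uint8_t> comp;     // ntypes x ntypes complementarity
  int ntypes = 0;

  // force-field parameters
  double Kb = 0, R0b = 0, kappa = 0, sigma = 0, Ens = 0, Rmax = 0;
  double Es = 0, R0s = 0, Rcut = 0, pon = 1, poff = 1;
  double sigma2 = 0, Rmax2 = 0, Rcut2 = 0, kstick = 0, shift2 = 0;
  bool have_pair = false;

  // energies of the last evaluation
  double e_bond = 0, e_pair = 0, e_angle = 0;

  // neighbour list
  double skin = 3.0, cutnb = 0, cutnb2 = 0;
  std::vector<int> pi_, pj_;
  std::vector<double> xb, yb, zb;
  bool allpairs = false;
  long long n_builds = 0;

  // nearest-image convention; valid for |d| < 1.5 L, which holds because
  // positions are kept wrapped inside the box (branch is cheaper than
  // nearbyint on targets without SSE4.1 rounding)
  inline double mix(double d, double L, double iL) const {
    double h = 0.5 * L;
    if (d > h) d -= L; else if (d < -h) d += L;
    if (d > h) d -= L; else if (d < -h) d += L;
    return d;
  }
  inline double dist2(int i, int j, double &dx, double &dy, double &dz) const {
    dx = mix(x[i] - x[j], Lx, iLx);
    dy = mix(y[i] - y[j], Ly, iLy);
    dz = mix(z[i] - z[j], Lz, iLz);
    return dx * dx + dy * dy + dz * dz;
  }
  inline bool excluded(int i, int j) const {
    for (int k : excl[i]) if (k == j) return true;
    return false;
  }
  inline bool complementary(int i, int j) const {
    int ti = stype[i], tj = stype[j];
    if (ti <= 0 || tj <= 0) return false;
    return comp[(size_t)(ti - 1) * ntypes + (tj - 1)] != 0;
  }

  void setup_derived() {
    iLx = 1.0 / Lx; iLy = 1.0 / Ly; iLz = 1.0 / Lz;
    sigma2 = sigma * sigma;
    Rmax2 = Rmax * Rmax;
    Rcut2 = Rcut * Rcut;
    double d = R0s - Rcut;
    kstick = (d != 0) ? Es / (d * d) : 0.0;
    shift2 = d * d;
    have_pair = (Ens > 0.0);
    double cut_needed = std::max(have_pair ? Rmax : 0.0,
                                 stickers.empty() ? 0.0 : Rcut);
    cutnb = cut_needed + skin;
    cutnb2 = cutnb * cutnb;
    excl.assign(N, {});
    for (size_t b = 0; b < b1.size(); ++b) {
      excl[b1[b]].push_back(b2[b]);
      excl[b2[b]].push_back(b1[b]);
    }
  }

  // -------------------------------------------------------------------------
  void build_neighbors() {
    ++n_builds;
    pi_.clear(); pj_.clear();
    xb = x; yb = y; zb = z;
    if (cutnb <= skin) { allpairs = false; return; } // no interactions at all
    // cap the grid so the cell count stays O(N) even for short cutoffs
    int cap = (int)std::ceil(std::cbrt(2.0 * N + 1.0));
    int nx = std::min((int)std::floor(Lx / cutnb), cap);
    int ny = std::min((int)std::floor(Ly / cutnb), cap);
    int nz = std::min((int)std::floor(Lz / cutnb), cap);
    allpairs = (nx < 3 || ny < 3 || nz < 3);
    if (allpairs) {
      for (int i = 0; i < N; ++i)
        for (int j = i + 1; j < N; ++j) {
          double dx, dy, dz;
          if (dist2(i, j, dx, dy, dz) <= cutnb2 && !excluded(i, j))
            { pi_.push_back(i); pj_.push_back(j); }
        }
      return;
    }
    double cx = Lx / nx, cy = Ly / ny, cz = Lz / nz;
    int ncell = nx * ny * nz;
    std::vector<int> head(ncell, -1), nxt(N, -1), ci(N), cj(N), ck(N);
    for (int i = 0; i < N; ++i) {
      int a = std::min(nx - 1, std::max(0, (int)(x[i] / cx)));
      int b = std::min(ny - 1, std::max(0, (int)(y[i] / cy)));
      int c = std::min(nz - 1, std::max(0, (int)(z[i] / cz)));
      ci[i] = a; cj[i] = b; ck[i] = c;
      int cell = (c * ny + b) * nx + a;
      nxt[i] = head[cell]; head[cell] = i;
    }
    // half stencil: 13 neighbour offsets + self cell; driven per bead so
    // cost scales with N, not with the (mostly empty) cell count
    static const int off[13][3] = {
      {1,0,0},{ -1,1,0},{0,1,0},{1,1,0},
      { -1,-1,1},{0,-1,1},{1,-1,1},{ -1,0,1},{0,0,1},{1,0,1},
      { -1,1,1},{0,1,1},{1,1,1}};
    for (int i = 0; i < N; ++i) {
      int a = ci[i], b = cj[i], c = ck[i];
      // same cell: list members after i
      for (int j = nxt[i]; j >= 0; j = nxt[j]) {
        double dx, dy, dz;
        if (dist2(i, j, dx, dy, dz) <= cutnb2 && !excluded(i, j)) {
          if (i < j) { pi_.push_back(i); pj_.push_back(j); }
          else       { pi_.push_back(j); pj_.push_back(i); }
        }
      }
      for (int o = 0; o < 13; ++o) {
        int aa = a + off[o][0]; if (aa < 0) aa += nx; else if (aa >= nx) aa -= nx;
        int bb = b + off[o][1]; if (bb < 0) bb += ny; else if (bb >= ny) bb -= ny;
        int cc = c + off[o][2]; if (cc < 0) cc += nz; else if (cc >= nz) cc -= nz;
        int cell2 = (cc * ny + bb) * nx + aa;
        for (int j = head[cell2]; j >= 0; j = nxt[j]) {
          double dx, dy, dz;
          if (dist2(i, j, dx, dy, dz) <= cutnb2 && !excluded(i, j)) {
            if (i < j) { pi_.push_back(i); pj_.push_back(j); }
            else       { pi_.push_back(j); pj_.push_back(i); }
          }
        }
      }
    }
  }

  bool need_rebuild() const {
    double lim = 0.25 * skin * skin; // (skin/2)^2
    for (int i = 0; i < N; ++i) {
      double dx = mix(x[i] - xb[i], Lx, iLx);
      double dy = mix(y[i] - yb[i], Ly, iLy);
      double dz = mix(z[i] - zb[i], Lz, iLz);
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }

  // -------------------------------------------------------------------------
  void forces(bool with_energy) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    e_bond = e_pair = e_angle = 0.0;

    // permanent harmonic bonds: E = Kb (R - R0)^2
    for (size_t b = 0; b < b1.size(); ++b) {
      int i = b1[b], j = b2[b];
      double dx, dy, dz;
      double r2 = dist2(i, j, dx, dy, dz);
      double rinv = 1.0 / std::sqrt(r2);
      double dr = r2 * rinv - R0b; // r - R0
      if (with_energy) e_bond += Kb * dr * dr;
      double fr = -2.0 * Kb * dr * rinv;
      fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
      fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    }

    // active sticker bonds: E = Es/(R0-Rcut)^2 [(R-R0)^2 - (Rcut-R0)^2], R < Rcut
    for (int i : stickers) {
      int j = partner[i];
      if (j > i) {
        double dx, dy, dz;
        double r2 = dist2(i, j, dx, dy, dz);
        if (r2 < Rcut2) {
          double r = std::sqrt(r2);
          double dr = r - R0s;
          if (with_energy) e_bond += kstick * (dr * dr - shift2);
          double fr = -2.0 * kstick * dr / r;
          fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
          fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
        }
      }
    }

    // cosine bending about the interior angle: E = kappa (1 + cos theta)
    for (size_t t = 0; t < a2.size(); ++t) {
      int i = a1[t], j = a2[t], k = a3[t];
      double ax = mix(x[i] - x[j], Lx, iLx);
      double ay = mix(y[i] - y[j], Ly, iLy);
      double az = mix(z[i] - z[j], Lz, iLz);
      double bx_ = mix(x[k] - x[j], Lx, iLx);
      double by_ = mix(y[k] - y[j], Ly, iLy);
      double bz_ = mix(z[k] - z[j], Lz, iLz);
      double ra2 = ax * ax + ay * ay + az * az;
      double rb2 = bx_ * bx_ + by_ * by_ + bz_ * bz_;
      double ira2 = 1.0 / ra2, irb2 = 1.0 / rb2;
      double inv = std::sqrt(ira2 * irb2);
      double c = (ax * bx_ + ay * by_ + az * bz_) * inv;
      if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
      if (with_energy) e_angle += kappa * (1.0 + c);
      // F = -kappa * grad(cos theta)
      double ca = c * ira2, cb = c * irb2;
      double gix = -kappa * (bx_ * inv - ca * ax);
      double giy = -kappa * (by_ * inv - ca * ay);
      double giz = -kappa * (bz_ * inv - ca * az);
      double gkx = -kappa * (ax * inv - cb * bx_);
      double gky = -kappa * (ay * inv - cb * by_);
      double gkz = -kappa * (az * inv - cb * bz_);
      fx[i] += gix; fy[i] += giy; fz[i] += giz;
      fx[k] += gkx; fy[k] += gky; fz[k] += gkz;
      fx[j] -= gix + gkx; fy[j] -= giy + gky; fz[j] -= giz + gkz;
    }

    // truncated (unshifted) Lennard-Jones over non-excluded pairs
    if (have_pair) {
      size_t np = pi_.size();
      for (size_t p = 0; p < np; ++p) {
        int i = pi_[p], j = pj_[p];
        if (partner[i] == j) continue; // bonded stickers feel no LJ
        double dx, dy, dz;
        double r2 = dist2(i, j, dx, dy, dz);
        if (r2 > Rmax2) continue;
        if (r2 < 1e-12) stop("bead overlap: pair distance numerically zero");
        double sr2 = sigma2 / r2;
        double sr6 = sr2 * sr2 * sr2;
        double sr12 = sr6 * sr6;
        if (with_energy) e_pair += 4.0 * Ens * (sr12 - sr6);
        double fr = 24.0 * Ens * (2.0 * sr12 - sr6) / r2;
        fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
        fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
      }
    }
  }

  // -------------------------------------------------------------------------
  int n_paired() const {
    int n = 0;
    for (int i : stickers) if (partner[i] >= 0) ++n;
    return n;
  }

  // returns true if any pairing changed
  bool bond_attempt(long long step, uint64_t seed_b,
                    std::vector<long long> &ev_step, std::vector<int> &ev_kind,
                    std::vector<int> &ev_i, std::vector<int> &ev_j) {
    Rng g(stream_seed(seed_b, (uint64_t)step));
    bool changed = false;
    // break pass: bonded pairs with R >= Rcut break with probability poff
    for (int i : stickers) {
      int j = partner[i];
      if (j > i) {
        double dx, dy, dz;
        double r2 = dist2(i, j, dx, dy, dz);
        if (r2 >= Rcut2) {
          if (g.unif() < poff) {
            partner[i] = -1; partner[j] = -1;
            ev_step.push_back(step); ev_kind.push_back(0);
            ev_i.push_back(i); ev_j.push_back(j);
            changed = true;
          }
        }
      }
    }
    // create pass: complementary unpaired pairs within Rcut, random order
    std::vector<std::pair<int,int>> cand;
    size_t np = pi_.size();
    for (size_t p = 0; p < np; ++p) {
      int i = pi_[p], j = pj_[p];
      if (partner[i] >= 0 || partner[j] >= 0) continue;
      if (!complementary(i, j)) continue;
      double dx, dy, dz;
      if (dist2(i, j, dx, dy, dz) <= Rcut2)
        cand.push_back(std::make_pair(i, j));
    }
    int nc = (int)cand.size();
    for (int k = nc - 1; k > 0; --k) std::swap(cand[k], cand[g.below(k + 1)]);
    for (int k = 0; k < nc; ++k) {
      int i = cand[k].first, j = cand[k].second;
      if (partner[i] >= 0 || partner[j] >= 0) continue;
      if (g.unif() < pon) {
        partner[i] = j; partner[j] = i;
        ev_step.push_back(step); ev_kind.push_back(1);
        ev_i.push_back(i); ev_j.push_back(j);
        changed = true;
      }
    }
    return changed;
  }
};

// ---------------------------------------------------------------------------
static Engine make_engine(NumericMatrix pos, NumericMatrix vel,
                          IntegerMatrix img, IntegerVector pairing,
                          NumericVector box, List topo, List params,
                          double skin) {
  Engine e;
  e.N = pos.nrow();
  e.Lx = box[0]; e.Ly = box[1]; e.Lz = box[2];
  e.x.resize(e.N); e.y.resize(e.N); e.z.resize(e.N);
  e.vx.resize(e.N); e.vy.resize(e.N); e.vz.resize(e.N);
  e.fx.resize(e.N); e.fy.resize(e.N); e.fz.resize(e.N);
  e.ix.resize(e.N); e.iy.resize(e.N); e.iz.resize(e.N);
  e.partner.assign(e.N, -1);
  for (int i = 0; i < e.N; ++i) {
    e.x[i] = pos(i, 0); e.y[i] = pos(i, 1); e.z[i] = pos(i, 2);
    e.vx[i] = vel(i, 0); e.vy[i] = vel(i, 1); e.vz[i] = vel(i, 2);
    e.ix[i] = img(i, 0); e.iy[i] = img(i, 1); e.iz[i] = img(i, 2);
    int p = pairing[i]; // 1-based, NA/0 = none
    e.partner[i] = (p == NA_INTEGER || p <= 0) ? -1 : p - 1;
  }
  IntegerMatrix bonds = topo["bonds"];
  for (int b = 0; b < bonds.nrow(); ++b) {
    e.b1.push_back(bonds(b, 0) - 1); e.b2.push_back(bonds(b, 1) - 1);
  }
  IntegerMatrix angles = topo["angles"];
  for (int t = 0; t < angles.nrow(); ++t) {
    e.a1.push_back(angles(t, 0) - 1);
    e.a2.push_back(angles(t, 1) - 1);
    e.a3.push_back(angles(t, 2) - 1);
  }
  IntegerVector st = topo["type"];
  IntegerVector ch = topo["chain"];
  e.stype.assign(st.begin(), st.end());
  e.chain.assign(ch.begin(), ch.end());
  for (int i = 0; i < e.N; ++i) if (e.stype[i] > 0) e.stickers.push_back(i);
  IntegerMatrix cm = topo["comp"];
  e.ntypes = cm.nrow();
  e.comp.resize((size_t)e.ntypes * e.ntypes);
  for (int a = 0; a < e.ntypes; ++a)
    for (int b = 0; b < e.ntypes; ++b)
      e.comp[(size_t)a * e.ntypes + b] = (uint8_t)(cm(a, b) != 0);

  e.Kb = params["Kb"]; e.R0b = params["R0_bond"]; e.kappa = params["kappa"];
  e.sigma = params["sigma"]; e.Ens = params["Ens"]; e.Rmax = params["Rmax"];
  e.Es = params["Es"]; e.R0s = params["R0_stick"]; e.Rcut = params["Rcut_stick"];
  e.pon = params["p_on"]; e.poff = params["p_off"];
  e.skin = skin;
  e.setup_derived();
  return e;
}

static List engine_state(const Engine &e, long long step) {
  NumericMatrix pos(e.N, 3), vel(e.N, 3);
  IntegerMatrix img(e.N, 3);
  IntegerVector pairing(e.N);
  for (int i = 0; i < e.N; ++i) {
    pos(i, 0) = e.x[i]; pos(i, 1) = e.y[i]; pos(i, 2) = e.z[i];
    vel(i, 0) = e.vx[i]; vel(i, 1) = e.vy[i]; vel(i, 2) = e.vz[i];
    img(i, 0) = e.ix[i]; img(i, 1) = e.iy[i]; img(i, 2) = e.iz[i];
    pairing[i] = (e.partner[i] < 0) ? NA_INTEGER : e.partner[i] + 1;
  }
  return List::create(_["pos"] = pos, _["vel"] = vel, _["img"] = img,
                      _["pairing"] = pairing,
                      _["box"] = NumericVector::create(e.Lx, e.Ly, e.Lz),
                      _["step"] = (double)step);
}

// [[Rcpp::export]]
List md_run_cpp(NumericMatrix pos, NumericMatrix vel, IntegerMatrix img,
                IntegerVector pairing, NumericVector box,
                List topo, List params, List config) {
  Engine e = make_engine(pos, vel, img, pairing, box, topo, params,
                         as<double>(config["skin"]));
  const double dt = config["dt"];
  const double T = config["T"];
  const double t_damp = config["t_damp"];
  const double mass = config["mass"];
  const long long n_steps = (long long)as<double>(config["n_steps"]);
  const long long step0 = (long long)as<double>(config["step0"]);
  const int bond_every = config["bond_attempt_every"];
  const long long thermo_every = (long long)as<double>(config["thermo_every"]);
  const long long dump_every = (long long)as<double>(config["dump_every"]);
  const bool sample_series = config["sample_series"];
  const bool langevin = config["langevin"];
  const bool do_bonds = config["bond_moves"];
  const uint64_t seed_t = (uint64_t)as<double>(config["seed_thermostat"]);
  const uint64_t seed_b = (uint64_t)as<double>(config["seed_bonds"]);

  const double inv_mE = 1.0 / (mass * MVV2E);
  const double h = 0.5 * dt;
  double c1 = 1.0, c2 = 0.0;
  const bool thermo_on = langevin && R_finite(t_damp);
  if (thermo_on) {
    c1 = std::exp(-dt / t_damp);
    c2 = std::sqrt(KB * T / (mass * MVV2E)) * std::sqrt(1.0 - c1 * c1);
  }
  const double guard = 0.25 * std::min(e.Lx, std::min(e.Ly, e.Lz));
  const double guard2 = guard * guard;
  const int nst = (int)e.stickers.size();

  std::vector<long long> ev_step; std::vector<int> ev_kind, ev_i, ev_j;
  std::vector<double> th_rows;          // thermo table, 8 columns
  std::vector<long long> series_step; std::vector<int> series_np;
  std::vector<double> traj; std::vector<long long> traj_step;

  e.build_neighbors();
  e.forces(true);

  auto kinetic = [&]() {
    double k = 0;
    for (int i = 0; i < e.N; ++i)
      k += e.vx[i] * e.vx[i] + e.vy[i] * e.vy[i] + e.vz[i] * e.vz[i];
    return 0.5 * mass * k * MVV2E;
  };
  auto emit_thermo = [&](long long s) {
    double ke = kinetic();
    double ep = e.e_bond + e.e_pair + e.e_angle;
    double ti = (e.N > 0) ? 2.0 * ke / (3.0 * e.N * KB) : 0.0;
    double sat = (nst > 0) ? (double)e.n_paired() / nst : NA_REAL;
    th_rows.push_back((double)s); th_rows.push_back(e.e_bond);
    th_rows.push_back(e.e_pair); th_rows.push_back(e.e_angle);
    th_rows.push_back(ep); th_rows.push_back(ke);
    th_rows.push_back(ti); th_rows.push_back(sat);
  };
  auto emit_dump = [&](long long s) {
    traj_step.push_back(s);
    for (int i = 0; i < e.N; ++i) {
      traj.push_back(e.x[i] + e.ix[i] * e.Lx);
      traj.push_back(e.y[i] + e.iy[i] * e.Ly);
      traj.push_back(e.z[i] + e.iz[i] * e.Lz);
    }
  };

  if (thermo_every > 0) emit_thermo(step0);
  if (dump_every > 0) emit_dump(step0);

  for (long long s = step0 + 1; s <= step0 + n_steps; ++s) {
    const bool attempt = do_bonds && bond_every > 0 && (s % bond_every == 0);
    const bool th = thermo_every > 0 &&
                    (s % thermo_every == 0 || s == step0 + n_steps);

    // B
    for (int i = 0; i < e.N; ++i) {
      e.vx[i] += h * e.fx[i] * inv_mE;
      e.vy[i] += h * e.fy[i] * inv_mE;
      e.vz[i] += h * e.fz[i] * inv_mE;
    }
    // A, O, A
    for (int i = 0; i < e.N; ++i) {
      e.x[i] += h * e.vx[i]; e.y[i] += h * e.vy[i]; e.z[i] += h * e.vz[i];
    }
    if (thermo_on) {
      Rng g(stream_seed(seed_t, (uint64_t)s));
      for (int i = 0; i < e.N; ++i) {
        e.vx[i] = c1 * e.vx[i] + c2 * g.kick();
        e.vy[i] = c1 * e.vy[i] + c2 * g.kick();
        e.vz[i] = c1 * e.vz[i] + c2 * g.kick();
      }
    }
    double maxd2 = 0.0;
    for (int i = 0; i < e.N; ++i) {
      double dx = h * e.vx[i], dy = h * e.vy[i], dz = h * e.vz[i];
      e.x[i] += dx; e.y[i] += dy; e.z[i] += dz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > maxd2) maxd2 = d2;
    }
    if (4.0 * maxd2 > guard2) {
      std::ostringstream msg;
      msg << "instability at step " << s
          << ": displacement exceeds box/4 (reduce dt)";
      stop(msg.str());
    }
    // wrap + image flags (per-step displacement is << L by the guard above)
    for (int i = 0; i < e.N; ++i) {
      if (e.x[i] >= e.Lx) { e.x[i] -= e.Lx; ++e.ix[i]; }
      else if (e.x[i] < 0) { e.x[i] += e.Lx; --e.ix[i]; }
      if (e.y[i] >= e.Ly) { e.y[i] -= e.Ly; ++e.iy[i]; }
      else if (e.y[i] < 0) { e.y[i] += e.Ly; --e.iy[i]; }
      if (e.z[i] >= e.Lz) { e.z[i] -= e.Lz; ++e.iz[i]; }
      else if (e.z[i] < 0) { e.z[i] += e.Lz; --e.iz[i]; }
    }
    if (e.need_rebuild()) e.build_neighbors();
    e.forces(th && !attempt);
    // B
    for (int i = 0; i < e.N; ++i) {
      e.vx[i] += h * e.fx[i] * inv_mE;
      e.vy[i] += h * e.fy[i] * inv_mE;
      e.vz[i] += h * e.fz[i] * inv_mE;
    }

    if (attempt) {
      bool changed = e.bond_attempt(s, seed_b, ev_step, ev_kind, ev_i, ev_j);
      if (changed || th) e.forces(th); // keep forces consistent with pairing
      if (sample_series) {
        series_step.push_back(s);
        series_np.push_back(e.n_paired());
      }
    }
    if (th) emit_thermo(s);
    if (dump_every > 0 && s % dump_every == 0) emit_dump(s);
    if ((s & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  int nth = (int)(th_rows.size() / 8);
  NumericMatrix thermo(nth, 8);
  for (int r = 0; r < nth; ++r)
    for (int c = 0; c < 8; ++c) thermo(r, c) = th_rows[(size_t)r * 8 + c];

  int nev = (int)ev_step.size();
  NumericVector evs(nev); IntegerVector evk(nev), evi(nev), evj(nev);
  for (int k = 0; k < nev; ++k) {
    evs[k] = (double)ev_step[k]; evk[k] = ev_kind[k];
    evi[k] = ev_i[k] + 1; evj[k] = ev_j[k] + 1;
  }

  int nfr = (int)traj_step.size();
  NumericVector tsteps(nfr);
  for (int k = 0; k < nfr; ++k) tsteps[k] = (double)traj_step[k];
  NumericVector tpos((size_t)nfr * e.N * 3);
  std::copy(traj.begin(), traj.end(), tpos.begin());

  int nsr = (int)series_step.size();
  NumericVector sst(nsr); IntegerVector snp(nsr);
  for (int k = 0; k < nsr; ++k) { sst[k] = (double)series_step[k]; snp[k] = series_np[k]; }

  return List::create(
    _["state"] = engine_state(e, step0 + n_steps),
    _["thermo"] = thermo,
    _["events"] = List::create(_["step"] = evs, _["kind"] = evk,
                               _["i"] = evi, _["j"] = evj),
    _["series"] = List::create(_["step"] = sst, _["n_paired"] = snp),
    _["traj_steps"] = tsteps,
    _["traj"] = tpos,
    _["n_neighbor_builds"] = (double)e.n_builds);
}

// [[Rcpp::export]]
List energy_forces_cpp(NumericMatrix pos, IntegerVector pairing,
                       NumericVector box, List topo, List params) {
  int n = pos.nrow();
  NumericMatrix vel(n, 3);
  IntegerMatrix img(n, 3);
  Engine e = make_engine(pos, vel, img, pairing, box, topo, params, 0.0);
  e.build_neighbors();
  e.forces(true);
  NumericMatrix f(n, 3);
  for (int i = 0; i < n; ++i) {
    f(i, 0) = e.fx[i]; f(i, 1) = e.fy[i]; f(i, 2) = e.fz[i];
  }
  return List::create(_["forces"] = f, _["E_bond"] = e.e_bond,
                      _["E_pair"] = e.e_pair, _["E_angle"] = e.e_angle,
                      _["E_potential"] = e.e_bond + e.e_pair + e.e_angle,
                      _["all_pairs"] = e.allpairs);
}

// [[Rcpp::export]]
List bond_update_cpp(NumericMatrix pos, IntegerVector pairing,
                     NumericVector box, List topo, List params,
                     double seed_bonds, double step) {
  int n = pos.nrow();
  NumericMatrix vel(n, 3);
  IntegerMatrix img(n, 3);
  Engine e = make_engine(pos, vel, img, pairing, box, topo, params, 0.0);
  e.build_neighbors();
  std::vector<long long> ev_step; std::vector<int> ev_kind, ev_i, ev_j;
  e.bond_attempt((long long)step, (uint64_t)seed_bonds,
                 ev_step, ev_kind, ev_i, ev_j);
  IntegerVector newp(n);
  for (int i = 0; i < n; ++i)
    newp[i] = (e.partner[i] < 0) ? NA_INTEGER : e.partner[i] + 1;
  int nev = (int)ev_step.size();
  NumericVector evs(nev); IntegerVector evk(nev), evi(nev), evj(nev);
  for (int k = 0; k < nev; ++k) {
    evs[k] = (double)ev_step[k]; evk[k] = ev_kind[k];
    evi[k] = ev_i[k] + 1; evj[k] = ev_j[k] + 1;
  }
  return List::create(_["pairing"] = newp,
                      _["events"] = List::create(_["step"] = evs,
                        _["kind"] = evk, _["i"] = evi, _["j"] = evj));
}

// [[Rcpp::export]]
IntegerMatrix neighbor_pairs_cpp(NumericMatrix pos, NumericVector box,
                                 double cutoff, double skin) {
  int n = pos.nrow();
  NumericMatrix vel(n, 3);
  IntegerMatrix img(n, 3);
  IntegerVector pairing(n, NA_INTEGER);
  List topo = List::create(
    _["bonds"] = IntegerMatrix(0, 2), _["angles"] = IntegerMatrix(0, 3),
    _["type"] = IntegerVector(n), _["chain"] = IntegerVector(n, 1),
    _["comp"] = IntegerMatrix(1, 1));
  List params = List::create(
    _["Kb"] = 0.0, _["R0_bond"] = 0.0, _["kappa"] = 0.0, _["sigma"] = 1.0,
    _["Ens"] = 1.0, _["Rmax"] = cutoff, _["Es"] = 0.0, _["R0_stick"] = 0.5,
    _["Rcut_stick"] = 1.0, _["p_on"] = 1.0, _["p_off"] = 1.0);
  Engine e = make_engine(pos, vel, img, pairing, box, topo, params, skin);
  e.build_neighbors();
  // prune to the true cutoff so callers get exactly the pairs within it
  std::vector<int> ai, aj;
  for (size_t p = 0; p < e.pi_.size(); ++p) {
    double dx, dy, dz;
    if (e.dist2(e.pi_[p], e.pj_[p], dx, dy, dz) <= cutoff * cutoff) {
      ai.push_back(e.pi_[p] + 1); aj.push_back(e.pj_[p] + 1);
    }
  }
  IntegerMatrix out((int)ai.size(), 2);
  for (int k = 0; k < (int)ai.size(); ++k) { out(k, 0) = ai[k]; out(k, 1) = aj[k]; }
  return out;
}

// [[Rcpp::export]]
List unit_constants_cpp() {
  return List::create(_["mvv2e"] = MVV2E, _["kB"] = KB);
}
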