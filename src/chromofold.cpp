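// Mesoscale chromatin fiber Monte Carlo kernels.
//
// The fiber is a flat bead list: nucleosome core centers (type 0) with rigid
// surface charge beads (1), linker-DNA beads (2), histone-tail beads (3),
// linker-histone beads (4), and massless attachment anchors (5 tail, 6 LH).
// Bonded terms are harmonic stretch / bend / twist; nonbonded terms are
// Debye-Hueckel screened electrostatics and 12-6 Lennard-Jones, both cut off
// at a configured radius. Folded (acetylated) tails are excluded from every
// nonbonded pair list and use their own (stiffened) bonded constants.
//
// All energies are in units of kBT; all lengths in nm.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <random>
#include <unordered_map>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: mt19937_64 with explicit uniform/normal so streams are reproducible
// across platforms independent of <random> distribution implementations.
struct RNG {
  std::mt19937_64 gen;
  bool has_spare = false;
  double spare = 0.0;
  explicit RNG(uint64_t seed) : gen(seed) {}
  double unif() {  // [0, 1)
    return (gen() >> 11) * (1.0 / 9007199254740992.0);
  }
  double unif(double a, double b) { return a + (b - a) * unif(); }
  int unif_int(int n) {  // 0 .. n-1
    return (int)(unif() * n) % n;
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = 0.0, u2;
    while (u1 == 0.0) u1 = unif();
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), t = 2.0 * M_PI * u2;
    spare = r * std::sin(t);
    has_spare = true;
    return r * std::cos(t);
  }
  void sphere(double* v) {  // uniform direction (Marsaglia)
    double a, b, s;
    do { a = unif(-1, 1); b = unif(-1, 1); s = a * a + b * b; } while (s >= 1);
    double f = 2.0 * std::sqrt(1.0 - s);
    v[0] = a * f; v[1] = b * f; v[2] = 1.0 - 2.0 * s;
  }
};

// ---------------------------------------------------------------------------
// System container (0-based indices internally)
struct Tail {
  std::vector<int> beads;   // ordered from the anchor outward
  int anchor;
  int kind;                 // 1 H3, 2 H4, 3 H2A-N, 4 H2A-C, 5 H2B
  int core;                 // 0-based nucleosome index
  bool acetylated;
  bool folded;
  std::vector<double> alt;  // 3*nb alternate-template coordinates
  std::vector<int> bond_ids, angle_ids;
  double l0_alt, h_alt, g_alt;  // constants of the inactive state
};

struct System {
  int N = 0, ncores = 0;
  std::vector<double> x, y, z;
  std::vector<int> type, core_of, tail_of, dna_owner;
  std::vector<double> charge, diam, path_pos;
  std::vector<char> folded_bead, is_nb;  // nonbonded-active types 1..4
  std::vector<int> mobile;               // indices of DNA + LH beads
  std::vector<int> core_idx;             // bead index of each core center
  // bonded
  std::vector<int> b1, b2;  std::vector<double> bl0, bk;
  std::vector<int> a1, a2, a3;  std::vector<double> ag, at0;
  std::vector<double> tw_phi, tw_phi0, tw_s;
  std::vector<Tail> tails;
  // per-bead bonded adjacency
  std::vector<std::vector<int>> bonds_of, angles_of;
  std::unordered_set<int64_t> excl;
  // force field
  double lB = 0, kappa = 0, kappa_dd = 0, lj_eps = 0, cutoff = 0;
  bool mg_mode = false;

  int64_t key(int i, int j) const {
    if (i > j) std::swap(i, j);
    return (int64_t)i * N + j;
  }
  // every exclusion pair lives within the same or adjacent nucleosomes, so
  // a cheap core-index prefilter avoids most hash lookups
  bool excluded(int i, int j) const {
    if (std::abs(core_of[i] - core_of[j]) > 1) return false;
    return excl.count(key(i, j)) > 0;
  }

  // squared distance (for cheap cutoff tests before any hash lookup)
  double dist2(int i, int j) const {
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    return dx * dx + dy * dy + dz * dz;
  }

  double pair_energy(int i, int j, double* elec, double* evol) const {
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= cutoff * cutoff) return 0.0;
    double r = std::sqrt(r2);
    if (r < 1e-9) return R_PosInf;
    double kap = (mg_mode && type[i] == 2 && type[j] == 2) ? kappa_dd : kappa;
    double e_el = lB * charge[i] * charge[j] * std::exp(-kap * r) / r;
    double sig = 0.5 * (diam[i] + diam[j]);
    double sr6 = std::pow(sig / r, 6);
    double e_lj = 4.0 * lj_eps * (sr6 * sr6 - sr6);
    if (elec) *elec += e_el;
    if (evol) *evol += e_lj;
    return e_el + e_lj;
  }
  bool nb_active(int i) const {
    return is_nb[i] && !folded_bead[i];
  }

  double bond_energy(int b) const {
    int i = b1[b], j = b2[b];
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    double l = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d = l - bl0[b];
    return 0.5 * bk[b] * d * d;
  }
  double angle_energy(int a) const {
    int i = a1[a], j = a2[a], k = a3[a];
    double ux = x[i] - x[j], uy = y[i] - y[j], uz = z[i] - z[j];
    double vx = x[k] - x[j], vy = y[k] - y[j], vz = z[k] - z[j];
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (nu < 1e-12 || nv < 1e-12) return 0.0;
    double c = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    c = std::max(-1.0, std::min(1.0, c));
    double d = std::acos(c) - at0[a];
    return 0.5 * ag[a] * d * d;
  }
  double twist_energy(int s) const {
    double d = tw_phi[s] - tw_phi0[s];
    return 0.5 * tw_s[s] * d * d;
  }

  void full_bonded(double* stretch, double* bend, double* twist) const {
    *stretch = *bend = *twist = 0.0;
    for (size_t b = 0; b < b1.size(); ++b) *stretch += bond_energy((int)b);
    for (size_t a = 0; a < a1.size(); ++a) *bend += angle_energy((int)a);
    for (size_t s = 0; s < tw_phi.size(); ++s) *twist += twist_energy((int)s);
  }
  void full_nonbonded(double* elec, double* evol) const {
    *elec = *evol = 0.0;
    double c2 = cutoff * cutoff;
    for (int i = 0; i < N; ++i) {
      if (!nb_active(i)) continue;
      for (int j = i + 1; j < N; ++j) {
        if (!nb_active(j) || dist2(i, j) >= c2 || excluded(i, j)) continue;
        pair_energy(i, j, elec, evol);
      }
    }
  }
  // nonbonded energy of the bead set S against everything (S-S pairs once)
  double nb_set_energy(const std::vector<int>& S) const {
    std::vector<char> inS(N, 0);
    for (int i : S) inS[i] = 1;
    double e = 0, dummy1 = 0, dummy2 = 0;
    double c2 = cutoff * cutoff;
    for (int i : S) {
      if (!nb_active(i)) continue;
      for (int j = 0; j < N; ++j) {
        if (j == i || !nb_active(j) || (inS[j] && j < i)) continue;
        if (dist2(i, j) >= c2 || excluded(i, j)) continue;
        e += pair_energy(i, j, &dummy1, &dummy2);
      }
    }
    return e;
  }
  // nonbonded energy of one bead against everything (assumed active)
  double nb_one(int i) const {
    double e = 0, d1 = 0, d2 = 0;
    double c2 = cutoff * cutoff;
    for (int j = 0; j < N; ++j) {
      if (j == i || !nb_active(j) || dist2(i, j) >= c2 || excluded(i, j))
        continue;
      e += pair_energy(i, j, &d1, &d2);
    }
    return e;
  }
  double bonded_of_bead(int i) const {
    double e = 0;
    for (int b : bonds_of[i]) e += bond_energy(b);
    for (int a : angles_of[i]) e += angle_energy(a);
    return e;
  }
  double rg() const {
    double mx = 0, my = 0, mz = 0;
    for (int c : core_idx) { mx += x[c]; my += y[c]; mz += z[c]; }
    mx /= ncores; my /= ncores; mz /= ncores;
    double s = 0;
    for (int c : core_idx) {
      double dx = x[c] - mx, dy = y[c] - my, dz = z[c] - mz;
      s += dx * dx + dy * dy + dz * dz;
    }
    return std::sqrt(s / ncores);
  }
  double inv_rij_sum() const {  // ordered pairs i != j
    double s = 0;
    for (size_t i = 0; i < core_idx.size(); ++i)
      for (size_t j = i + 1; j < core_idx.size(); ++j) {
        int a = core_idx[i], b = core_idx[j];
        double dx = x[a] - x[b], dy = y[a] - y[b], dz = z[a] - z[b];
        s += 2.0 / std::sqrt(dx * dx + dy * dy + dz * dz);
      }
    return s;
  }
};

static System build_system(const List& sys) {
  System S;
  NumericMatrix pos = sys["pos"];
  S.N = pos.nrow();
  S.x.resize(S.N); S.y.resize(S.N); S.z.resize(S.N);
  for (int i = 0; i < S.N; ++i) {
    S.x[i] = pos(i, 0); S.y[i] = pos(i, 1); S.z[i] = pos(i, 2);
  }
  S.type = as<std::vector<int>>(sys["type"]);
  S.core_of = as<std::vector<int>>(sys["core_of"]);
  S.tail_of = as<std::vector<int>>(sys["tail_of"]);
  S.dna_owner = as<std::vector<int>>(sys["dna_owner"]);
  S.charge = as<std::vector<double>>(sys["charge"]);
  S.diam = as<std::vector<double>>(sys["diam"]);
  S.path_pos = as<std::vector<double>>(sys["path_pos"]);
  LogicalVector fb = sys["folded_bead"];
  S.folded_bead.assign(fb.begin(), fb.end());
  S.is_nb.resize(S.N);
  for (int i = 0; i < S.N; ++i)
    S.is_nb[i] = (S.type[i] >= 1 && S.type[i] <= 4);
  for (int i = 0; i < S.N; ++i)
    if (S.type[i] == 2 || S.type[i] == 4) S.mobile.push_back(i);
  IntegerVector ci = sys["core_idx"];
  for (int i = 0; i < ci.size(); ++i) S.core_idx.push_back(ci[i] - 1);
  S.ncores = S.core_idx.size();

  IntegerMatrix bonds = sys["bonds"];
  S.bl0 = as<std::vector<double>>(sys["bond_l0"]);
  S.bk = as<std::vector<double>>(sys["bond_k"]);
  for (int b = 0; b < bonds.nrow(); ++b) {
    S.b1.push_back(bonds(b, 0) - 1);
    S.b2.push_back(bonds(b, 1) - 1);
  }
  IntegerMatrix angles = sys["angles"];
  S.ag = as<std::vector<double>>(sys["angle_g"]);
  S.at0 = as<std::vector<double>>(sys["angle_t0"]);
  for (int a = 0; a < angles.nrow(); ++a) {
    S.a1.push_back(angles(a, 0) - 1);
    S.a2.push_back(angles(a, 1) - 1);
    S.a3.push_back(angles(a, 2) - 1);
  }
  S.tw_phi = as<std::vector<double>>(sys["twist_phi"]);
  S.tw_phi0 = as<std::vector<double>>(sys["twist_phi0"]);
  S.tw_s = as<std::vector<double>>(sys["twist_s"]);

  List tl = sys["tails"];
  for (int t = 0; t < tl.size(); ++t) {
    List ti = tl[t];
    Tail T;
    IntegerVector bd = ti["beads"];
    for (int i = 0; i < bd.size(); ++i) T.beads.push_back(bd[i] - 1);
    T.anchor = as<int>(ti["anchor"]) - 1;
    T.kind = as<int>(ti["kind"]);
    T.core = as<int>(ti["core"]) - 1;
    T.acetylated = as<bool>(ti["acetylated"]);
    T.folded = as<bool>(ti["folded"]);
    NumericMatrix ap = ti["alt_pos"];
    for (int i = 0; i < ap.nrow(); ++i) {
      T.alt.push_back(ap(i, 0)); T.alt.push_back(ap(i, 1));
      T.alt.push_back(ap(i, 2));
    }
    IntegerVector bi = ti["bond_ids"], ai = ti["angle_ids"];
    for (int i = 0; i < bi.size(); ++i) T.bond_ids.push_back(bi[i] - 1);
    for (int i = 0; i < ai.size(); ++i) T.angle_ids.push_back(ai[i] - 1);
    T.l0_alt = as<double>(ti["l0_alt"]);
    T.h_alt = as<double>(ti["h_alt"]);
    T.g_alt = as<double>(ti["g_alt"]);
    S.tails.push_back(T);
  }

  List ff = sys["ff_consts"];
  S.lB = as<double>(ff["lB"]);
  S.kappa = as<double>(ff["kappa"]);
  S.kappa_dd = as<double>(ff["kappa_dd"]);
  S.lj_eps = as<double>(ff["lj_eps"]);
  S.cutoff = as<double>(ff["cutoff"]);
  S.mg_mode = as<bool>(ff["mg_mode"]);

  S.bonds_of.assign(S.N, {});
  S.angles_of.assign(S.N, {});
  for (size_t b = 0; b < S.b1.size(); ++b) {
    S.bonds_of[S.b1[b]].push_back((int)b);
    S.bonds_of[S.b2[b]].push_back((int)b);
    S.excl.insert(S.key(S.b1[b], S.b2[b]));
  }
  for (size_t a = 0; a < S.a1.size(); ++a) {
    S.angles_of[S.a1[a]].push_back((int)a);
    S.angles_of[S.a2[a]].push_back((int)a);
    S.angles_of[S.a3[a]].push_back((int)a);
    S.excl.insert(S.key(S.a1[a], S.a3[a]));
    S.excl.insert(S.key(S.a1[a], S.a2[a]));
    S.excl.insert(S.key(S.a2[a], S.a3[a]));
  }
  // rigid same-core groups (charge beads + anchors + center) never interact
  for (int i = 0; i < S.N; ++i) {
    if (S.type[i] != 1) continue;
    for (int j = i + 1; j < S.N; ++j)
      if (S.type[j] == 1 && S.core_of[j] == S.core_of[i])
        S.excl.insert(S.key(i, j));
  }
  // linker DNA is continuous with its own nucleosome's wrapped DNA: a DNA
  // bead does not interact with the charge beads of its owner core.
  // Likewise a linker histone's binding to its parent nucleosome is carried
  // by its anchor tether (the chromatosome), so LH beads do not interact
  // nonbonded with their own core's charge beads; they are free to bridge
  // their own linker DNA and other nucleosomes.
  for (int d = 0; d < S.N; ++d) {
    if (S.type[d] != 2 && S.type[d] != 4) continue;
    int own = (S.type[d] == 2) ? S.dna_owner[d] : S.core_of[d];
    for (int c = 0; c < S.N; ++c)
      if (S.type[c] == 1 && S.core_of[c] == own)
        S.excl.insert(S.key(d, c));
  }
  return S;
}

// ---------------------------------------------------------------------------
// Exposed energy evaluators

// [[Rcpp::export]]
NumericVector cf_bonded_energy(List sys) {
  System S = build_system(sys);
  for (int i = 0; i < S.N; ++i)
    if (!std::isfinite(S.x[i]) || !std::isfinite(S.y[i]) ||
        !std::isfinite(S.z[i]))
      stop("NaN/Inf coordinate at bead %d", i + 1);
  double st, be, tw;
  S.full_bonded(&st, &be, &tw);
  return NumericVector::create(_["stretch"] = st, _["bend"] = be,
                               _["twist"] = tw);
}

// [[Rcpp::export]]
NumericVector cf_nonbonded_energy(List sys) {
  System S = build_system(sys);
  double el, ev;
  S.full_nonbonded(&el, &ev);
  if (!std::isfinite(el) || !std::isfinite(ev))
    stop("overlapping beads (r = 0) in nonbonded evaluation");
  return NumericVector::create(_["electrostatic"] = el,
                               _["excluded_volume"] = ev);
}

// ---------------------------------------------------------------------------
// Trajectory sampler

static void rotate_about(double* px, double* py, double* pz,
                         const double* origin, const double* axis,
                         double angle) {
  // Rodrigues rotation of point p about axis through origin
  double vx = *px - origin[0], vy = *py - origin[1], vz = *pz - origin[2];
  double c = std::cos(angle), s = std::sin(angle);
  double kx = axis[0], ky = axis[1], kz = axis[2];
  double dot = kx * vx + ky * vy + kz * vz;
  double cx = ky * vz - kz * vy, cy = kz * vx - kx * vz, cz = kx * vy - ky * vx;
  *px = origin[0] + vx * c + cx * s + kx * dot * (1 - c);
  *py = origin[1] + vy * c + cy * s + ky * dot * (1 - c);
  *pz = origin[2] + vz * c + cz * s + kz * dot * (1 - c);
}

// cross-side nonbonded energy between moved set and the rest, via a cell
// list over the unmoved side (cells of edge = cutoff)
static double cross_energy(const System& S, const std::vector<char>& moved) {
  std::vector<int> A;
  A.reserve(S.N);
  std::unordered_map<int64_t, std::vector<int>> cells;
  double c = S.cutoff;
  auto cell_key = [&](double x, double y, double z) {
    int64_t ix = (int64_t)std::floor(x / c) + (1 << 20);
    int64_t iy = (int64_t)std::floor(y / c) + (1 << 20);
    int64_t iz = (int64_t)std::floor(z / c) + (1 << 20);
    return ix | (iy << 21) | (iz << 42);
  };
  for (int i = 0; i < S.N; ++i) {
    if (!S.nb_active(i)) continue;
    if (moved[i]) A.push_back(i);
    else cells[cell_key(S.x[i], S.y[i], S.z[i])].push_back(i);
  }
  double e = 0, d1 = 0, d2 = 0, c2 = c * c;
  for (int i : A) {
    int64_t ix = (int64_t)std::floor(S.x[i] / c) + (1 << 20);
    int64_t iy = (int64_t)std::floor(S.y[i] / c) + (1 << 20);
    int64_t iz = (int64_t)std::floor(S.z[i] / c) + (1 << 20);
    for (int64_t dx = -1; dx <= 1; ++dx)
      for (int64_t dy = -1; dy <= 1; ++dy)
        for (int64_t dz = -1; dz <= 1; ++dz) {
          auto it = cells.find((ix + dx) | ((iy + dy) << 21) |
                               ((iz + dz) << 42));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            if (S.dist2(i, j) >= c2 || S.excluded(i, j)) continue;
            e += S.pair_energy(i, j, &d1, &d2);
          }
        }
  }
  return e;
}

static double boundary_bonded(const System& S, const std::vector<char>& moved) {
  double e = 0;
  for (size_t b = 0; b < S.b1.size(); ++b)
    if (moved[S.b1[b]] != moved[S.b2[b]]) e += S.bond_energy((int)b);
  for (size_t a = 0; a < S.a1.size(); ++a) {
    char m1 = moved[S.a1[a]], m2 = moved[S.a2[a]], m3 = moved[S.a3[a]];
    if (!(m1 == m2 && m2 == m3)) e += S.angle_energy((int)a);
  }
  return e;
}

// regrow one tail with configurational bias; returns log(Wnew/Wold) in
// *logratio and the proposed coordinates; false if all trial weights vanish.
// Trial bond lengths are drawn from the full internal Boltzmann density
// p(l) dl ~ l^2 exp(-h (l - l0)^2 / 2) dl (Gaussian proposal + rejection on
// the l^2 Jacobian), so trial weights carry only the external energy and the
// sampler is exact; in zero external field W_new == W_old and every regrow
// is accepted.
static bool regrow_tail(System& S, RNG& rng, const Tail& T, int ntrial,
                        double l0, double h_stretch,
                        std::vector<double>& newpos, double* logratio) {
  int nb = (int)T.beads.size();
  newpos.assign(3 * nb, 0.0);
  double sigma = 1.0 / std::sqrt(std::max(h_stretch, 1e-9));
  double lmax = l0 + 6.0 * sigma;  // envelope for the Jacobian rejection
  // candidate interaction partners: everything within reach of the anchor
  double reach = nb * lmax + S.cutoff + 1.0;
  double reach2 = reach * reach;
  std::vector<int> near;
  for (int j = 0; j < S.N; ++j)
    if (S.nb_active(j) && S.dist2(T.anchor, j) < reach2) near.push_back(j);
  auto draw_len = [&]() {
    for (int it = 0; it < 1000; ++it) {
      double l = l0 + sigma * rng.norm();
      if (l <= 0 || l > lmax) continue;
      if (rng.unif() < (l * l) / (lmax * lmax)) return l;
    }
    return l0;
  };
  std::vector<double> oldx(nb), oldy(nb), oldz(nb);
  for (int b = 0; b < nb; ++b) {
    oldx[b] = S.x[T.beads[b]]; oldy[b] = S.y[T.beads[b]];
    oldz[b] = S.z[T.beads[b]];
  }
  // external energy of a candidate position for tail bead b: nonbonded vs
  // all beads outside this tail plus already-placed beads of this tail, and
  // the bending term closed by placing bead b (tail angles are built with
  // their outermost bead as the third vertex, so an angle contributes
  // exactly when a3 == i)
  auto ext_energy = [&](int b, double cx, double cy, double cz) -> double {
    int i = T.beads[b];
    double sx = S.x[i], sy = S.y[i], sz = S.z[i];
    S.x[i] = cx; S.y[i] = cy; S.z[i] = cz;
    double e = 0, d1 = 0, d2 = 0, c2 = S.cutoff * S.cutoff;
    for (int j : near) {
      if (j == i || S.dist2(i, j) >= c2 || S.excluded(i, j)) continue;
      if (S.tail_of[j] == S.tail_of[i]) {
        // same tail: count only already-placed beads (index < b)
        int bj = -1;
        for (int q = 0; q < nb; ++q) if (T.beads[q] == j) { bj = q; break; }
        if (bj >= b) continue;
      }
      e += S.pair_energy(i, j, &d1, &d2);
    }
    for (int a : S.angles_of[i])
      if (S.a3[a] == i) e += S.angle_energy(a);
    S.x[i] = sx; S.y[i] = sy; S.z[i] = sz;
    return e;
  };

  double logW_new = 0, logW_old = 0;
  for (int b = 0; b < nb; ++b) {
    double px, py, pz;  // previous bead (or anchor) in the NEW growth
    if (b == 0) { px = S.x[T.anchor]; py = S.y[T.anchor]; pz = S.z[T.anchor]; }
    else { px = newpos[3 * (b - 1)]; py = newpos[3 * (b - 1) + 1];
           pz = newpos[3 * (b - 1) + 2]; }
    // --- new growth: write already-placed new beads into S for energy evals
    for (int q = 0; q < b; ++q) {
      S.x[T.beads[q]] = newpos[3 * q]; S.y[T.beads[q]] = newpos[3 * q + 1];
      S.z[T.beads[q]] = newpos[3 * q + 2];
    }
    std::vector<double> w(ntrial), tx(ntrial), ty(ntrial), tz(ntrial);
    double wsum = 0;
    for (int t = 0; t < ntrial; ++t) {
      double dir[3]; rng.sphere(dir);
      double l = draw_len();
      tx[t] = px + l * dir[0]; ty[t] = py + l * dir[1]; tz[t] = pz + l * dir[2];
      double e = ext_energy(b, tx[t], ty[t], tz[t]);
      w[t] = (e < 500.0) ? std::exp(-e) : 0.0;
      wsum += w[t];
    }
    if (wsum <= 0) {  // hard overlap everywhere: restore and reject
      for (int q = 0; q < nb; ++q) {
        S.x[T.beads[q]] = oldx[q]; S.y[T.beads[q]] = oldy[q];
        S.z[T.beads[q]] = oldz[q];
      }
      return false;
    }
    double u = rng.unif() * wsum, acc = 0; int pick = ntrial - 1;
    for (int t = 0; t < ntrial; ++t) { acc += w[t]; if (u <= acc) { pick = t; break; } }
    newpos[3 * b] = tx[pick]; newpos[3 * b + 1] = ty[pick];
    newpos[3 * b + 2] = tz[pick];
    logW_new += std::log(wsum);

    // --- old retrace: restore old coords for beads 0..b-1, old bead b is
    // the first "trial", plus ntrial-1 fresh ones around the OLD previous
    for (int q = 0; q < nb; ++q) {
      S.x[T.beads[q]] = oldx[q]; S.y[T.beads[q]] = oldy[q];
      S.z[T.beads[q]] = oldz[q];
    }
    double qx, qy, qz;
    if (b == 0) { qx = S.x[T.anchor]; qy = S.y[T.anchor]; qz = S.z[T.anchor]; }
    else { qx = oldx[b - 1]; qy = oldy[b - 1]; qz = oldz[b - 1]; }
    double e_old = ext_energy(b, oldx[b], oldy[b], oldz[b]);
    double wsum_old = (e_old < 500.0) ? std::exp(-e_old) : 0.0;
    for (int t = 0; t < ntrial - 1; ++t) {
      double dir[3]; rng.sphere(dir);
      double l = draw_len();
      double cx = qx + l * dir[0], cy = qy + l * dir[1], cz = qz + l * dir[2];
      double e = ext_energy(b, cx, cy, cz);
      wsum_old += (e < 500.0) ? std::exp(-e) : 0.0;
    }
    if (wsum_old <= 0) wsum_old = 1e-300;
    logW_old += std::log(wsum_old);
  }
  // leave S with old coordinates; caller applies newpos on acceptance
  for (int q = 0; q < nb; ++q) {
    S.x[T.beads[q]] = oldx[q]; S.y[T.beads[q]] = oldy[q];
    S.z[T.beads[q]] = oldz[q];
  }
  *logratio = logW_new - logW_old;
  return true;
}

// [[Rcpp::export]]
List cf_run_trajectory(List sys, List schedule) {
  System S = build_system(sys);
  double p_pivot = as<double>(schedule["p_pivot"]);
  double p_trans = as<double>(schedule["p_translate"]);
  double p_rot = as<double>(schedule["p_rotate"]);
  double p_regrow = as<double>(schedule["p_regrow"]);
  double p_swap = as<double>(schedule["p_foldswap"]);
  double amp_pivot = as<double>(schedule["amp_pivot"]);
  double amp_trans = as<double>(schedule["amp_translate"]);
  double amp_rot = as<double>(schedule["amp_rotate"]);
  int ntrial = as<int>(schedule["regrow_trials"]);
  long total = as<double>(schedule["total_steps"]);
  long save_int = as<double>(schedule["save_interval"]);
  uint64_t seed = (uint64_t)as<double>(schedule["seed"]);
  RNG rng(seed);

  // unfolded/acetylated tail bookkeeping
  std::vector<int> acet_tails;
  for (size_t t = 0; t < S.tails.size(); ++t)
    if (S.tails[t].acetylated) acet_tails.push_back((int)t);

  double c1 = p_pivot, c2 = c1 + p_trans, c3 = c2 + p_rot, c4 = c3 + p_regrow;
  double csum = c4 + p_swap;
  if (std::abs(csum - 1.0) > 1e-9) stop("move probabilities must sum to 1");

  // fold-swap helper with correct single exchange of shared constants
  auto do_fold_swap = [&](Tail& T) {
    int nb = (int)T.beads.size();
    for (int b = 0; b < nb; ++b) {
      int i = T.beads[b];
      std::swap(S.x[i], T.alt[3 * b]);
      std::swap(S.y[i], T.alt[3 * b + 1]);
      std::swap(S.z[i], T.alt[3 * b + 2]);
    }
    double l0_cur = S.bl0[T.bond_ids[0]], h_cur = S.bk[T.bond_ids[0]];
    double g_cur = T.angle_ids.empty() ? 0.0 : S.ag[T.angle_ids[0]];
    for (int bid : T.bond_ids) { S.bl0[bid] = T.l0_alt; S.bk[bid] = T.h_alt; }
    for (int aid : T.angle_ids) S.ag[aid] = T.g_alt;
    T.l0_alt = l0_cur; T.h_alt = h_cur; T.g_alt = g_cur;
    T.folded = !T.folded;
    for (int i : T.beads) S.folded_bead[i] = T.folded;
  };

  // tail energy: bonded terms + nonbonded of its beads (0 when folded)
  auto tail_energy = [&](const Tail& T) {
    double e = 0;
    for (int bid : T.bond_ids) e += S.bond_energy(bid);
    for (int aid : T.angle_ids) e += S.angle_energy(aid);
    if (!T.folded) e += S.nb_set_energy(T.beads);
    return e;
  };

  long n_saves = total / save_int;
  List saves(n_saves);
  NumericMatrix series(n_saves, 9);
  colnames(series) = CharacterVector::create(
      "step", "stretch", "bend", "twist", "electrostatic", "excluded_volume",
      "total", "rg", "inv_rij_sum");
  LogicalMatrix folded_saves(n_saves, (int)S.tails.size());
  NumericMatrix attempts(5, 2);
  rownames(attempts) = CharacterVector::create(
      "pivot", "translate", "rotate", "regrow", "foldswap");
  colnames(attempts) = CharacterVector::create("attempts", "accepts");

  // path bead ranks for pivot cuts (cores + DNA in fiber order)
  std::vector<int> path_beads;
  for (int i = 0; i < S.N; ++i)
    if (S.type[i] == 0 || S.type[i] == 2) path_beads.push_back(i);
  std::sort(path_beads.begin(), path_beads.end(),
            [&](int a, int b) { return S.path_pos[a] < S.path_pos[b]; });

  std::vector<char> moved(S.N, 0);
  std::vector<double> sx(S.N), sy(S.N), sz(S.N);
  bool aborted = false;
  long isave = 0;

  auto metropolis = [&](double dE) {
    if (!std::isfinite(dE)) return false;
    if (dE <= 0) return true;
    return rng.unif() < std::exp(-dE);
  };

  for (long step = 1; step <= total; ++step) {
    auto do_move = [&]() {
    double u = rng.unif();
    if (u < c1) {  // ---- pivot
      attempts(0, 0) += 1;
      int cut = 1 + rng.unif_int((int)path_beads.size() - 1);
      int pb = path_beads[cut];
      double cutpos = S.path_pos[pb];
      int n_right = (int)path_beads.size() - cut - 1;
      int n_left = cut;  // path beads strictly before the pivot bead
      bool rotate_right = n_right < n_left;  // tie -> lower-index side
      std::fill(moved.begin(), moved.end(), 0);
      int nmove = 0;
      for (int i = 0; i < S.N; ++i) {
        bool m = rotate_right ? (S.path_pos[i] > cutpos)
                              : (S.path_pos[i] < cutpos);
        moved[i] = m; nmove += m;
      }
      if (nmove == 0) { return; }
      double origin[3] = {S.x[pb], S.y[pb], S.z[pb]};
      double axis[3]; rng.sphere(axis);
      double ang = rng.unif(-amp_pivot, amp_pivot);
      double e_before = cross_energy(S, moved) + boundary_bonded(S, moved);
      for (int i = 0; i < S.N; ++i) if (moved[i]) {
        sx[i] = S.x[i]; sy[i] = S.y[i]; sz[i] = S.z[i];
        rotate_about(&S.x[i], &S.y[i], &S.z[i], origin, axis, ang);
      }
      double e_after = cross_energy(S, moved) + boundary_bonded(S, moved);
      if (metropolis(e_after - e_before)) {
        attempts(0, 1) += 1;
      } else {
        for (int i = 0; i < S.N; ++i) if (moved[i]) {
          S.x[i] = sx[i]; S.y[i] = sy[i]; S.z[i] = sz[i];
        }
      }
    } else if (u < c2) {  // ---- local translate (DNA or LH bead)
      attempts(1, 0) += 1;
      if (S.mobile.empty()) return;
      int i = S.mobile[rng.unif_int((int)S.mobile.size())];
      double e_before = S.bonded_of_bead(i) + S.nb_one(i);
      double ox = S.x[i], oy = S.y[i], oz = S.z[i];
      S.x[i] += rng.unif(-amp_trans, amp_trans);
      S.y[i] += rng.unif(-amp_trans, amp_trans);
      S.z[i] += rng.unif(-amp_trans, amp_trans);
      double e_after = S.bonded_of_bead(i) + S.nb_one(i);
      if (metropolis(e_after - e_before)) {
        attempts(1, 1) += 1;
      } else {
        S.x[i] = ox; S.y[i] = oy; S.z[i] = oz;
      }
    } else if (u < c3) {  // ---- local rotate (twist register of a segment)
      attempts(2, 0) += 1;
      if (S.tw_phi.empty()) return;
      int s = rng.unif_int((int)S.tw_phi.size());
      double old = S.tw_phi[s];
      double e_before = S.twist_energy(s);
      S.tw_phi[s] += rng.unif(-amp_rot, amp_rot);
      double e_after = S.twist_energy(s);
      if (metropolis(e_after - e_before)) {
        attempts(2, 1) += 1;
      } else {
        S.tw_phi[s] = old;
      }
    } else if (u < c4) {  // ---- tail regrow (Rosenbluth), unfolded only
      attempts(3, 0) += 1;
      std::vector<int> unfolded;
      for (size_t t = 0; t < S.tails.size(); ++t)
        if (!S.tails[t].folded) unfolded.push_back((int)t);
      if (unfolded.empty()) return;
      Tail& T = S.tails[unfolded[rng.unif_int((int)unfolded.size())]];
      double l0 = S.bl0[T.bond_ids[0]], h = S.bk[T.bond_ids[0]];
      std::vector<double> np;
      double logratio;
      if (regrow_tail(S, rng, T, ntrial, l0, h, np, &logratio)) {
        bool acc = (logratio >= 0) || (rng.unif() < std::exp(logratio));
        if (acc) {
          attempts(3, 1) += 1;
          for (size_t b = 0; b < T.beads.size(); ++b) {
            S.x[T.beads[b]] = np[3 * b];
            S.y[T.beads[b]] = np[3 * b + 1];
            S.z[T.beads[b]] = np[3 * b + 2];
          }
        }
      }
    } else {  // ---- fold swap (acetylated tails only)
      attempts(4, 0) += 1;
      if (acet_tails.empty()) return;
      Tail& T = S.tails[acet_tails[rng.unif_int((int)acet_tails.size())]];
      double e_before = tail_energy(T);
      do_fold_swap(T);
      double e_after = tail_energy(T);
      if (metropolis(e_after - e_before)) {
        attempts(4, 1) += 1;
      } else {
        do_fold_swap(T);  // exact involution restores the original state
      }
    }

    };
    do_move();

    if (step % save_int == 0 && isave < n_saves) {
      double st, be, tw, el, ev;
      S.full_bonded(&st, &be, &tw);
      S.full_nonbonded(&el, &ev);
      double tot = st + be + tw + el + ev;
      NumericMatrix p(S.N, 3);
      for (int i = 0; i < S.N; ++i) {
        p(i, 0) = S.x[i]; p(i, 1) = S.y[i]; p(i, 2) = S.z[i];
      }
      saves[isave] = p;
      series(isave, 0) = (double)step;
      series(isave, 1) = st; series(isave, 2) = be; series(isave, 3) = tw;
      series(isave, 4) = el; series(isave, 5) = ev; series(isave, 6) = tot;
      series(isave, 7) = S.rg();
      series(isave, 8) = S.inv_rij_sum();
      for (size_t t = 0; t < S.tails.size(); ++t)
        folded_saves(isave, (int)t) = S.tails[t].folded;
      ++isave;
      if (!std::isfinite(tot)) { aborted = true; break; }
    }
  }

  NumericMatrix final_pos(S.N, 3);
  for (int i = 0; i < S.N; ++i) {
    final_pos(i, 0) = S.x[i]; final_pos(i, 1) = S.y[i];
    final_pos(i, 2) = S.z[i];
  }
  LogicalVector folded_final((int)S.tails.size());
  List alt_final((int)S.tails.size());
  NumericMatrix alt_consts((int)S.tails.size(), 3);
  for (size_t t = 0; t < S.tails.size(); ++t) {
    folded_final[(int)t] = S.tails[t].folded;
    int nb = (int)S.tails[t].beads.size();
    NumericMatrix ap(nb, 3);
    for (int b = 0; b < nb; ++b) {
      ap(b, 0) = S.tails[t].alt[3 * b];
      ap(b, 1) = S.tails[t].alt[3 * b + 1];
      ap(b, 2) = S.tails[t].alt[3 * b + 2];
    }
    alt_final[(int)t] = ap;
    alt_consts((int)t, 0) = S.tails[t].l0_alt;
    alt_consts((int)t, 1) = S.tails[t].h_alt;
    alt_consts((int)t, 2) = S.tails[t].g_alt;
  }
  return List::create(
      _["saves"] = saves, _["series"] = series,
      _["folded_saves"] = folded_saves, _["acceptance"] = attempts,
      _["final_pos"] = final_pos, _["final_twist"] = wrap(S.tw_phi),
      _["folded_final"] = folded_final, _["alt_final"] = alt_final,
      _["alt_consts"] = alt_consts, _["bond_l0"] = wrap(S.bl0),
      _["bond_k"] = wrap(S.bk), _["angle_g"] = wrap(S.ag),
      _["aborted"] = aborted, _["n_saved"] = (double)isave);
}

// ---------------------------------------------------------------------------
// Analysis kernels

// binary internucleosome contact matrix: cores i,j are in contact when any
// tail or charge bead of i is within `cutoff` of a tail or charge bead of j
// (folded tail beads excluded)
// [[Rcpp::export]]
IntegerMatrix cf_contact_matrix(NumericMatrix pos, IntegerVector type,
                                IntegerVector core_of,
                                LogicalVector folded_bead, int ncores,
                                double cutoff) {
  int N = pos.nrow();
  std::vector<int> use;
  for (int i = 0; i < N; ++i)
    if ((type[i] == 1 || type[i] == 3) && !folded_bead[i]) use.push_back(i);
  IntegerMatrix M(ncores, ncores);
  double c2 = cutoff * cutoff;
  for (size_t a = 0; a < use.size(); ++a) {
    int i = use[a];
    for (size_t b = a + 1; b < use.size(); ++b) {
      int j = use[b];
      int ci = core_of[i] - 1, cj = core_of[j] - 1;
      if (ci == cj) continue;
      if (M(ci, cj)) continue;
      double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1),
             dz = pos(i, 2) - pos(j, 2);
      if (dx * dx + dy * dy + dz * dz <= c2) {
        M(ci, cj) = 1; M(cj, ci) = 1;
      }
    }
  }
  return M;
}

// per-tail minimum distances to the three separate-nucleosome element
// classes (columns: core charge beads, DNA beads, tail beads); folded tails
// get NA rows; folded target tails are excluded as interaction partners
// [[Rcpp::export]]
NumericMatrix cf_tail_min_dist(NumericMatrix pos, IntegerVector type,
                               IntegerVector core_of, IntegerVector tail_of,
                               LogicalVector folded_bead, IntegerVector dna_owner,
                               int ntails, IntegerVector tail_core,
                               LogicalVector tail_folded) {
  int N = pos.nrow();
  NumericMatrix out(ntails, 3);
  std::fill(out.begin(), out.end(), R_PosInf);
  for (int t = 0; t < ntails; ++t)
    if (tail_folded[t])
      for (int e = 0; e < 3; ++e) out(t, e) = NA_REAL;
  for (int i = 0; i < N; ++i) {
    if (type[i] != 3 || folded_bead[i]) continue;
    int t = tail_of[i] - 1;
    if (t < 0 || tail_folded[t]) continue;
    int own = tail_core[t];
    for (int j = 0; j < N; ++j) {
      int cls;
      if (type[j] == 1) { cls = 0; if (core_of[j] == own) continue; }
      else if (type[j] == 2) { cls = 1; if (dna_owner[j] == own) continue; }
      else if (type[j] == 3) {
        cls = 2;
        if (folded_bead[j] || core_of[j] == own) continue;
      } else continue;
      double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1),
             dz = pos(i, 2) - pos(j, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < out(t, cls)) out(t, cls) = d;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher),
// distance of each voxel to the nearest zero (background) voxel; voxels
// outside the array are treated as foreground. Background voxels get 0.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zbuf, int n) {
  int k = 0;
  v[0] = 0;
  zbuf[0] = -1e30; zbuf[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= zbuf[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cf_sq_edt(IntegerVector arr) {
  IntegerVector dims = arr.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> D(n);
  const double INF = 1e30;
  for (size_t i = 0; i < n; ++i) D[i] = arr[i] ? INF : 0.0;
  int nmax = std::max({nx, ny, nz});
  std::vector<double> f(nmax), d(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);
  auto idx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  };
  for (int k = 0; k < nz; ++k)        // pass along x
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = D[idx(i, j, k)];
      dt1d(f, d, v, zbuf, nx);
      for (int i = 0; i < nx; ++i) D[idx(i, j, k)] = d[i];
    }
  for (int k = 0; k < nz; ++k)        // pass along y
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = D[idx(i, j, k)];
      dt1d(f, d, v, zbuf, ny);
      for (int j = 0; j < ny; ++j) D[idx(i, j, k)] = d[j];
    }
  for (int j = 0; j < ny; ++j)        // pass along z
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = D[idx(i, j, k)];
      dt1d(f, d, v, zbuf, nz);
      for (int k = 0; k < nz; ++k) D[idx(i, j, k)] = d[k];
    }
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = (D[i] >= 1e29) ? R_PosInf : D[i];
  out.attr("dim") = dims;
  return out;
}
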