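// Monte-Carlo kernels: periodic-lattice polymer (bond addition/removal/kink),
// minimal lattice-gas bulk (spin flips), two-species molecular bulk (kink,
// reptation, reservoir exchange), and exact small-system enumeration oracles.
//
// Conventions shared by every routine in this file (and mirrored by the R
// reference implementations in R/hamiltonian.R):
//  * sites are 0-based (x, y, z) wrapped into dims (Lx, Ly, Lz);
//    linear index = x + Lx*(y + Ly*z);
//  * neighbour order is +x, -x, +y, -y, +z, -z;
//  * nearest-neighbour pair sums enumerate (site, +axis) pairs, so on a
//    periodic dimension of length 2 the doubled edge is counted twice;
//  * all energies are in units of kT;
//  * the polymer chain is stored in unwrapped coordinates; when the two
//    terminal monomers are periodic images of one another (a chain spanning
//    the box with winding number 1) they share one wrapped site which is
//    counted once, so N_p = monomers - 1.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG (pcg32)

struct RNG {
  uint64_t state;
  uint64_t inc;
  RNG(uint64_t seed, uint64_t seq = 54u) {
    state = 0u; inc = (seq << 1u) | 1u;
    next(); state += seed; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double unif() { return next() * 2.3283064365386963e-10; } // / 2^32, in [0,1)
  int bounded(int n) { // uniform on 0..n-1, rejection to avoid modulo bias
    uint32_t threshold = (uint32_t)(-(uint32_t)n) % (uint32_t)n;
    for (;;) { uint32_t r = next(); if (r >= threshold) return (int)(r % (uint32_t)n); }
  }
};

// -------------------------------------------------------------------- lattice

static const int DIR[6][3] = {
  {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}
};

struct Lattice {
  int Lx, Ly, Lz, V;
  std::vector<int> nbr; // V*6
  Lattice(IntegerVector dims) {
    Lx = dims[0]; Ly = dims[1]; Lz = dims[2];
    if (Lx < 2 || Ly < 2 || Lz < 2) stop("lattice dimensions must all be >= 2");
    V = Lx * Ly * Lz;
    nbr.resize((size_t)V * 6);
    for (int z = 0; z < Lz; ++z)
      for (int y = 0; y < Ly; ++y)
        for (int x = 0; x < Lx; ++x) {
          int i = idx(x, y, z);
          for (int d = 0; d < 6; ++d)
            nbr[(size_t)i * 6 + d] =
              idx(wrap(x + DIR[d][0], Lx), wrap(y + DIR[d][1], Ly),
                  wrap(z + DIR[d][2], Lz));
        }
  }
  static int wrap(int c, int L) { c %= L; if (c < 0) c += L; return c; }
  int idx(int x, int y, int z) const { return x + Lx * (y + Ly * z); }
  int widx(int x, int y, int z) const {
    return idx(wrap(x, Lx), wrap(y, Ly), wrap(z, Lz));
  }
  int neighbour(int site, int d) const { return nbr[(size_t)site * 6 + d]; }
};

// --------------------------------------------------------------------- params

struct Params {
  double mu_p, v_p, p_kink;
  int n_max;
  double mu_b, J_bulk, J_nn;
  std::vector<double> J_int; // per polymer type (1-based type ids)
  int N_b;
  double jint(int type) const {
    if (type <= 0) return 0.0;
    if ((size_t)type > J_int.size()) return 0.0;
    return J_int[(size_t)type - 1];
  }
};

static Params read_params(List p) {
  Params q;
  q.mu_p = as<double>(p["mu_p"]);
  q.v_p = as<double>(p["v_p"]);
  q.p_kink = as<double>(p["p_kink"]);
  q.n_max = as<int>(p["n_max"]);
  q.mu_b = as<double>(p["mu_b"]);
  q.J_bulk = as<double>(p["j_bulk"]);
  q.J_nn = as<double>(p["j_nn"]);
  q.J_int = as<std::vector<double> >(p["j_int"]);
  q.N_b = as<int>(p["n_b"]);
  return q;
}

// ---------------------------------------------------------------------- state

struct Molecule {
  int sp; // 1 or 2
  std::vector<int> s; // wrapped site indices, contour order
};

struct State {
  Lattice lat;
  Params par;
  int bulk_mode; // 0 none, 1 minimal lattice gas, 2 two-species molecules

  // polymer: unwrapped coordinates, one entry per monomer
  std::vector<int> ux, uy, uz;
  std::vector<int> type;    // 1-based type id per monomer (1 if untyped)
  std::vector<int> seg;     // segment id per monomer (0-based), -1 if none
  std::vector<int> segcount, segmin, segmax;
  bool shared_ends;         // terminal monomers are periodic images
  std::vector<uint8_t> occP;   // per-site monomer count (2 only at shared end)
  std::vector<int> occT;       // per-site type id of occupying monomer (0 none)

  // minimal bulk
  std::vector<uint8_t> gas;

  // molecular bulk
  std::vector<Molecule> mols;
  std::vector<uint8_t> occ1, occ2;
  long n_reservoir;

  State(IntegerVector dims, List p, int mode)
    : lat(dims), par(read_params(p)), bulk_mode(mode), shared_ends(false),
      n_reservoir(0) {
    occP.assign(lat.V, 0); occT.assign(lat.V, 0);
    gas.assign(lat.V, 0);
    occ1.assign(lat.V, 0); occ2.assign(lat.V, 0);
  }

  int nmono() const { return (int)ux.size(); }
  int n_sites() const { return nmono() - (shared_ends ? 1 : 0); }
  int site_of(int i) const { return lat.widx(ux[i], uy[i], uz[i]); }

  double bulk1_at(int w) const {
    if (bulk_mode == 1) return (double)gas[w];
    if (bulk_mode == 2) return (double)occ1[w];
    return 0.0;
  }

  // ---- incremental polymer-site updates (site transitions are always 0<->1
  // during moves; the shared-end site never changes)
  double add_poly_site(int w, int tp) {
    double dE = 0.0;
    int c = 0;
    for (int d = 0; d < 6; ++d) c += (occP[lat.neighbour(w, d)] > 0);
    dE += -(par.mu_p + par.v_p) + par.v_p * c;
    dE += -par.jint(tp) * bulk1_at(w);
    occP[w] = 1; occT[w] = tp;
    return dE;
  }
  double remove_poly_site(int w, int tp) {
    occP[w] = 0; occT[w] = 0;
    double dE = 0.0;
    int c = 0;
    for (int d = 0; d < 6; ++d) c += (occP[lat.neighbour(w, d)] > 0);
    dE -= -(par.mu_p + par.v_p) + par.v_p * c;
    dE -= -par.jint(tp) * bulk1_at(w);
    return dE;
  }

  // ---- incremental molecular-bulk updates
  double add_bulk_site(int sp, int w) {
    double dE = 0.0;
    dE += -par.J_bulk * (sp == 1 ? (double)occ2[w] : (double)occ1[w]);
    int c = 0;
    for (int d = 0; d < 6; ++d) {
      int n = lat.neighbour(w, d);
      c += occ1[n] + occ2[n];
    }
    dE += -par.J_nn * c;
    if (sp == 1 && occP[w] > 0) dE += -par.jint(occT[w]);
    (sp == 1 ? occ1 : occ2)[w] = 1;
    return dE;
  }
  double remove_bulk_site(int sp, int w) {
    (sp == 1 ? occ1 : occ2)[w] = 0;
    double dE = 0.0;
    dE -= -par.J_bulk * (sp == 1 ? (double)occ2[w] : (double)occ1[w]);
    int c = 0;
    for (int d = 0; d < 6; ++d) {
      int n = lat.neighbour(w, d);
      c += occ1[n] + occ2[n];
    }
    dE -= -par.J_nn * c;
    if (sp == 1 && occP[w] > 0) dE -= -par.jint(occT[w]);
    return dE;
  }
  void set_bulk_site(int sp, int w, uint8_t v) { (sp == 1 ? occ1 : occ2)[w] = v; }

  // ---- full-energy recomputation (used at measurement time; the move loop
  // only ever uses local deltas, so frames carry no floating drift)
  long poly_contacts() const {
    long c = 0;
    for (int w = 0; w < lat.V; ++w)
      if (occP[w] > 0)
        for (int d = 0; d < 6; d += 2) // +x, +y, +z
          c += (occP[lat.neighbour(w, d)] > 0);
    return c;
  }
  double e_poly() const {
    return -(par.mu_p + par.v_p) * n_sites() + par.v_p * poly_contacts();
  }
  double e_bulk() const {
    double e = 0.0;
    if (bulk_mode == 1) {
      long n = 0, c = 0;
      for (int w = 0; w < lat.V; ++w) {
        if (!gas[w]) continue;
        ++n;
        for (int d = 0; d < 6; d += 2) c += gas[lat.neighbour(w, d)];
      }
      e = -par.mu_b * n - par.J_bulk * c;
    } else if (bulk_mode == 2) {
      long on = 0, c = 0;
      for (int w = 0; w < lat.V; ++w) {
        on += (long)occ1[w] * occ2[w];
        int nw = occ1[w] + occ2[w];
        if (nw)
          for (int d = 0; d < 6; d += 2) {
            int n2 = lat.neighbour(w, d);
            c += (long)nw * (occ1[n2] + occ2[n2]);
          }
      }
      e = -par.mu_b * (double)mols.size() - par.J_bulk * on - par.J_nn * c;
    }
    return e;
  }
  double e_int() const {
    double e = 0.0;
    for (int w = 0; w < lat.V; ++w)
      if (occP[w] > 0) e += -par.jint(occT[w]) * bulk1_at(w);
    return e;
  }
};

// ------------------------------------------------- polymer move (BFACF-style)

static const int ORTH[3][4] = { // orthogonal direction indices by bond axis
  {2,3,4,5}, {0,1,4,5}, {0,1,2,3}
};

struct PolyCounters { long att[3], acc[3]; };

// printed proposal schedule
static inline double p_add(int np, double pk) {
  return (np + 2.0) / (2.0 * (1.0 + np)) * (1.0 - pk);
}
static inline double p_rem(int np, double pk) {
  return np / (2.0 * (1.0 + np)) * (1.0 - pk);
}

static void attempt_polymer(State& st, RNG& rng, PolyCounters& ct) {
  int N = st.nmono();
  if (N < 2) return;
  int nb = N - 1;
  int np = st.n_sites();
  double pk = st.par.p_kink;

  // draw a move class from the proposal schedule
  double u = rng.unif();
  int cls; // 0 add, 1 rem, 2 kink
  double pa = p_add(np, pk), pr = p_rem(np, pk);
  if (u < pa) cls = 0; else if (u < pa + pr) cls = 1; else cls = 2;
  ct.att[cls]++;

  int s = rng.bounded(nb);
  int bx = st.ux[s+1] - st.ux[s], by = st.uy[s+1] - st.uy[s],
      bz = st.uz[s+1] - st.uz[s];
  int axis = (bx != 0) ? 0 : (by != 0) ? 1 : 2;
  int d = ORTH[axis][rng.bounded(4)];
  int dx = DIR[d][0], dy = DIR[d][1], dz = DIR[d][2];

  bool iL = (s > 0) &&
    (st.ux[s] + dx == st.ux[s-1] && st.uy[s] + dy == st.uy[s-1] &&
     st.uz[s] + dz == st.uz[s-1]);
  bool iR = (s + 2 < N) &&
    (st.ux[s+1] + dx == st.ux[s+2] && st.uy[s+1] + dy == st.uy[s+2] &&
     st.uz[s+1] + dz == st.uz[s+2]);
  int geo = (iL && iR) ? 1 : (!iL && !iR) ? 0 : 2;
  if (geo != cls) return; // class/geometry mismatch -> rejection

  if (cls == 0) { // addition of two monomers between s and s+1
    if (np + 2 >= st.par.n_max) return;
    int t1x = st.ux[s] + dx, t1y = st.uy[s] + dy, t1z = st.uz[s] + dz;
    int t2x = st.ux[s+1] + dx, t2y = st.uy[s+1] + dy, t2z = st.uz[s+1] + dz;
    int w1 = st.lat.widx(t1x, t1y, t1z), w2 = st.lat.widx(t2x, t2y, t2z);
    if (st.occP[w1] || st.occP[w2]) return;
    int tp1 = st.type[s], tp2 = st.type[s+1];
    int g1 = st.seg[s], g2 = st.seg[s+1];
    if (g1 >= 0) { // segment windows
      if (g1 == g2) { if (st.segcount[g1] + 2 > st.segmax[g1]) return; }
      else if (st.segcount[g1] + 1 > st.segmax[g1] ||
               st.segcount[g2] + 1 > st.segmax[g2]) return;
    }
    double dE = st.add_poly_site(w1, tp1);
    dE += st.add_poly_site(w2, tp2);
    double H = (p_rem(np + 2, pk) * nb) / (p_add(np, pk) * (nb + 2));
    if (rng.unif() < std::fmin(1.0, H * std::exp(-dE))) {
      st.ux.insert(st.ux.begin() + s + 1, {t1x, t2x});
      st.uy.insert(st.uy.begin() + s + 1, {t1y, t2y});
      st.uz.insert(st.uz.begin() + s + 1, {t1z, t2z});
      st.type.insert(st.type.begin() + s + 1, {tp1, tp2});
      st.seg.insert(st.seg.begin() + s + 1, {g1, g2});
      if (g1 >= 0) { st.segcount[g1]++; st.segcount[g2]++; }
      ct.acc[0]++;
    } else {
      st.remove_poly_site(w2, tp2);
      st.remove_poly_site(w1, tp1);
    }
  } else if (cls == 1) { // removal of monomers s and s+1
    // geo == 1 guarantees both flanks exist, so s,s+1 are interior
    int w1 = st.site_of(s), w2 = st.site_of(s + 1);
    int tp1 = st.type[s], tp2 = st.type[s+1];
    int g1 = st.seg[s], g2 = st.seg[s+1];
    if (g1 >= 0) {
      if (g1 == g2) { if (st.segcount[g1] - 2 < st.segmin[g1]) return; }
      else if (st.segcount[g1] - 1 < st.segmin[g1] ||
               st.segcount[g2] - 1 < st.segmin[g2]) return;
    }
    double dE = st.remove_poly_site(w2, tp2);
    dE += st.remove_poly_site(w1, tp1);
    double H = (p_add(np - 2, pk) * nb) / (p_rem(np, pk) * (nb - 2));
    if (rng.unif() < std::fmin(1.0, H * std::exp(-dE))) {
      st.ux.erase(st.ux.begin() + s, st.ux.begin() + s + 2);
      st.uy.erase(st.uy.begin() + s, st.uy.begin() + s + 2);
      st.uz.erase(st.uz.begin() + s, st.uz.begin() + s + 2);
      st.type.erase(st.type.begin() + s, st.type.begin() + s + 2);
      st.seg.erase(st.seg.begin() + s, st.seg.begin() + s + 2);
      if (g1 >= 0) { st.segcount[g1]--; st.segcount[g2]--; }
      ct.acc[1]++;
    } else {
      st.add_poly_site(w1, tp1);
      st.add_poly_site(w2, tp2);
    }
  } else { // kink: re-thread the corner, moving one interior monomer
    int m, tx, ty, tz;
    if (iL) { m = s; tx = st.ux[s+1] + dx; ty = st.uy[s+1] + dy; tz = st.uz[s+1] + dz; }
    else    { m = s + 1; tx = st.ux[s] + dx; ty = st.uy[s] + dy; tz = st.uz[s] + dz; }
    int wt = st.lat.widx(tx, ty, tz);
    if (st.occP[wt]) return;
    int wm = st.site_of(m), tp = st.type[m];
    double dE = st.remove_poly_site(wm, tp);
    dE += st.add_poly_site(wt, tp);
    if (rng.unif() < std::fmin(1.0, std::exp(-dE))) {
      st.ux[m] = tx; st.uy[m] = ty; st.uz[m] = tz;
      ct.acc[2]++;
    } else {
      st.remove_poly_site(wt, tp);
      st.add_poly_site(wm, tp);
    }
  }
}

// -------------------------------------------------------- minimal bulk moves

static void attempt_flip(State& st, RNG& rng, long& att, long& acc) {
  int w = rng.bounded(st.lat.V);
  ++att;
  int c = 0;
  for (int d = 0; d < 6; ++d) c += st.gas[st.lat.neighbour(w, d)];
  double eon = -st.par.mu_b - st.par.J_bulk * c -
    (st.occP[w] > 0 ? st.par.jint(st.occT[w]) : 0.0);
  double dE = st.gas[w] ? -eon : eon;
  if (rng.unif() < std::fmin(1.0, std::exp(-dE))) {
    st.gas[w] ^= 1;
    ++acc;
  }
}

// ------------------------------------------------------ molecular bulk moves

struct BulkCounters { long att[3], acc[3]; }; // kink, reptation, exchange

static void attempt_mol_kink(State& st, RNG& rng, BulkCounters& ct) {
  ct.att[0]++;
  if (st.mols.empty()) return;
  Molecule& m = st.mols[rng.bounded((int)st.mols.size())];
  int Nb = (int)m.s.size();
  if (Nb < 2) return;
  int s = rng.bounded(Nb - 1);
  int a = m.s[s], b = m.s[s+1];
  int axis = -1, dfwd = -1;
  for (int d = 0; d < 6; ++d)
    if (st.lat.neighbour(a, d) == b) { dfwd = d; break; }
  axis = dfwd / 2;
  int d = ORTH[axis][rng.bounded(4)];
  int t1 = st.lat.neighbour(a, d), t2 = st.lat.neighbour(b, d);
  bool iL = (s > 0) && (t1 == m.s[s-1]);
  bool iR = (s + 2 < Nb) && (t2 == m.s[s+2]);
  if (!(iL ^ iR)) return; // only length-preserving kinks for bulk molecules
  int mi = iL ? s : s + 1;
  int wt = iL ? t2 : t1;
  std::vector<uint8_t>& occ = (m.sp == 1 ? st.occ1 : st.occ2);
  if (occ[wt]) return;
  int wm = m.s[mi];
  double dE = st.remove_bulk_site(m.sp, wm);
  dE += st.add_bulk_site(m.sp, wt);
  if (rng.unif() < std::fmin(1.0, std::exp(-dE))) {
    m.s[mi] = wt;
    ct.acc[0]++;
  } else {
    st.set_bulk_site(m.sp, wt, 0);
    st.set_bulk_site(m.sp, wm, 1);
  }
}

static void attempt_reptation(State& st, RNG& rng, BulkCounters& ct) {
  ct.att[1]++;
  if (st.mols.empty()) return;
  int mi = rng.bounded((int)st.mols.size());
  Molecule& m = st.mols[mi];
  int Nb = (int)m.s.size();
  if (Nb < 2) return;
  bool from_front = rng.unif() < 0.5;
  int wrem = from_front ? m.s.front() : m.s.back();
  int head = from_front ? m.s.back() : m.s.front();
  std::vector<uint8_t>& occ = (m.sp == 1 ? st.occ1 : st.occ2);
  double dE = st.remove_bulk_site(m.sp, wrem);
  int cand[6], nf = 0;
  for (int d = 0; d < 6; ++d) {
    int w = st.lat.neighbour(head, d);
    if (!occ[w]) cand[nf++] = w;
  }
  if (nf == 0) { st.set_bulk_site(m.sp, wrem, 1); return; }
  int wt = cand[rng.bounded(nf)];
  dE += st.add_bulk_site(m.sp, wt);
  // reverse move grows next to the monomer that becomes the other end
  int rhead = from_front ? m.s[1] : m.s[Nb - 2];
  st.set_bulk_site(m.sp, wt, 0);
  int nr = 0;
  for (int d = 0; d < 6; ++d) nr += !occ[st.lat.neighbour(rhead, d)];
  st.set_bulk_site(m.sp, wt, 1);
  double H = (double)nf / (double)nr;
  if (rng.unif() < std::fmin(1.0, H * std::exp(-dE))) {
    if (from_front) { m.s.erase(m.s.begin()); m.s.push_back(wt); }
    else { m.s.pop_back(); m.s.insert(m.s.begin(), wt); }
    ct.acc[1]++;
  } else {
    st.set_bulk_site(m.sp, wt, 0);
    st.set_bulk_site(m.sp, wrem, 1);
  }
}

static void attempt_exchange(State& st, RNG& rng, BulkCounters& ct) {
  ct.att[2]++;
  long Nr = st.n_reservoir, Ns = (long)st.mols.size();
  double lam_plus = (double)Nr / (double)(Nr + Ns + 1);
  if (rng.unif() < lam_plus) { // insertion of an ideal-chain configuration
    int sp = 1 + rng.bounded(2);
    int Nb = st.par.N_b;
    std::vector<int> walk(Nb);
    walk[0] = rng.bounded(st.lat.V);
    for (int k = 1; k < Nb; ++k)
      walk[k] = st.lat.neighbour(walk[k-1], rng.bounded(6));
    std::vector<uint8_t>& occ = (sp == 1 ? st.occ1 : st.occ2);
    double dE = -st.par.mu_b;
    int placed = 0;
    bool ok = true;
    for (int k = 0; k < Nb; ++k) {
      if (occ[walk[k]]) { ok = false; break; }
      dE += st.add_bulk_site(sp, walk[k]);
      ++placed;
    }
    if (ok && rng.unif() < std::fmin(1.0, std::exp(-dE))) {
      Molecule m; m.sp = sp; m.s = walk;
      st.mols.push_back(m);
      st.n_reservoir--;
      ct.acc[2]++;
    } else {
      for (int k = placed - 1; k >= 0; --k) st.set_bulk_site(sp, walk[k], 0);
    }
  } else { // removal of a uniformly chosen system molecule
    if (Ns == 0) return;
    int mi = rng.bounded((int)Ns);
    Molecule& m = st.mols[mi];
    double dE = st.par.mu_b;
    for (int k = (int)m.s.size() - 1; k >= 0; --k)
      dE += st.remove_bulk_site(m.sp, m.s[k]);
    if (rng.unif() < std::fmin(1.0, std::exp(-dE))) {
      st.mols.erase(st.mols.begin() + mi);
      st.n_reservoir++;
      ct.acc[2]++;
    } else {
      for (size_t k = 0; k < m.s.size(); ++k) st.set_bulk_site(m.sp, m.s[k], 1);
    }
  }
}

// ----------------------------------------------------------- state <-> R glue

static void load_polymer(State& st, IntegerMatrix chain, IntegerVector types,
                         IntegerVector seg_id, IntegerVector seg_min,
                         IntegerVector seg_max) {
  int N = chain.nrow();
  if (N < 2) stop("chain needs at least 2 monomers");
  st.ux.resize(N); st.uy.resize(N); st.uz.resize(N);
  st.type.assign(N, 1); st.seg.assign(N, -1);
  for (int i = 0; i < N; ++i) {
    st.ux[i] = chain(i, 0); st.uy[i] = chain(i, 1); st.uz[i] = chain(i, 2);
    if (i > 0) {
      int d = std::abs(st.ux[i]-st.ux[i-1]) + std::abs(st.uy[i]-st.uy[i-1]) +
              std::abs(st.uz[i]-st.uz[i-1]);
      if (d != 1) stop("chain bonds must be unit steps (unwrapped coordinates)");
    }
  }
  if (types.size() == N) for (int i = 0; i < N; ++i) st.type[i] = types[i];
  if (seg_id.size() == N) {
    for (int i = 0; i < N; ++i) st.seg[i] = seg_id[i];
    int ns = seg_min.size();
    st.segmin.assign(seg_min.begin(), seg_min.end());
    st.segmax.assign(seg_max.begin(), seg_max.end());
    st.segcount.assign(ns, 0);
  }
  st.shared_ends = (st.site_of(0) == st.site_of(N - 1)) &&
    !(st.ux[0] == st.ux[N-1] && st.uy[0] == st.uy[N-1] && st.uz[0] == st.uz[N-1]);
  for (int i = 0; i < N; ++i) {
    if (st.shared_ends && i == N - 1) break; // image monomer: site already set
    int w = st.site_of(i);
    if (st.occP[w]) stop("polymer self-intersection in initial chain");
    st.occP[w] = 1; st.occT[w] = st.type[i];
  }
  if (st.shared_ends) st.occP[st.site_of(0)] = 2;
  // count monomers per segment (the image monomer is not counted twice)
  if (!st.segcount.empty())
    for (int i = 0; i < st.nmono() - (st.shared_ends ? 1 : 0); ++i)
      if (st.seg[i] >= 0) st.segcount[st.seg[i]]++;
}

static IntegerMatrix chain_matrix(const State& st) {
  int N = st.nmono();
  IntegerMatrix m(N, 3);
  for (int i = 0; i < N; ++i) {
    m(i,0) = st.ux[i]; m(i,1) = st.uy[i]; m(i,2) = st.uz[i];
  }
  return m;
}

static void load_molecules(State& st, List mol_list) {
  for (int i = 0; i < mol_list.size(); ++i) {
    List ml = mol_list[i];
    Molecule m;
    m.sp = as<int>(ml["species"]);
    m.s = as<std::vector<int> >(ml["sites"]);
    std::vector<uint8_t>& occ = (m.sp == 1 ? st.occ1 : st.occ2);
    for (size_t k = 0; k < m.s.size(); ++k) {
      if (occ[m.s[k]]) stop("same-species collision in initial bulk state");
      occ[m.s[k]] = 1;
    }
    st.mols.push_back(m);
  }
}

static List molecules_list(const State& st) {
  List out(st.mols.size());
  for (size_t i = 0; i < st.mols.size(); ++i) {
    out[i] = List::create(_["species"] = st.mols[i].sp,
                          _["sites"] = IntegerVector(st.mols[i].s.begin(),
                                                     st.mols[i].s.end()));
  }
  return out;
}

// radius of gyration over the distinct monomers, unwrapped coordinates
static double rgyr(const State& st) {
  int n = st.n_sites();
  double mx = 0, my = 0, mz = 0;
  for (int i = 0; i < n; ++i) { mx += st.ux[i]; my += st.uy[i]; mz += st.uz[i]; }
  mx /= n; my /= n; mz /= n;
  double s2 = 0;
  for (int i = 0; i < n; ++i) {
    double dx = st.ux[i] - mx, dy = st.uy[i] - my, dz = st.uz[i] - mz;
    s2 += dx*dx + dy*dy + dz*dz;
  }
  return std::sqrt(s2 / n);
}

// ------------------------------------------------------------------- runner

// [[Rcpp::export]]
List cpp_run(IntegerVector dims, IntegerMatrix chain, IntegerVector types,
             IntegerVector seg_id, IntegerVector seg_min, IntegerVector seg_max,
             List params, int bulk_mode, IntegerVector gas_init, List mol_init,
             double n_reservoir, int sweeps, int equil, int meas_every,
             bool collect_frames, double seed) {
  State st(dims, params, bulk_mode);
  load_polymer(st, chain, types, seg_id, seg_min, seg_max);
  if (bulk_mode == 1)
    for (int i = 0; i < gas_init.size(); ++i) st.gas[gas_init[i]] = 1;
  if (bulk_mode == 2) { load_molecules(st, mol_init); st.n_reservoir = (long)n_reservoir; }
  RNG rng((uint64_t)seed);

  int ntypes = 1;
  for (int i = 0; i < st.nmono(); ++i) ntypes = std::max(ntypes, st.type[i]);

  PolyCounters pct = {{0,0,0},{0,0,0}};
  BulkCounters bct = {{0,0,0},{0,0,0}};
  long flip_att = 0, flip_acc = 0;

  std::vector<double> o_sweep, o_np, o_rg, o_contacts, o_epoly, o_ebulk, o_eint,
    o_bulk_total, o_dens_on, o_dens_off, o_dens1_on, o_dens1_off, o_dens2_on,
    o_dens2_off, o_ns1, o_ns2, o_nr;
  std::vector<std::vector<double> > o_occ1(ntypes), o_occ2(ntypes);
  std::vector<Rcpp::List> frame_list; // Rcpp objects keep their SEXPs protected

  int total = sweeps + equil;
  for (int sw = 1; sw <= total; ++sw) {
    int natt = st.n_sites();
    for (int a = 0; a < natt; ++a) attempt_polymer(st, rng, pct);
    if (bulk_mode == 1) {
      for (int a = 0; a < st.lat.V; ++a) attempt_flip(st, rng, flip_att, flip_acc);
    } else if (bulk_mode == 2) {
      long nb_att = (long)st.mols.size() * st.par.N_b;
      for (long a = 0; a < nb_att; ++a) {
        if (rng.unif() < 0.5) attempt_mol_kink(st, rng, bct);
        else attempt_reptation(st, rng, bct);
      }
      attempt_exchange(st, rng, bct);
    }
    if (sw > equil && ((sw - equil) % meas_every == 0)) {
      int np = st.n_sites();
      o_sweep.push_back(sw - equil);
      o_np.push_back(np);
      o_rg.push_back(rgyr(st));
      o_contacts.push_back((double)st.poly_contacts());
      o_epoly.push_back(st.e_poly());
      o_ebulk.push_back(st.e_bulk());
      o_eint.push_back(st.e_int());
      // bulk density on polymer sites vs everywhere else (site fractions of
      // s1+s2, or of the lattice-gas occupancy in minimal mode), per species
      double on1 = 0, on2 = 0, tot1 = 0, tot2 = 0;
      for (int w = 0; w < st.lat.V; ++w) {
        double b1 = (bulk_mode == 2) ? (double)st.occ1[w] : (double)st.gas[w];
        double b2 = (bulk_mode == 2) ? (double)st.occ2[w] : 0.0;
        tot1 += b1; tot2 += b2;
        if (st.occP[w] > 0) { on1 += b1; on2 += b2; }
      }
      int far = st.lat.V - np;
      o_bulk_total.push_back(tot1 + tot2);
      o_dens_on.push_back(np > 0 ? (on1 + on2) / np : NA_REAL);
      o_dens_off.push_back(far > 0 ? (tot1 + tot2 - on1 - on2) / far
                                   : NA_REAL);
      o_dens1_on.push_back(np > 0 ? on1 / np : NA_REAL);
      o_dens1_off.push_back(far > 0 ? (tot1 - on1) / far : NA_REAL);
      o_dens2_on.push_back(np > 0 ? on2 / np : NA_REAL);
      o_dens2_off.push_back(far > 0 ? (tot2 - on2) / far : NA_REAL);
      // per-type occupancy fractions at monomer sites
      std::vector<double> cnt(ntypes, 0), s1(ntypes, 0), s2(ntypes, 0);
      for (int i = 0; i < np; ++i) {
        int tp = st.type[i] - 1, w = st.site_of(i);
        cnt[tp] += 1;
        double b1 = (bulk_mode == 2) ? st.occ1[w] : (double)st.gas[w];
        double b2 = (bulk_mode == 2) ? (double)st.occ2[w] : 0.0;
        s1[tp] += b1; s2[tp] += b2;
      }
      for (int t = 0; t < ntypes; ++t) {
        o_occ1[t].push_back(cnt[t] > 0 ? s1[t]/cnt[t] : NA_REAL);
        o_occ2[t].push_back(cnt[t] > 0 ? s2[t]/cnt[t] : NA_REAL);
      }
      long ns1 = 0, ns2 = 0;
      for (size_t i = 0; i < st.mols.size(); ++i)
        (st.mols[i].sp == 1 ? ns1 : ns2)++;
      o_ns1.push_back((double)ns1);
      o_ns2.push_back((double)ns2);
      o_nr.push_back((double)st.n_reservoir);
      if (collect_frames) {
        std::vector<int> g1, g2;
        for (int w = 0; w < st.lat.V; ++w) {
          if (bulk_mode == 1) { if (st.gas[w]) g1.push_back(w); }
          else if (bulk_mode == 2) {
            if (st.occ1[w]) g1.push_back(w);
            if (st.occ2[w]) g2.push_back(w);
          }
        }
        frame_list.push_back(List::create(
          _["sweep"] = sw - equil,
          _["chain"] = chain_matrix(st),
          _["types"] = IntegerVector(st.type.begin(), st.type.end()),
          _["bulk1"] = IntegerVector(g1.begin(), g1.end()),
          _["bulk2"] = IntegerVector(g2.begin(), g2.end())));
      }
    }
    if (sw % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  int nf = (int)o_sweep.size();
  List obs = List::create(
    _["sweep"] = wrap(o_sweep), _["n_p"] = wrap(o_np), _["rg"] = wrap(o_rg),
    _["contacts"] = wrap(o_contacts), _["e_poly"] = wrap(o_epoly),
    _["e_bulk"] = wrap(o_ebulk), _["e_int"] = wrap(o_eint),
    _["bulk_total"] = wrap(o_bulk_total), _["dens_on"] = wrap(o_dens_on),
    _["dens_off"] = wrap(o_dens_off), _["dens1_on"] = wrap(o_dens1_on),
    _["dens1_off"] = wrap(o_dens1_off), _["dens2_on"] = wrap(o_dens2_on),
    _["dens2_off"] = wrap(o_dens2_off), _["n_s1"] = wrap(o_ns1),
    _["n_s2"] = wrap(o_ns2), _["n_r"] = wrap(o_nr));
  NumericMatrix m1(nf, ntypes), m2(nf, ntypes);
  for (int t = 0; t < ntypes; ++t)
    for (int f = 0; f < nf; ++f) { m1(f,t) = o_occ1[t][f]; m2(f,t) = o_occ2[t][f]; }

  List accept = List::create(
    _["poly_att"] = NumericVector::create(pct.att[0], pct.att[1], pct.att[2]),
    _["poly_acc"] = NumericVector::create(pct.acc[0], pct.acc[1], pct.acc[2]),
    _["flip_att"] = (double)flip_att, _["flip_acc"] = (double)flip_acc,
    _["bulk_att"] = NumericVector::create(bct.att[0], bct.att[1], bct.att[2]),
    _["bulk_acc"] = NumericVector::create(bct.acc[0], bct.acc[1], bct.acc[2]));

  std::vector<int> gfin1, gfin2;
  for (int w = 0; w < st.lat.V; ++w) {
    if (bulk_mode == 1 && st.gas[w]) gfin1.push_back(w);
  }
  List fin = List::create(
    _["chain"] = chain_matrix(st),
    _["types"] = IntegerVector(st.type.begin(), st.type.end()),
    _["gas"] = IntegerVector(gfin1.begin(), gfin1.end()),
    _["molecules"] = molecules_list(st),
    _["n_reservoir"] = (double)st.n_reservoir,
    _["seg"] = IntegerVector(st.seg.begin(), st.seg.end()),
    _["seg_counts"] = IntegerVector(st.segcount.begin(), st.segcount.end()));

  return List::create(_["obs"] = obs, _["occ1"] = m1, _["occ2"] = m2,
                      _["accept"] = accept, _["final"] = fin,
                      _["frames"] = List(frame_list.begin(), frame_list.end()));
}

// --------------------------------------------------- exported state energies

// [[Rcpp::export]]
NumericVector cpp_state_energies(IntegerVector dims, IntegerMatrix chain,
                                 IntegerVector types, List params,
                                 int bulk_mode, IntegerVector gas_sites,
                                 List mol_list) {
  State st(dims, params, bulk_mode);
  IntegerVector none(0);
  load_polymer(st, chain, types, none, none, none);
  if (bulk_mode == 1)
    for (int i = 0; i < gas_sites.size(); ++i) st.gas[gas_sites[i]] = 1;
  if (bulk_mode == 2) load_molecules(st, mol_list);
  return NumericVector::create(_["e_poly"] = st.e_poly(),
                               _["e_bulk"] = st.e_bulk(),
                               _["e_int"] = st.e_int(),
                               _["contacts"] = (double)st.poly_contacts(),
                               _["n_p"] = (double)st.n_sites());
}

// [[Rcpp::export]]
List cpp_classify_move(IntegerVector dims, IntegerMatrix chain, int bond,
                       IntegerVector dir) {
  Lattice lat(dims);
  int N = chain.nrow();
  if (bond < 0 || bond >= N - 1) stop("bond index out of range");
  int bx = chain(bond+1,0)-chain(bond,0), by = chain(bond+1,1)-chain(bond,1),
      bz = chain(bond+1,2)-chain(bond,2);
  int dx = dir[0], dy = dir[1], dz = dir[2];
  if (std::abs(dx)+std::abs(dy)+std::abs(dz) != 1 || bx*dx+by*dy+bz*dz != 0)
    stop("direction must be a unit vector orthogonal to the bond");
  bool iL = (bond > 0) &&
    (chain(bond,0)+dx == chain(bond-1,0) && chain(bond,1)+dy == chain(bond-1,1) &&
     chain(bond,2)+dz == chain(bond-1,2));
  bool iR = (bond + 2 < N) &&
    (chain(bond+1,0)+dx == chain(bond+2,0) && chain(bond+1,1)+dy == chain(bond+2,1) &&
     chain(bond+1,2)+dz == chain(bond+2,2));
  std::string kind = (iL && iR) ? "removal" : (!iL && !iR) ? "addition" : "kink";
  int mover = NA_INTEGER;
  if (kind == "kink") mover = iL ? bond : bond + 1;
  return List::create(_["kind"] = kind, _["mover"] = mover);
}

// -------------------------------------------------------------- enumeration

struct WalkEnum {
  Lattice lat;
  double mu_p, v_p;
  int n_max;
  long cap;
  int tx, ty, tz; // unwrapped target
  int wstart;
  bool spanning;  // target wraps onto the start site
  std::vector<uint8_t> occ;
  long visited, count;
  double Z, sumE, sumC, sumN;
  WalkEnum(IntegerVector dims) : lat(dims), visited(0), count(0),
    Z(0), sumE(0), sumC(0), sumN(0) { occ.assign(lat.V, 0); }

  void dfs(int x, int y, int z, int ns, long contacts) {
    if (++visited > cap) stop("enumeration state cap exceeded");
    for (int d = 0; d < 6; ++d) {
      int nx = x + DIR[d][0], ny = y + DIR[d][1], nz = z + DIR[d][2];
      int w = lat.widx(nx, ny, nz);
      if (nx == tx && ny == ty && nz == tz) {
        // reached the pinned terminus
        long c; int n2;
        if (spanning) { c = contacts; n2 = ns; }
        else {
          if (occ[w]) continue;
          long dc = 0;
          for (int dd = 0; dd < 6; ++dd) dc += (occ[lat.neighbour(w, dd)] > 0);
          c = contacts + dc; n2 = ns + 1;
        }
        if (n2 < n_max) {
          double E = -(mu_p + v_p) * n2 + v_p * c;
          double wgt = std::exp(-E);
          Z += wgt; sumE += E * wgt; sumC += c * wgt; sumN += n2 * wgt;
          ++count;
        }
        continue;
      }
      if (occ[w]) continue;
      if (ns + 1 >= n_max) continue; // no room for another occupied site
      // distance prune: remaining new sites must cover the unwrapped gap
      int dist = std::abs(tx-nx) + std::abs(ty-ny) + std::abs(tz-nz);
      int budget = (n_max - 1) - (ns + 1) + (spanning ? 1 : 0);
      if (dist > budget) continue;
      long dc = 0;
      for (int dd = 0; dd < 6; ++dd) dc += (occ[lat.neighbour(w, dd)] > 0);
      occ[w] = 1;
      dfs(nx, ny, nz, ns + 1, contacts + dc);
      occ[w] = 0;
    }
  }
};

// [[Rcpp::export]]
List cpp_enumerate_walks(IntegerVector dims, IntegerVector start,
                         IntegerVector target, int n_max, double mu_p,
                         double v_p, double cap) {
  WalkEnum en(dims);
  en.mu_p = mu_p; en.v_p = v_p; en.n_max = n_max; en.cap = (long)cap;
  en.tx = target[0]; en.ty = target[1]; en.tz = target[2];
  int sx = start[0], sy = start[1], sz = start[2];
  en.wstart = en.lat.widx(sx, sy, sz);
  int wt = en.lat.widx(en.tx, en.ty, en.tz);
  bool same_unwrapped = (sx == en.tx && sy == en.ty && sz == en.tz);
  en.spanning = (wt == en.wstart) && !same_unwrapped;
  if (same_unwrapped) stop("start and target must be distinct");
  en.occ[en.wstart] = 1;
  en.dfs(sx, sy, sz, 1, 0);
  if (en.count == 0)
    return List::create(_["n_states"] = 0.0, _["Z"] = 0.0);
  return List::create(
    _["n_states"] = (double)en.count,
    _["Z"] = en.Z,
    _["mean_energy"] = en.sumE / en.Z,
    _["mean_contacts"] = en.sumC / en.Z,
    _["mean_n_p"] = en.sumN / en.Z,
    _["states_visited"] = (double)en.visited);
}

// [[Rcpp::export]]
List cpp_enumerate_gas(IntegerVector dims, double mu_b, double J_bulk,
                       IntegerVector poly_sites, NumericVector j_int_site) {
  Lattice lat(dims);
  int V = lat.V;
  if (V > 24) stop("lattice-gas enumeration limited to 24 sites");
  // +axis pair list (doubled edges on length-2 dimensions are counted twice)
  std::vector<std::pair<int,int> > pairs;
  for (int w = 0; w < V; ++w)
    for (int d = 0; d < 6; d += 2) pairs.push_back(std::make_pair(w, lat.neighbour(w, d)));
  std::vector<double> field(V, 0.0); // -J_int at polymer-occupied sites
  for (int i = 0; i < poly_sites.size(); ++i)
    field[poly_sites[i]] = j_int_site[i];
  double Z = 0, sumN = 0, sumE = 0;
  uint32_t nstates = 1u << V;
  for (uint32_t m = 0; m < nstates; ++m) {
    int n = __builtin_popcount(m);
    double E = -mu_b * n;
    for (size_t p = 0; p < pairs.size(); ++p)
      if ((m >> pairs[p].first & 1u) && (m >> pairs[p].second & 1u)) E += -J_bulk;
    for (int w = 0; w < V; ++w)
      if (m >> w & 1u) E += -field[w];
    double wgt = std::exp(-E);
    Z += wgt; sumN += n * wgt; sumE += E * wgt;
  }
  return List::create(
    _["n_states"] = (double)nstates,
    _["Z"] = Z,
    _["mean_n"] = sumN / Z,
    _["mean_occupancy"] = sumN / Z / V,
    _["mean_energy"] = sumE / Z);
}
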