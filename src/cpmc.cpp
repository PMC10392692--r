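// Constant-pH Metropolis Monte Carlo of coarse-grained bead-spring
// peptides in a slit: Debye-Hueckel screened electrostatics, Lennard-Jones
// excluded volume, harmonic bonds, hard walls at z = 0 and z = Lz,
// periodic boundaries in x and y, and titration swap moves.
//
// Energies are in kT, lengths in Angstrom.  The engine owns a small
// deterministic RNG (splitmix64-seeded xoshiro256**) so runs are
// bit-reproducible for a fixed seed, independent of R's RNG state.
//
// Performance notes: the Lennard-Jones part is short-ranged and, when a
// cutoff is configured, evaluated through a linked-cell list; screened
// electrostatics loops over a maintained index of charged beads only
// (most beads of the model are neutral).  With both cutoffs at zero the
// engine falls back to exact all-pairs sums.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ---
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  double unif(double a, double b) { return a + (b - a) * unif(); }
  int integer(int n) { return (int)(unif() * n) % n; }  // 0..n-1
  void unit_vector(double v[3]) {                       // Marsaglia (1972)
    double a, b, s2;
    do {
      a = unif(-1.0, 1.0); b = unif(-1.0, 1.0);
      s2 = a * a + b * b;
    } while (s2 >= 1.0);
    double f = 2.0 * std::sqrt(1.0 - s2);
    v[0] = a * f; v[1] = b * f; v[2] = 1.0 - 2.0 * s2;
  }
};

// ------------------------------------------------------------- system ---
struct System {
  int n;
  std::vector<double> x, y, z, sigma, q;
  std::vector<int> chain;            // chain id per bead
  std::vector<int> cstart, clen;     // per chain
  std::vector<char> grafted;         // per chain: first bead anchored
  int free_chain;
  std::vector<int> site_bead;
  std::vector<char> site_acid, site_prot;
  std::vector<double> site_pka;
  double Lxy, Lz, lB, debye, eps_lj, bond_k, bond_req, pH;
  double rc_el2, rc_lj2;             // squared cutoffs; <= 0: none
  double invL;

  // charged-bead index (electrostatics loops over this only)
  std::vector<int> charged;
  std::vector<int> charged_pos;      // -1 if neutral

  // linked-cell list for the LJ part
  bool use_cells = false;
  int ncx = 0, ncz = 0;
  double csx = 0, csz = 0;
  std::vector<int> chead, cnxt, cprv, cell_of;

  double mi(double d) const {
    // minimum image in x/y for arbitrary separations
    d -= Lxy * std::nearbyint(d * invL);
    return d;
  }
  bool anchored(int i) const {
    int c = chain[i];
    return grafted[c] && i == cstart[c];
  }
  bool bonded(int i, int j) const {
    return chain[i] == chain[j] && (i - j == 1 || j - i == 1);
  }
  bool in_slit(double zz) const { return zz > 0.0 && zz < Lz; }

  // ---- charge bookkeeping ----
  void set_charges_from_sites() {
    q.assign(n, 0.0);
    for (size_t s = 0; s < site_bead.size(); ++s) {
      double qs = site_acid[s] ? (site_prot[s] ? 0.0 : -1.0)
                               : (site_prot[s] ? 1.0 : 0.0);
      q[site_bead[s]] += qs;
    }
    charged.clear();
    charged_pos.assign(n, -1);
    for (int i = 0; i < n; ++i)
      if (q[i] != 0.0) {
        charged_pos[i] = (int)charged.size();
        charged.push_back(i);
      }
  }
  void update_charge(int b, double dq) {
    bool was = q[b] != 0.0;
    q[b] += dq;
    bool is = q[b] != 0.0;
    if (was && !is) {
      int p = charged_pos[b], last = charged.back();
      charged[p] = last; charged_pos[last] = p;
      charged.pop_back(); charged_pos[b] = -1;
    } else if (!was && is) {
      charged_pos[b] = (int)charged.size();
      charged.push_back(b);
    }
  }

  // ---- cell list ----
  int cell_index(double xx, double yy, double zz) const {
    int cx = (int)std::floor(xx / csx); cx %= ncx; if (cx < 0) cx += ncx;
    int cy = (int)std::floor(yy / csx); cy %= ncx; if (cy < 0) cy += ncx;
    int cz = (int)std::floor(zz / csz);
    if (cz < 0) cz = 0; if (cz >= ncz) cz = ncz - 1;
    return (cz * ncx + cy) * ncx + cx;
  }
  void build_cells() {
    double rc = std::sqrt(rc_lj2);
    ncx = (int)std::floor(Lxy / rc);
    ncz = (int)std::floor(Lz / rc);
    use_cells = rc_lj2 > 0 && ncx >= 3 && ncz >= 3;
    if (!use_cells) return;
    csx = Lxy / ncx; csz = Lz / ncz;
    chead.assign(ncx * ncx * ncz, -1);
    cnxt.assign(n, -1); cprv.assign(n, -1); cell_of.assign(n, -1);
    for (int i = 0; i < n; ++i) cell_insert(i);
  }
  void cell_insert(int i) {
    int c = cell_index(x[i], y[i], z[i]);
    cell_of[i] = c;
    cnxt[i] = chead[c]; cprv[i] = -1;
    if (chead[c] >= 0) cprv[chead[c]] = i;
    chead[c] = i;
  }
  void cell_remove(int i) {
    int c = cell_of[i];
    if (cprv[i] >= 0) cnxt[cprv[i]] = cnxt[i]; else chead[c] = cnxt[i];
    if (cnxt[i] >= 0) cprv[cnxt[i]] = cprv[i];
  }
  void cell_update(int i) {
    int c = cell_index(x[i], y[i], z[i]);
    if (c == cell_of[i]) return;
    cell_remove(i);
    cell_insert(i);
  }

  double lj_of_r2(double r2, double s) const {
    double sr2 = s * s / r2, sr6 = sr2 * sr2 * sr2;
    return 4.0 * eps_lj * (sr6 * sr6 - sr6);
  }
  double el_of_r2(double r2, double qq) const {
    double r = std::sqrt(r2);
    double e = (debye > 0.0) ? std::exp(-r / debye) : 1.0;
    return lB * qq * e / r;
  }

  // LJ energy of bead i at (xi, yi, zi) against beads outside `skip`
  // (skip may be null); bonded neighbours excluded
  double lj_env(int i, double xi, double yi, double zi,
                const std::vector<char> *skip) const {
    double u = 0.0;
    if (use_cells) {
      int cx = (int)std::floor(xi / csx); cx %= ncx; if (cx < 0) cx += ncx;
      int cy = (int)std::floor(yi / csx); cy %= ncx; if (cy < 0) cy += ncx;
      int cz = (int)std::floor(zi / csz);
      if (cz < 0) cz = 0; if (cz >= ncz) cz = ncz - 1;
      for (int dz = -1; dz <= 1; ++dz) {
        int zc = cz + dz;
        if (zc < 0 || zc >= ncz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yc = (cy + dy + ncx) % ncx;
          for (int dx = -1; dx <= 1; ++dx) {
            int xc = (cx + dx + ncx) % ncx;
            for (int j = chead[(zc * ncx + yc) * ncx + xc]; j >= 0;
                 j = cnxt[j]) {
              if (j == i || (skip && (*skip)[j]) || bonded(i, j)) continue;
              double ddx = mi(xi - x[j]), ddy = mi(yi - y[j]),
                     ddz = zi - z[j];
              double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if (r2 >= rc_lj2) continue;
              if (r2 <= 0.0) return 1e30;
              u += lj_of_r2(r2, 0.5 * (sigma[i] + sigma[j]));
            }
          }
        }
      }
    } else {
      for (int j = 0; j < n; ++j) {
        if (j == i || (skip && (*skip)[j]) || bonded(i, j)) continue;
        double ddx = mi(xi - x[j]), ddy = mi(yi - y[j]), ddz = zi - z[j];
        double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
        if (rc_lj2 > 0.0 && r2 >= rc_lj2) continue;
        if (r2 <= 0.0) return 1e30;
        u += lj_of_r2(r2, 0.5 * (sigma[i] + sigma[j]));
      }
    }
    return u;
  }

  // screened-Coulomb energy of charge qi at (xi, yi, zi) vs charged beads
  double el_env(int i, double qi, double xi, double yi, double zi,
                const std::vector<char> *skip) const {
    if (qi == 0.0) return 0.0;
    double u = 0.0;
    for (size_t k = 0; k < charged.size(); ++k) {
      int j = charged[k];
      if (j == i || (skip && (*skip)[j]) || bonded(i, j)) continue;
      double ddx = mi(xi - x[j]), ddy = mi(yi - y[j]), ddz = zi - z[j];
      double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (rc_el2 > 0.0 && r2 >= rc_el2) continue;
      if (r2 <= 0.0) return 1e30;
      u += el_of_r2(r2, qi * q[j]);
    }
    return u;
  }

  double bond_u(double r) const {
    double d = r - bond_req;
    return 0.5 * bond_k * d * d;
  }
  double bond_env(int i, double xi, double yi, double zi) const {
    double u = 0.0;
    int c = chain[i];
    if (i > cstart[c]) {
      double dx = mi(xi - x[i - 1]), dy = mi(yi - y[i - 1]),
             dz = zi - z[i - 1];
      u += bond_u(std::sqrt(dx * dx + dy * dy + dz * dz));
    }
    if (i < cstart[c] + clen[c] - 1) {
      double dx = mi(xi - x[i + 1]), dy = mi(yi - y[i + 1]),
             dz = zi - z[i + 1];
      u += bond_u(std::sqrt(dx * dx + dy * dy + dz * dz));
    }
    return u;
  }

  // exact all-pairs total energy (drift oracle; also used at startup)
  double total_energy() const {
    double u = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = mi(x[i] - x[j]), dy = mi(y[i] - y[j]),
               dz = z[i] - z[j];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (bonded(i, j)) {
          u += bond_u(std::sqrt(r2));
          continue;
        }
        if (r2 <= 0.0) return 1e30;
        if (rc_lj2 <= 0.0 || r2 < rc_lj2)
          u += lj_of_r2(r2, 0.5 * (sigma[i] + sigma[j]));
        double qq = q[i] * q[j];
        if (qq != 0.0 && (rc_el2 <= 0.0 || r2 < rc_el2))
          u += el_of_r2(r2, qq);
      }
    }
    return u;
  }
};

static System read_system(List sys) {
  System S;
  NumericMatrix pos = sys["pos"];
  S.n = pos.nrow();
  S.x.resize(S.n); S.y.resize(S.n); S.z.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    S.x[i] = pos(i, 0); S.y[i] = pos(i, 1); S.z[i] = pos(i, 2);
  }
  S.sigma = as<std::vector<double>>(sys["sigma"]);
  S.chain = as<std::vector<int>>(sys["chain"]);
  S.cstart = as<std::vector<int>>(sys["chain_start"]);
  S.clen = as<std::vector<int>>(sys["chain_len"]);
  LogicalVector g = sys["grafted"];
  for (int i = 0; i < g.size(); ++i) S.grafted.push_back(g[i]);
  S.free_chain = as<int>(sys["free_chain"]);
  S.site_bead = as<std::vector<int>>(sys["site_bead"]);
  LogicalVector a = sys["site_acid"], pr = sys["site_prot"];
  for (int i = 0; i < a.size(); ++i) {
    S.site_acid.push_back(a[i]);
    S.site_prot.push_back(pr[i]);
  }
  S.site_pka = as<std::vector<double>>(sys["site_pka"]);
  S.Lxy = as<double>(sys["Lxy"]);   S.Lz = as<double>(sys["Lz"]);
  S.lB = as<double>(sys["lB"]);     S.debye = as<double>(sys["debye"]);
  S.eps_lj = as<double>(sys["eps_lj"]);
  S.bond_k = as<double>(sys["bond_k"]);
  S.bond_req = as<double>(sys["bond_req"]);
  S.pH = as<double>(sys["pH"]);
  double rc_el = as<double>(sys["cutoff_el"]);
  double rc_lj = as<double>(sys["cutoff_lj"]);
  S.rc_el2 = rc_el > 0 ? rc_el * rc_el : 0.0;
  S.rc_lj2 = rc_lj > 0 ? rc_lj * rc_lj : 0.0;
  S.invL = 1.0 / S.Lxy;
  S.set_charges_from_sites();
  S.build_cells();
  return S;
}

// nonbonded pair energy between two explicit coordinates (cutoffs applied)
static double pair_full(const System &S, int i, int j, double xi,
                        double yi, double zi, double xj, double yj,
                        double zj) {
  double dx = S.mi(xi - xj), dy = S.mi(yi - yj), dz = zi - zj;
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 <= 0.0) return 1e30;
  double u = 0.0;
  if (S.rc_lj2 <= 0.0 || r2 < S.rc_lj2)
    u += S.lj_of_r2(r2, 0.5 * (S.sigma[i] + S.sigma[j]));
  double qq = S.q[i] * S.q[j];
  if (qq != 0.0 && (S.rc_el2 <= 0.0 || r2 < S.rc_el2))
    u += S.el_of_r2(r2, qq);
  return u;
}

// rigid motion preserves true distances inside the moved set, but not
// minimum-image distances once a chain spans more than half the box, so
// internal nonbonded pairs must still enter the energy difference
static double set_internal_u(const System &S, const std::vector<int> &idx,
                             const std::vector<double> &sx,
                             const std::vector<double> &sy,
                             const std::vector<double> &sz) {
  double u = 0.0;
  for (size_t k = 0; k + 1 < idx.size(); ++k)
    for (size_t l = k + 1; l < idx.size(); ++l) {
      if (S.bonded(idx[k], idx[l])) continue;
      u += pair_full(S, idx[k], idx[l], sx[k], sy[k], sz[k],
                     sx[l], sy[l], sz[l]);
    }
  return u;
}

static void rodrigues(const double a[3], double c, double s,
                      double &vx, double &vy, double &vz) {
  double dot = a[0] * vx + a[1] * vy + a[2] * vz;
  double cx = a[1] * vz - a[2] * vy;
  double cy = a[2] * vx - a[0] * vz;
  double cz = a[0] * vy - a[1] * vx;
  double nx = vx * c + cx * s + a[0] * dot * (1 - c);
  double ny = vy * c + cy * s + a[1] * dot * (1 - c);
  double nz = vz * c + cz * s + a[2] * dot * (1 - c);
  vx = nx; vy = ny; vz = nz;
}

// ------------------------------------------------------------- engine ---
// [[Rcpp::export(name = ".cpmc_engine")]]
List cpmc_engine(List sys, int n_equil, int n_prod, int sample_every,
                 double seed, List mv) {
  System S = read_system(sys);
  double d_bead = as<double>(mv["d_bead"]);
  double d_chain = as<double>(mv["d_chain"]);
  double d_rot = as<double>(mv["d_rot"]);
  bool do_bead = as<bool>(mv["do_bead"]);
  bool do_chain = as<bool>(mv["do_chain"]);
  bool do_pivot = as<bool>(mv["do_pivot"]);
  bool do_tit = as<bool>(mv["do_titration"]);
  bool tune = as<bool>(mv["tune"]);
  double p_tele = as<double>(mv["p_teleport"]);

  Xoshiro rng((uint64_t)seed);
  const double LN10 = 2.302585092994046;
  int n_sites = (int)S.site_bead.size();
  int n_chain = (int)S.cstart.size();

  std::vector<int> mobile;
  for (int i = 0; i < S.n; ++i)
    if (!S.anchored(i)) mobile.push_back(i);
  int n_mobile = (int)mobile.size();

  double E = S.total_energy();
  double drift_max = 0.0;

  long att[4] = {0, 0, 0, 0}, acc[4] = {0, 0, 0, 0};
  long tune_att[3] = {0, 0, 0}, tune_acc[3] = {0, 0, 0};

  int n_samples_max = (sample_every > 0) ? (n_prod / sample_every + 1) : 0;
  NumericMatrix samples(std::max(n_samples_max, 1), 8);
  std::vector<double> site_prot_sum(n_sites, 0.0);
  int n_samp = 0;
  long prot_samples = 0;

  std::vector<char> inset(S.n, 0);
  std::vector<int> set_idx;
  std::vector<double> tx, ty, tz;

  for (int sweep = 0; sweep < n_equil + n_prod; ++sweep) {
    bool prod = sweep >= n_equil;

    // (a) single-bead translations
    if (do_bead && n_mobile > 0) {
      for (int m = 0; m < n_mobile; ++m) {
        int i = mobile[rng.integer(n_mobile)];
        double nx = S.x[i] + rng.unif(-d_bead, d_bead);
        double ny = S.y[i] + rng.unif(-d_bead, d_bead);
        double nz = S.z[i] + rng.unif(-d_bead, d_bead);
        ++att[0]; if (!prod) ++tune_att[0];
        if (!S.in_slit(nz)) continue;
        double du = S.lj_env(i, nx, ny, nz, nullptr)
                  - S.lj_env(i, S.x[i], S.y[i], S.z[i], nullptr)
                  + S.el_env(i, S.q[i], nx, ny, nz, nullptr)
                  - S.el_env(i, S.q[i], S.x[i], S.y[i], S.z[i], nullptr)
                  + S.bond_env(i, nx, ny, nz)
                  - S.bond_env(i, S.x[i], S.y[i], S.z[i]);
        if (du <= 0.0 || rng.unif() < std::exp(-du)) {
          S.x[i] = nx; S.y[i] = ny; S.z[i] = nz;
          if (S.use_cells) S.cell_update(i);
          E += du; ++acc[0]; if (!prod) ++tune_acc[0];
        }
      }
    }

    // (b) rigid chain translation/rotation (rotation about the anchor
    //     for grafted chains, about the centre of mass otherwise)
    if (do_chain) {
      for (int c = 0; c < n_chain; ++c) {
        if (S.clen[c] < 1) continue;
        if (S.grafted[c] && S.clen[c] < 2) continue;
        ++att[1]; if (!prod) ++tune_att[1];
        set_idx.clear(); tx.clear(); ty.clear(); tz.clear();
        int i0 = S.cstart[c], L = S.clen[c];
        double px = 0, py = 0, pz = 0;
        if (S.grafted[c]) { px = S.x[i0]; py = S.y[i0]; pz = S.z[i0]; }
        else {
          for (int i = i0; i < i0 + L; ++i) {
            px += S.x[i]; py += S.y[i]; pz += S.z[i];
          }
          px /= L; py /= L; pz /= L;
        }
        double axis[3]; rng.unit_vector(axis);
        double ang = rng.unif(-d_rot, d_rot);
        double ca = std::cos(ang), sa = std::sin(ang);
        double sx = 0, sy = 0, sz = 0;
        if (!S.grafted[c]) {
          if (rng.unif() < p_tele) {
            // symmetric global re-placement: uniform target for the mass
            // centre anywhere in the slit (surface/bulk exchange for
            // strongly adsorbed chains)
            sx = rng.unif(0.0, S.Lxy) - px;
            sy = rng.unif(0.0, S.Lxy) - py;
            sz = rng.unif(0.0, S.Lz) - pz;
          } else {
            sx = rng.unif(-d_chain, d_chain);
            sy = rng.unif(-d_chain, d_chain);
            sz = rng.unif(-d_chain, d_chain);
          }
        }
        bool ok = true;
        int first = S.grafted[c] ? i0 + 1 : i0;   // anchor stays put
        for (int i = first; i < i0 + L; ++i) {
          double vx = S.x[i] - px, vy = S.y[i] - py, vz = S.z[i] - pz;
          rodrigues(axis, ca, sa, vx, vy, vz);
          double zz = pz + vz + sz;
          if (!S.in_slit(zz)) { ok = false; break; }
          set_idx.push_back(i);
          tx.push_back(px + vx + sx); ty.push_back(py + vy + sy);
          tz.push_back(zz);
        }
        if (!ok) continue;
        for (size_t k = 0; k < set_idx.size(); ++k) inset[set_idx[k]] = 1;
        double du = 0.0;
        std::vector<double> ox(set_idx.size()), oy(set_idx.size()),
            oz(set_idx.size());
        for (size_t k = 0; k < set_idx.size(); ++k) {
          int i = set_idx[k];
          ox[k] = S.x[i]; oy[k] = S.y[i]; oz[k] = S.z[i];
          du += S.lj_env(i, tx[k], ty[k], tz[k], &inset)
              - S.lj_env(i, S.x[i], S.y[i], S.z[i], &inset)
              + S.el_env(i, S.q[i], tx[k], ty[k], tz[k], &inset)
              - S.el_env(i, S.q[i], S.x[i], S.y[i], S.z[i], &inset);
        }
        du += set_internal_u(S, set_idx, tx, ty, tz)
            - set_internal_u(S, set_idx, ox, oy, oz);
        if (du <= 0.0 || rng.unif() < std::exp(-du)) {
          for (size_t k = 0; k < set_idx.size(); ++k) {
            int i = set_idx[k];
            S.x[i] = tx[k]; S.y[i] = ty[k]; S.z[i] = tz[k];
            if (S.use_cells) S.cell_update(i);
          }
          E += du; ++acc[1]; if (!prod) ++tune_acc[1];
        }
        for (size_t k = 0; k < set_idx.size(); ++k) inset[set_idx[k]] = 0;
      }
    }

    // (c) pivot rotations around randomly selected bonds
    if (do_pivot) {
      for (int m = 0; m < n_chain; ++m) {
        int c = rng.integer(n_chain);
        int L = S.clen[c];
        if (L < 3) continue;
        ++att[2]; if (!prod) ++tune_att[2];
        int i0 = S.cstart[c];
        int jp = i0 + rng.integer(L - 1);   // pivot bead; distal part moves
        double px = S.x[jp], py = S.y[jp], pz = S.z[jp];
        double axis[3]; rng.unit_vector(axis);
        double ang = rng.unif(-d_rot, d_rot);
        double ca = std::cos(ang), sa = std::sin(ang);
        set_idx.clear(); tx.clear(); ty.clear(); tz.clear();
        bool ok = true;
        for (int i = jp + 1; i < i0 + L; ++i) {
          double vx = S.x[i] - px, vy = S.y[i] - py, vz = S.z[i] - pz;
          rodrigues(axis, ca, sa, vx, vy, vz);
          double zz = pz + vz;
          if (!S.in_slit(zz)) { ok = false; break; }
          set_idx.push_back(i);
          tx.push_back(px + vx); ty.push_back(py + vy); tz.push_back(zz);
        }
        if (!ok || set_idx.empty()) continue;
        for (size_t k = 0; k < set_idx.size(); ++k) inset[set_idx[k]] = 1;
        double du = 0.0;
        std::vector<double> ox(set_idx.size()), oy(set_idx.size()),
            oz(set_idx.size());
        for (size_t k = 0; k < set_idx.size(); ++k) {
          int i = set_idx[k];
          ox[k] = S.x[i]; oy[k] = S.y[i]; oz[k] = S.z[i];
          du += S.lj_env(i, tx[k], ty[k], tz[k], &inset)
              - S.lj_env(i, S.x[i], S.y[i], S.z[i], &inset)
              + S.el_env(i, S.q[i], tx[k], ty[k], tz[k], &inset)
              - S.el_env(i, S.q[i], S.x[i], S.y[i], S.z[i], &inset);
        }
        du += set_internal_u(S, set_idx, tx, ty, tz)
            - set_internal_u(S, set_idx, ox, oy, oz);
        if (du <= 0.0 || rng.unif() < std::exp(-du)) {
          for (size_t k = 0; k < set_idx.size(); ++k) {
            int i = set_idx[k];
            S.x[i] = tx[k]; S.y[i] = ty[k]; S.z[i] = tz[k];
            if (S.use_cells) S.cell_update(i);
          }
          E += du; ++acc[2]; if (!prod) ++tune_acc[2];
        }
        for (size_t k = 0; k < set_idx.size(); ++k) inset[set_idx[k]] = 0;
      }
    }

    // (d) titration swap moves: Metropolis on
    //     dU = dq * phi + s * ln(10) * (pH - pKa), s = +1 protonation
    if (do_tit && n_sites > 0) {
      for (int m = 0; m < n_sites; ++m) {
        int s = rng.integer(n_sites);
        int b = S.site_bead[s];
        bool protonate = !S.site_prot[s];
        double dq = protonate ? +1.0 : -1.0;
        ++att[3];
        double phi = S.el_env(b, 1.0, S.x[b], S.y[b], S.z[b], nullptr);
        double sgn = protonate ? +1.0 : -1.0;
        double du = dq * phi + sgn * LN10 * (S.pH - S.site_pka[s]);
        if (du <= 0.0 || rng.unif() < std::exp(-du)) {
          S.site_prot[s] = !S.site_prot[s];
          S.update_charge(b, dq);
          E += dq * phi;   // running energy tracks configurational terms
          ++acc[3];
        }
      }
    }

    // step-size tuning during equilibration, frozen afterwards.  The
    // rigid-translation step is left untouched: its acceptance is set by
    // the adsorption free energy, not the step size, and shrinking it
    // would suppress exchange between surface and bulk.
    if (tune && !prod && (sweep + 1) % 100 == 0) {
      double *steps[3] = {&d_bead, &d_chain, &d_rot};
      double caps[3] = {S.Lxy / 4.0, S.Lxy / 2.0, M_PI};
      for (int k = 0; k < 3; ++k) {
        if (k == 1) continue;
        if (tune_att[k] < 50) continue;
        double a2 = (double)tune_acc[k] / (double)tune_att[k];
        if (a2 < 0.30) *steps[k] *= 0.8;
        else if (a2 > 0.50) *steps[k] *= 1.25;
        if (*steps[k] > caps[k]) *steps[k] = caps[k];
        if (*steps[k] < 0.05) *steps[k] = 0.05;
        tune_att[k] = tune_acc[k] = 0;
      }
    }

    // sampling during production
    if (prod && sample_every > 0 &&
        (sweep - n_equil) % sample_every == 0 && n_samp < n_samples_max) {
      int fc = S.free_chain;
      double zcm = NA_REAL, mux = 0, muy = 0, muz = 0, qf = 0;
      if (fc >= 0) {
        int i0 = S.cstart[fc], L = S.clen[fc];
        double cx = 0, cy = 0, cz = 0;
        for (int i = i0; i < i0 + L; ++i) {
          cx += S.x[i]; cy += S.y[i]; cz += S.z[i];
        }
        cx /= L; cy /= L; cz /= L;
        zcm = cz;
        for (int i = i0; i < i0 + L; ++i) {
          qf += S.q[i];
          mux += S.q[i] * (S.x[i] - cx);
          muy += S.q[i] * (S.y[i] - cy);
          muz += S.q[i] * (S.z[i] - cz);
        }
      }
      double qt = 0; int ng = 0;
      for (int c = 0; c < n_chain; ++c) {
        if (!S.grafted[c]) continue;
        ++ng;
        for (int i = S.cstart[c]; i < S.cstart[c] + S.clen[c]; ++i)
          qt += S.q[i];
      }
      if (ng > 0) qt /= ng;
      if (n_samp % 20 == 0) {   // periodic from-scratch drift check
        double Efull = S.total_energy();
        double d = std::fabs(Efull - E);
        if (d > drift_max) drift_max = d;
        E = Efull;
      }
      samples(n_samp, 0) = sweep - n_equil;
      samples(n_samp, 1) = zcm;
      samples(n_samp, 2) = mux; samples(n_samp, 3) = muy;
      samples(n_samp, 4) = muz;
      samples(n_samp, 5) = qf;
      samples(n_samp, 6) = (ng > 0) ? qt : NA_REAL;
      samples(n_samp, 7) = E;
      for (int s2 = 0; s2 < n_sites; ++s2)
        site_prot_sum[s2] += S.site_prot[s2] ? 1.0 : 0.0;
      ++prot_samples;
      ++n_samp;
    }
    if ((sweep & 255) == 0) Rcpp::checkUserInterrupt();
  }

  {
    double Efull = S.total_energy();
    double d = std::fabs(Efull - E);
    if (d > drift_max) drift_max = d;
    E = Efull;
  }

  NumericMatrix out_samples(n_samp, 8);
  for (int i = 0; i < n_samp; ++i)
    for (int j = 0; j < 8; ++j) out_samples(i, j) = samples(i, j);
  colnames(out_samples) =
      CharacterVector::create("sweep", "z_cm", "mux", "muy", "muz",
                              "q_free", "q_tails", "energy");
  NumericMatrix fpos(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    fpos(i, 0) = S.x[i]; fpos(i, 1) = S.y[i]; fpos(i, 2) = S.z[i];
  }
  NumericVector fprot(n_sites);
  for (int s = 0; s < n_sites; ++s)
    fprot[s] = prot_samples > 0 ? site_prot_sum[s] / prot_samples
                                : (S.site_prot[s] ? 1.0 : 0.0);
  LogicalVector prot_now(n_sites);
  for (int s = 0; s < n_sites; ++s) prot_now[s] = (bool)S.site_prot[s];

  DataFrame stats = DataFrame::create(
      _["move"] = CharacterVector::create("bead", "chain", "pivot",
                                          "titration"),
      _["attempts"] = NumericVector::create(att[0], att[1], att[2], att[3]),
      _["accepts"] = NumericVector::create(acc[0], acc[1], acc[2], acc[3]));

  return List::create(
      _["samples"] = out_samples, _["site_frac_prot"] = fprot,
      _["site_prot_final"] = prot_now, _["move_stats"] = stats,
      _["energy"] = E, _["drift_max"] = drift_max, _["pos"] = fpos,
      _["steps"] = NumericVector::create(_["d_bead"] = d_bead,
                                         _["d_chain"] = d_chain,
                                         _["d_rot"] = d_rot));
}

// total energy of a configuration (exported for bookkeeping tests)
// [[Rcpp::export(name = ".cpmc_total_energy")]]
double cpmc_total_energy(List sys) {
  System S = read_system(sys);
  return S.total_energy();
}
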