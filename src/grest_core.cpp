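// Core kernels for the gREST toy simulator: per-term energies, scaled
// potential / forces, Metropolis MC sweeps, and BAOAB Langevin steps.
// The packed system layout is produced by .pack_system() on the R side:
//   bonds      (nb x 4):  i  j  kf r0
//   angles     (na x 5):  i  j  k  kf th0
//   dihedrals  (nd x 7):  i  j  k  l  K  n  delta
//   restraints (nr x 5):  i  kf x0 y0 z0
//   pairs      (np x 5):  i  j  eps sig qq
// indices 0-based.  Exponent vectors eb/ea/ed/er/ev/ee give the scaling
// exponent k/l per term (0 => unscaled); the factor applied is s^exponent
// with s = beta_m / beta_0.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Sys {
  int n;
  NumericMatrix bonds, angles, dihedrals, restr, pairs;
  NumericVector eb, ea, ed, er, ev, ee;
};

Sys unpack(const List& sys) {
  Sys s;
  s.n = as<int>(sys["n_atoms"]);
  s.bonds = as<NumericMatrix>(sys["bonds"]);
  s.angles = as<NumericMatrix>(sys["angles"]);
  s.dihedrals = as<NumericMatrix>(sys["dihedrals"]);
  s.restr = as<NumericMatrix>(sys["restraints"]);
  s.pairs = as<NumericMatrix>(sys["pairs"]);
  s.eb = as<NumericVector>(sys["eb"]);
  s.ea = as<NumericVector>(sys["ea"]);
  s.ed = as<NumericVector>(sys["ed"]);
  s.er = as<NumericVector>(sys["er"]);
  s.ev = as<NumericVector>(sys["ev"]);
  s.ee = as<NumericVector>(sys["ee"]);
  return s;
}

inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
inline double vdot(const double* a, const double* b) {
  return a[0]*b[0] + a[1]*b[1] + a[2]*b[2];
}
inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1]*b[2] - a[2]*b[1];
  out[1] = a[2]*b[0] - a[0]*b[2];
  out[2] = a[0]*b[1] - a[1]*b[0];
}
inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }

// --- per-term energies (and optional force accumulation with factor w) ---

double bond_term(const double* x, const double* row, double w, double* f) {
  int i = (int)row[0], j = (int)row[1];
  double kf = row[2], r0 = row[3], d[3];
  vsub(x + 3*i, x + 3*j, d);
  double r = vnorm(d);
  double e = 0.5 * kf * (r - r0) * (r - r0);
  if (f) {
    double c = -w * kf * (r - r0) / std::max(r, 1e-12);
    for (int q = 0; q < 3; ++q) { f[3*i+q] += c * d[q]; f[3*j+q] -= c * d[q]; }
  }
  return e;
}

double restraint_term(const double* x, const double* row, double w, double* f) {
  int i = (int)row[0];
  double kf = row[1];
  double d[3] = { x[3*i] - row[2], x[3*i+1] - row[3], x[3*i+2] - row[4] };
  double e = 0.5 * kf * vdot(d, d);
  if (f) for (int q = 0; q < 3; ++q) f[3*i+q] -= w * kf * d[q];
  return e;
}

double angle_term(const double* x, const double* row, double w, double* f) {
  int i = (int)row[0], j = (int)row[1], k = (int)row[2];
  double kf = row[3], th0 = row[4];
  double u[3], v[3];
  vsub(x + 3*i, x + 3*j, u);
  vsub(x + 3*k, x + 3*j, v);
  double lu = vnorm(u), lv = vnorm(v);
  double c = vdot(u, v) / (lu * lv);
  c = std::max(-1.0, std::min(1.0, c));
  double th = std::acos(c);
  double e = 0.5 * kf * (th - th0) * (th - th0);
  if (f) {
    double s = std::sqrt(std::max(1.0 - c * c, 1e-12));
    double dEdth = kf * (th - th0);
    for (int q = 0; q < 3; ++q) {
      double dth_di = (c * u[q] / lu - v[q] / lv) / (lu * s);
      double dth_dk = (c * v[q] / lv - u[q] / lu) / (lv * s);
      f[3*i+q] -= w * dEdth * dth_di;
      f[3*k+q] -= w * dEdth * dth_dk;
      f[3*j+q] += w * dEdth * (dth_di + dth_dk);
    }
  }
  return e;
}

// IUPAC-sign dihedral: phi = atan2((n1 x n2).b2hat, n1.n2)
double dihedral_term(const double* x, const double* row, double w, double* f) {
  int i = (int)row[0], j = (int)row[1], k = (int)row[2], l = (int)row[3];
  double K = row[4], mult = row[5], delta = row[6];
  double b1[3], b2[3], b3[3], n1[3], n2[3], m1[3];
  vsub(x + 3*j, x + 3*i, b1);
  vsub(x + 3*k, x + 3*j, b2);
  vsub(x + 3*l, x + 3*k, b3);
  vcross(b1, b2, n1);
  vcross(b2, b3, n2);
  vcross(n1, n2, m1);
  double lb2 = vnorm(b2);
  double phi = std::atan2(vdot(m1, b2) / std::max(lb2, 1e-12), vdot(n1, n2));
  double e = K * (1.0 + std::cos(mult * phi - delta));
  if (f) {
    double dEdphi = -K * mult * std::sin(mult * phi - delta);
    double n1sq = std::max(vdot(n1, n1), 1e-12);
    double n2sq = std::max(vdot(n2, n2), 1e-12);
    double s1 = vdot(b1, b2) / (lb2 * lb2);
    double s2 = vdot(b3, b2) / (lb2 * lb2);
    for (int q = 0; q < 3; ++q) {
      double dphi_di = -(lb2 / n1sq) * n1[q];
      double dphi_dl =  (lb2 / n2sq) * n2[q];
      double dphi_dj = -(1.0 + s1) * dphi_di + s2 * dphi_dl;
      double dphi_dk = s1 * dphi_di - (1.0 + s2) * dphi_dl;
      f[3*i+q] -= w * dEdphi * dphi_di;
      f[3*j+q] -= w * dEdphi * dphi_dj;
      f[3*k+q] -= w * dEdphi * dphi_dk;
      f[3*l+q] -= w * dEdphi * dphi_dl;
    }
  }
  return e;
}

// Lennard-Jones part of a nonbonded pair
double lj_term(const double* x, const double* row, double w, double* f) {
  int i = (int)row[0], j = (int)row[1];
  double eps = row[2], sig = row[3];
  if (eps == 0.0) return 0.0;
  double d[3];
  vsub(x + 3*i, x + 3*j, d);
  double r2 = std::max(vdot(d, d), 1e-12);
  double sr2 = sig * sig / r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
  double e = 4.0 * eps * (sr12 - sr6);
  if (f) {
    double c = w * 24.0 * eps * (2.0 * sr12 - sr6) / r2;  // -dE/dr / r
    for (int q = 0; q < 3; ++q) { f[3*i+q] += c * d[q]; f[3*j+q] -= c * d[q]; }
  }
  return e;
}

// Coulomb part of a nonbonded pair (reduced units: E = q_i q_j / r)
double coul_term(const double* x, const double* row, double w, double* f) {
  int i = (int)row[0], j = (int)row[1];
  double qq = row[4];
  if (qq == 0.0) return 0.0;
  double d[3];
  vsub(x + 3*i, x + 3*j, d);
  double r = std::max(vnorm(d), 1e-9);
  double e = qq / r;
  if (f) {
    double c = w * qq / (r * r * r);  // -dE/dr / r
    for (int q = 0; q < 3; ++q) { f[3*i+q] += c * d[q]; f[3*j+q] -= c * d[q]; }
  }
  return e;
}

std::vector<double> factors(const NumericVector& expo, double s) {
  std::vector<double> f(expo.size());
  for (int i = 0; i < expo.size(); ++i)
    f[i] = (expo[i] == 0.0) ? 1.0 : std::pow(s, expo[i]);
  return f;
}

// row pointer helper: Rcpp matrices are column-major, copy row into buf
inline void get_row(const NumericMatrix& m, int t, double* buf) {
  for (int c = 0; c < m.ncol(); ++c) buf[c] = m(t, c);
}

struct Factors {
  std::vector<double> b, a, d, r, v, e;
};

Factors make_factors(const Sys& s, double scale) {
  Factors f;
  f.b = factors(s.eb, scale);
  f.a = factors(s.ea, scale);
  f.d = factors(s.ed, scale);
  f.r = factors(s.er, scale);
  f.v = factors(s.ev, scale);
  f.e = factors(s.ee, scale);
  return f;
}

double total_scaled(const double* x, const Sys& s, const Factors& fac, double* force) {
  double row[8], e = 0.0;
  for (int t = 0; t < s.bonds.nrow(); ++t) {
    get_row(s.bonds, t, row);
    e += fac.b[t] * bond_term(x, row, fac.b[t], force);
  }
  for (int t = 0; t < s.angles.nrow(); ++t) {
    get_row(s.angles, t, row);
    e += fac.a[t] * angle_term(x, row, fac.a[t], force);
  }
  for (int t = 0; t < s.dihedrals.nrow(); ++t) {
    get_row(s.dihedrals, t, row);
    e += fac.d[t] * dihedral_term(x, row, fac.d[t], force);
  }
  for (int t = 0; t < s.restr.nrow(); ++t) {
    get_row(s.restr, t, row);
    e += fac.r[t] * restraint_term(x, row, fac.r[t], force);
  }
  for (int t = 0; t < s.pairs.nrow(); ++t) {
    get_row(s.pairs, t, row);
    e += fac.v[t] * lj_term(x, row, fac.v[t], force);
    e += fac.e[t] * coul_term(x, row, fac.e[t], force);
  }
  return e;
}

// adjacency: for each atom, the term rows touching it, tagged by type
struct Adjacency {
  // type codes: 0 bond, 1 angle, 2 dihedral, 3 restraint, 4 pair
  std::vector<std::vector<std::pair<int,int> > > at;
};

Adjacency build_adjacency(const Sys& s) {
  Adjacency adj;
  adj.at.resize(s.n);
  for (int t = 0; t < s.bonds.nrow(); ++t)
    for (int q = 0; q < 2; ++q) adj.at[(int)s.bonds(t, q)].push_back({0, t});
  for (int t = 0; t < s.angles.nrow(); ++t)
    for (int q = 0; q < 3; ++q) adj.at[(int)s.angles(t, q)].push_back({1, t});
  for (int t = 0; t < s.dihedrals.nrow(); ++t)
    for (int q = 0; q < 4; ++q) adj.at[(int)s.dihedrals(t, q)].push_back({2, t});
  for (int t = 0; t < s.restr.nrow(); ++t)
    adj.at[(int)s.restr(t, 0)].push_back({3, t});
  for (int t = 0; t < s.pairs.nrow(); ++t)
    for (int q = 0; q < 2; ++q) adj.at[(int)s.pairs(t, q)].push_back({4, t});
  return adj;
}

// scaled energy of all terms touching atom a
double atom_scaled_energy(const double* x, const Sys& s, const Factors& fac,
                          const Adjacency& adj, int a) {
  double row[8], e = 0.0;
  for (size_t q = 0; q < adj.at[a].size(); ++q) {
    int type = adj.at[a][q].first, t = adj.at[a][q].second;
    switch (type) {
      case 0: get_row(s.bonds, t, row); e += fac.b[t] * bond_term(x, row, 0, nullptr); break;
      case 1: get_row(s.angles, t, row); e += fac.a[t] * angle_term(x, row, 0, nullptr); break;
      case 2: get_row(s.dihedrals, t, row); e += fac.d[t] * dihedral_term(x, row, 0, nullptr); break;
      case 3: get_row(s.restr, t, row); e += fac.r[t] * restraint_term(x, row, 0, nullptr); break;
      case 4: get_row(s.pairs, t, row);
        e += fac.v[t] * lj_term(x, row, 0, nullptr);
        e += fac.e[t] * coul_term(x, row, 0, nullptr);
        break;
    }
  }
  return e;
}

std::mt19937_64 make_engine(const IntegerVector& seed) {
  std::vector<std::uint32_t> sv(seed.begin(), seed.end());
  std::seed_seq seq(sv.begin(), sv.end());
  return std::mt19937_64(seq);
}

std::vector<double> as_flat(const NumericMatrix& pos) {
  // pos is n x 3 (column-major in R); flatten to xyz triples per atom
  std::vector<double> x(3 * pos.nrow());
  for (int i = 0; i < pos.nrow(); ++i)
    for (int q = 0; q < 3; ++q) x[3*i+q] = pos(i, q);
  return x;
}

NumericMatrix as_mat(const std::vector<double>& x, int n) {
  NumericMatrix m(n, 3);
  for (int i = 0; i < n; ++i)
    for (int q = 0; q < 3; ++q) m(i, q) = x[3*i+q];
  return m;
}

}  // namespace

// [[Rcpp::export]]
List cpp_term_energies(NumericMatrix pos, List sys) {
  Sys s = unpack(sys);
  std::vector<double> x = as_flat(pos);
  double row[8];
  NumericVector bond(s.bonds.nrow()), angle(s.angles.nrow()),
      dihedral(s.dihedrals.nrow()), restraint(s.restr.nrow()),
      vdw(s.pairs.nrow()), elec(s.pairs.nrow());
  for (int t = 0; t < s.bonds.nrow(); ++t) {
    get_row(s.bonds, t, row); bond[t] = bond_term(x.data(), row, 0, nullptr);
  }
  for (int t = 0; t < s.angles.nrow(); ++t) {
    get_row(s.angles, t, row); angle[t] = angle_term(x.data(), row, 0, nullptr);
  }
  for (int t = 0; t < s.dihedrals.nrow(); ++t) {
    get_row(s.dihedrals, t, row); dihedral[t] = dihedral_term(x.data(), row, 0, nullptr);
  }
  for (int t = 0; t < s.restr.nrow(); ++t) {
    get_row(s.restr, t, row); restraint[t] = restraint_term(x.data(), row, 0, nullptr);
  }
  for (int t = 0; t < s.pairs.nrow(); ++t) {
    get_row(s.pairs, t, row);
    vdw[t] = lj_term(x.data(), row, 0, nullptr);
    elec[t] = coul_term(x.data(), row, 0, nullptr);
  }
  return List::create(_["bond"] = bond, _["angle"] = angle,
                      _["dihedral"] = dihedral, _["restraint"] = restraint,
                      _["vdw"] = vdw, _["elec"] = elec);
}

// [[Rcpp::export]]
double cpp_scaled_energy(NumericMatrix pos, List sys, double s) {
  Sys sy = unpack(sys);
  std::vector<double> x = as_flat(pos);
  Factors fac = make_factors(sy, s);
  return total_scaled(x.data(), sy, fac, nullptr);
}

// [[Rcpp::export]]
NumericMatrix cpp_scaled_forces(NumericMatrix pos, List sys, double s) {
  Sys sy = unpack(sys);
  std::vector<double> x = as_flat(pos);
  std::vector<double> f(3 * sy.n, 0.0);
  Factors fac = make_factors(sy, s);
  total_scaled(x.data(), sy, fac, f.data());
  return as_mat(f, sy.n);
}

// Metropolis single-particle sweeps against the scaled potential at bath
// inverse temperature beta0.  One sweep = one Gaussian displacement attempt
// per atom, atoms in index order.
// [[Rcpp::export]]
List cpp_mc_run(NumericMatrix pos, List sys, double s, double beta0,
                int n_sweeps, double step_sd, IntegerVector seed) {
  Sys sy = unpack(sys);
  std::vector<double> x = as_flat(pos);
  Factors fac = make_factors(sy, s);
  Adjacency adj = build_adjacency(sy);
  std::mt19937_64 eng = make_engine(seed);
  std::normal_distribution<double> gauss(0.0, step_sd);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  long accepted = 0, attempted = 0;
  double old_pos[3];
  for (int sw = 0; sw < n_sweeps; ++sw) {
    for (int a = 0; a < sy.n; ++a) {
      double e_old = atom_scaled_energy(x.data(), sy, fac, adj, a);
      for (int q = 0; q < 3; ++q) {
        old_pos[q] = x[3*a+q];
        x[3*a+q] += gauss(eng);
      }
      double de = atom_scaled_energy(x.data(), sy, fac, adj, a) - e_old;
      ++attempted;
      bool acc;
      if (de <= 0.0) acc = true;
      else acc = (unif(eng) <= std::exp(-beta0 * de));
      if (acc) ++accepted;
      else for (int q = 0; q < 3; ++q) x[3*a+q] = old_pos[q];
    }
  }
  return List::create(_["pos"] = as_mat(x, sy.n),
                      _["accepted"] = (double)accepted,
                      _["attempted"] = (double)attempted);
}

// BAOAB Langevin integrator under the scaled potential.
// [[Rcpp::export]]
List cpp_langevin_run(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
                      List sys, double s, double beta0, int n_steps,
                      double dt, double gamma, IntegerVector seed) {
  Sys sy = unpack(sys);
  int n = sy.n;
  std::vector<double> x = as_flat(pos), v = as_flat(vel);
  Factors fac = make_factors(sy, s);
  std::mt19937_64 eng = make_engine(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  double T = 1.0 / beta0;
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);
  std::vector<double> f(3 * n, 0.0);
  total_scaled(x.data(), sy, fac, f.data());
  for (int st = 0; st < n_steps; ++st) {
    for (int i = 0; i < n; ++i)
      for (int q = 0; q < 3; ++q) {
        v[3*i+q] += 0.5 * dt * f[3*i+q] / mass[i];
        x[3*i+q] += 0.5 * dt * v[3*i+q];
      }
    for (int i = 0; i < n; ++i) {
      double sd = std::sqrt(T / mass[i]);
      for (int q = 0; q < 3; ++q)
        v[3*i+q] = c1 * v[3*i+q] + c2 * sd * gauss(eng);
    }
    for (int i = 0; i < n; ++i)
      for (int q = 0; q < 3; ++q) x[3*i+q] += 0.5 * dt * v[3*i+q];
    std::fill(f.begin(), f.end(), 0.0);
    double e = total_scaled(x.data(), sy, fac, f.data());
    if (!std::isfinite(e)) stop("Langevin integrator diverged (non-finite energy)");
    for (int i = 0; i < n; ++i)
      for (int q = 0; q < 3; ++q) v[3*i+q] += 0.5 * dt * f[3*i+q] / mass[i];
  }
  return List::create(_["pos"] = as_mat(x, n), _["vel"] = as_mat(v, n));
}

// Discrete-state extended-ensemble chain used for exact detailed-balance
// fixtures: per-state scaled energies are supplied per ladder rung.
// emat: n_states x M matrix, beta0-scaled total energy beta0*E_m(x).
// delta(m, xa, xb) is evaluated on the R side and passed as a lookup
// cube via ddelta[(m-1)][xa][xb] flattened; exchange attempted every
// exch_every cycles with alternating parity.
// [[Rcpp::export]]
List cpp_discrete_run(NumericMatrix emat, NumericVector ddelta, int M,
                      int n_steps, int exch_every, IntegerVector seed) {
  int ns = emat.nrow();
  std::mt19937_64 eng = make_engine(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::uniform_int_distribution<int> pick(0, ns - 1);
  std::vector<int> state(M, 0);      // configuration per replica
  std::vector<int> m_of_a(M), a_of_m(M);
  for (int a = 0; a < M; ++a) { m_of_a[a] = a; a_of_m[a] = a; }
  // joint occupancy keyed by (configuration at rung 1, ..., rung M)
  std::vector<long> counts((size_t)std::round(std::pow((double)ns, M)), 0);
  int parity = 0;
  for (int st = 0; st < n_steps; ++st) {
    // one Metropolis update per replica: propose uniformly another state
    for (int a = 0; a < M; ++a) {
      int cur = state[a];
      int prop = pick(eng);
      if (prop == cur) continue;
      double de = emat(prop, m_of_a[a]) - emat(cur, m_of_a[a]);
      if (de <= 0.0 || unif(eng) <= std::exp(-de)) state[a] = prop;
    }
    if (exch_every > 0 && (st + 1) % exch_every == 0) {
      for (int m = parity; m + 1 < M; m += 2) {
        int a = a_of_m[m], b = a_of_m[m + 1];
        double d = ddelta[(size_t)m * ns * ns + (size_t)state[a] * ns + state[b]];
        bool acc = (d <= 0.0) || (unif(eng) <= std::exp(-d));
        if (acc) {
          std::swap(m_of_a[a], m_of_a[b]);
          a_of_m[m] = b; a_of_m[m + 1] = a;
        }
      }
      parity = 1 - parity;
    }
    // record occupancy keyed by configuration at each rung
    size_t key = 0;
    for (int m = 0; m < M; ++m) key = key * ns + state[a_of_m[m]];
    counts[key]++;
  }
  NumericVector out(counts.size());
  for (size_t i = 0; i < counts.size(); ++i) out[i] = (double)counts[i];
  return List::create(_["counts"] = out);
}
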