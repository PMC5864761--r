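// Core numerics: atomic-overlap contact scan, the structure-based
// C-alpha Hamiltonian with analytic forces, and Langevin dynamics via
// the fifth-order Gear predictor-corrector, plus the three simulation
// protocols (equilibrium sampling, thermal unfolding, constant-speed
// pulling). Reduced units: energy eps, length Angstrom, time tau,
// mass m = 1, k_B = 1.

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------- overlap criterion ----------

// all atom pairs (belonging to different beads) whose spheres overlap:
// dist <= scale * (r_i + r_j); returns the bead index pairs (1-based)
// [[Rcpp::export]]
IntegerMatrix overlap_pairs_cpp(NumericMatrix xyz, NumericVector r,
                                IntegerVector bead, double scale,
                                double maxcut) {
  const int n = xyz.nrow();
  std::vector<int> bi, bj;
  const double mc2 = maxcut * maxcut;
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      if (bead[a] == bead[b]) continue;
      double dx = xyz(a, 0) - xyz(b, 0);
      double dy = xyz(a, 1) - xyz(b, 1);
      double dz = xyz(a, 2) - xyz(b, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > mc2) continue;
      double cut = scale * (r[a] + r[b]);
      if (d2 <= cut * cut) {
        bi.push_back(bead[a]);
        bj.push_back(bead[b]);
      }
    }
  }
  IntegerMatrix out(bi.size(), 2);
  for (size_t k = 0; k < bi.size(); ++k) {
    out(k, 0) = bi[k];
    out(k, 1) = bj[k];
  }
  return out;
}

// ---------- topology ----------

struct Topo {
  int n;
  std::vector<double> x0;           // native coords, 3n
  std::vector<int> bi, bj;          // bonds (0-based)
  std::vector<double> br0;
  std::vector<int> ci, cj;          // native contacts
  std::vector<double> sigma;
  std::vector<int> nonlocal;        // per contact
  std::vector<int> interface;       // per contact
  std::vector<int> q0, q1, q2, q3;  // chirality quadruplets
  std::vector<double> cnat, d0;
  std::unordered_set<long long> excl;  // bonded + native pairs
  double k_bond, eps, r0_rep, kappa;
  double sr6;  // (r0_rep / 2^(1/6))^6

  long long key(int i, int j) const {
    if (i > j) std::swap(i, j);
    return (long long)i * n + j;
  }
};

static Topo parse_topo(const List& tl) {
  Topo t;
  NumericMatrix x0 = tl["coords"];
  t.n = x0.nrow();
  t.x0.resize(3 * t.n);
  for (int i = 0; i < t.n; ++i)
    for (int d = 0; d < 3; ++d) t.x0[3 * i + d] = x0(i, d);
  IntegerVector bi = tl["bond_i"], bj = tl["bond_j"];
  NumericVector br0 = tl["bond_r0"];
  t.bi.assign(bi.begin(), bi.end());
  t.bj.assign(bj.begin(), bj.end());
  t.br0.assign(br0.begin(), br0.end());
  IntegerVector ci = tl["contact_i"], cj = tl["contact_j"];
  NumericVector sg = tl["contact_sigma"];
  IntegerVector nl = tl["contact_nonlocal"], fi = tl["contact_interface"];
  t.ci.assign(ci.begin(), ci.end());
  t.cj.assign(cj.begin(), cj.end());
  t.sigma.assign(sg.begin(), sg.end());
  t.nonlocal.assign(nl.begin(), nl.end());
  t.interface.assign(fi.begin(), fi.end());
  IntegerVector q0 = tl["chir_q0"], q1 = tl["chir_q1"], q2 = tl["chir_q2"],
               q3 = tl["chir_q3"];
  NumericVector cn = tl["chir_native"], d0 = tl["chir_d0"];
  t.q0.assign(q0.begin(), q0.end());
  t.q1.assign(q1.begin(), q1.end());
  t.q2.assign(q2.begin(), q2.end());
  t.q3.assign(q3.begin(), q3.end());
  t.cnat.assign(cn.begin(), cn.end());
  t.d0.assign(d0.begin(), d0.end());
  List pars = tl["params"];
  t.k_bond = as<double>(pars["k_bond"]);
  t.eps = as<double>(pars["epsilon_model"]);
  t.r0_rep = as<double>(pars["r0_rep"]);
  t.kappa = as<double>(pars["chirality_strength"]);
  double sr = t.r0_rep / std::pow(2.0, 1.0 / 6.0);
  t.sr6 = std::pow(sr, 6);
  for (size_t k = 0; k < t.bi.size(); ++k)
    t.excl.insert(t.key(t.bi[k], t.bj[k]));
  for (size_t k = 0; k < t.ci.size(); ++k)
    t.excl.insert(t.key(t.ci[k], t.cj[k]));
  return t;
}

// ---------- energy and forces ----------

struct EnergyParts {
  double bond = 0, native = 0, rep = 0, chir = 0;
  double total() const { return bond + native + rep + chir; }
};

// neighbor list for the repulsive term
struct NeighborList {
  std::vector<int> pi, pj;
  std::vector<double> ref;  // coords at last build
  double skin = 2.0;

  void build(const Topo& t, const std::vector<double>& x) {
    pi.clear();
    pj.clear();
    double cut = t.r0_rep + skin;
    double c2 = cut * cut;
    for (int i = 0; i < t.n; ++i) {
      for (int j = i + 1; j < t.n; ++j) {
        if (t.excl.count(t.key(i, j))) continue;
        double dx = x[3 * i] - x[3 * j];
        double dy = x[3 * i + 1] - x[3 * j + 1];
        double dz = x[3 * i + 2] - x[3 * j + 2];
        if (dx * dx + dy * dy + dz * dz < c2) {
          pi.push_back(i);
          pj.push_back(j);
        }
      }
    }
    ref = x;
  }

  bool stale(const std::vector<double>& x) const {
    if (ref.size() != x.size()) return true;
    double lim = (skin * 0.5) * (skin * 0.5);
    for (size_t i = 0; i < x.size(); i += 3) {
      double dx = x[i] - ref[i], dy = x[i + 1] - ref[i + 1],
             dz = x[i + 2] - ref[i + 2];
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }
};

static EnergyParts eval_forces(const Topo& t, const std::vector<double>& x,
                               std::vector<double>& f, NeighborList* nl) {
  EnergyParts e;
  std::fill(f.begin(), f.end(), 0.0);

  // bonds: (k/2)(r - r0)^2
  for (size_t k = 0; k < t.bi.size(); ++k) {
    int i = t.bi[k], j = t.bj[k];
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - t.br0[k];
    e.bond += 0.5 * t.k_bond * dr * dr;
    double fr = -t.k_bond * dr / r;  // dV/dr, projected
    f[3 * i] += fr * dx;     f[3 * j] -= fr * dx;
    f[3 * i + 1] += fr * dy; f[3 * j + 1] -= fr * dy;
    f[3 * i + 2] += fr * dz; f[3 * j + 2] -= fr * dz;
  }

  // native 12-6 contacts
  for (size_t k = 0; k < t.ci.size(); ++k) {
    int i = t.ci[k], j = t.cj[k];
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    double s2 = t.sigma[k] * t.sigma[k] / r2;
    double s6 = s2 * s2 * s2;
    e.native += 4.0 * t.eps * (s6 * s6 - s6);
    double fr = 24.0 * t.eps * (2.0 * s6 * s6 - s6) / r2;  // -dV/dr / r
    f[3 * i] += fr * dx;     f[3 * j] -= fr * dx;
    f[3 * i + 1] += fr * dy; f[3 * j + 1] -= fr * dy;
    f[3 * i + 2] += fr * dz; f[3 * j + 2] -= fr * dz;
  }

  // truncated-shifted repulsion on everything else
  NeighborList local;
  NeighborList* use = nl;
  if (use == nullptr) {
    local.build(t, x);
    use = &local;
  } else if (use->stale(x)) {
    use->build(t, x);
  }
  double r0c2 = t.r0_rep * t.r0_rep;
  for (size_t k = 0; k < use->pi.size(); ++k) {
    int i = use->pi[k], j = use->pj[k];
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= r0c2) continue;
    double s6 = t.sr6 / (r2 * r2 * r2);
    e.rep += 4.0 * t.eps * (s6 * s6 - s6) + t.eps;
    double fr = 24.0 * t.eps * (2.0 * s6 * s6 - s6) / r2;
    f[3 * i] += fr * dx;     f[3 * j] -= fr * dx;
    f[3 * i + 1] += fr * dy; f[3 * j + 1] -= fr * dy;
    f[3 * i + 2] += fr * dz; f[3 * j + 2] -= fr * dz;
  }

  // chirality: (kappa/2)(C - Cnat)^2, C = (v1 x v2) . v3 / d0^3
  for (size_t k = 0; k < t.q0.size(); ++k) {
    int a = t.q0[k], b = t.q1[k], c = t.q2[k], d = t.q3[k];
    double v1[3], v2[3], v3[3];
    for (int m = 0; m < 3; ++m) {
      v1[m] = x[3 * b + m] - x[3 * a + m];
      v2[m] = x[3 * c + m] - x[3 * b + m];
      v3[m] = x[3 * d + m] - x[3 * c + m];
    }
    double c12[3] = {v1[1] * v2[2] - v1[2] * v2[1],
                     v1[2] * v2[0] - v1[0] * v2[2],
                     v1[0] * v2[1] - v1[1] * v2[0]};
    double c23[3] = {v2[1] * v3[2] - v2[2] * v3[1],
                     v2[2] * v3[0] - v2[0] * v3[2],
                     v2[0] * v3[1] - v2[1] * v3[0]};
    double c31[3] = {v3[1] * v1[2] - v3[2] * v1[1],
                     v3[2] * v1[0] - v3[0] * v1[2],
                     v3[0] * v1[1] - v3[1] * v1[0]};
    double d03 = t.d0[k] * t.d0[k] * t.d0[k];
    double C = (c12[0] * v3[0] + c12[1] * v3[1] + c12[2] * v3[2]) / d03;
    double dC = C - t.cnat[k];
    e.chir += 0.5 * t.kappa * dC * dC;
    double pref = -t.kappa * dC / d03;  // force prefactor
    for (int m = 0; m < 3; ++m) {
      // dC*d03 w.r.t. v1 = v2 x v3, v2 = v3 x v1, v3 = v1 x v2
      double g_a = -c23[m];
      double g_b = c23[m] - c31[m];
      double g_c = c31[m] - c12[m];
      double g_d = c12[m];
      f[3 * a + m] += pref * g_a;
      f[3 * b + m] += pref * g_b;
      f[3 * c + m] += pref * g_c;
      f[3 * d + m] += pref * g_d;
    }
  }
  return e;
}

// [[Rcpp::export]]
List cg_eval_cpp(List topo, NumericMatrix coords, bool forces = true) {
  Topo t = parse_topo(topo);
  if (coords.nrow() != t.n) stop("coordinate/bead count mismatch");
  std::vector<double> x(3 * t.n), f(3 * t.n, 0.0);
  for (int i = 0; i < t.n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);
  // guard against coincident beads
  for (size_t k = 0; k < t.ci.size(); ++k) {
    int i = t.ci[k], j = t.cj[k];
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    if (dx * dx + dy * dy + dz * dz < 0.01)
      stop("overlapping beads (contact %d-%d closer than 0.1 A)", i + 1,
           j + 1);
  }
  EnergyParts e = eval_forces(t, x, f, nullptr);
  NumericMatrix fm(t.n, 3);
  if (forces)
    for (int i = 0; i < t.n; ++i)
      for (int d = 0; d < 3; ++d) fm(i, d) = f[3 * i + d];
  return List::create(_["bond"] = e.bond, _["native"] = e.native,
                      _["repulsive"] = e.rep, _["chirality"] = e.chir,
                      _["total"] = e.total(), _["forces"] = fm);
}

// ---------- Gear-5 Langevin integrator ----------

struct Tether {
  int bead;
  double anchor[3];
  double k;
  double vel[3];  // anchor velocity (A/tau)
};

struct GearState {
  int n;
  double dt;
  std::vector<double> r0, r1, r2, r3, r4, r5;  // scaled derivatives

  void init(const std::vector<double>& x, double T, double dt_) {
    n = (int)x.size() / 3;
    dt = dt_;
    r0 = x;
    r1.assign(3 * n, 0.0);
    r2.assign(3 * n, 0.0);
    r3.assign(3 * n, 0.0);
    r4.assign(3 * n, 0.0);
    r5.assign(3 * n, 0.0);
    if (T > 0) {
      double s = std::sqrt(T);  // m = kB = 1
      for (int i = 0; i < 3 * n; ++i) r1[i] = s * norm_rand() * dt;
    }
  }

  void predict() {
    for (int i = 0; i < 3 * n; ++i) {
      r0[i] += r1[i] + r2[i] + r3[i] + r4[i] + r5[i];
      r1[i] += 2 * r2[i] + 3 * r3[i] + 4 * r4[i] + 5 * r5[i];
      r2[i] += 3 * r3[i] + 6 * r4[i] + 10 * r5[i];
      r3[i] += 4 * r4[i] + 10 * r5[i];
      r4[i] += 5 * r5[i];
    }
  }

  // a = acceleration evaluated at predicted state
  void correct(const std::vector<double>& a) {
    // Gear-5 coefficients for 2nd-order ODEs with velocity-dependent force
    const double c0 = 3.0 / 16.0, c1 = 251.0 / 360.0, c3 = 11.0 / 18.0,
                 c4 = 1.0 / 6.0, c5 = 1.0 / 60.0;
    for (int i = 0; i < 3 * n; ++i) {
      double corr = a[i] * dt * dt * 0.5 - r2[i];
      r0[i] += c0 * corr;
      r1[i] += c1 * corr;
      r2[i] += corr;
      r3[i] += c3 * corr;
      r4[i] += c4 * corr;
      r5[i] += c5 * corr;
    }
  }
};

struct SimEngine {
  Topo t;
  GearState g;
  NeighborList nl;
  std::vector<double> f, acc, noise;
  std::vector<Tether> tethers;
  double T, gamma, dt, noise_sd;
  long step_count = 0;
  EnergyParts last_e;

  void init(const Topo& topo, const std::vector<double>& x0, double T_,
            double gamma_, double dt_) {
    t = topo;
    T = T_;
    gamma = gamma_;
    dt = dt_;
    g.init(x0, T, dt);
    f.assign(3 * t.n, 0.0);
    acc.assign(3 * t.n, 0.0);
    noise.assign(3 * t.n, 0.0);
    noise_sd = (T > 0 && gamma > 0) ? std::sqrt(2.0 * gamma * T / dt) : 0.0;
    nl.build(t, g.r0);
  }

  void add_tether(int bead, double ax, double ay, double az, double k,
                  double vx = 0, double vy = 0, double vz = 0) {
    Tether th;
    th.bead = bead;
    th.anchor[0] = ax; th.anchor[1] = ay; th.anchor[2] = az;
    th.k = k;
    th.vel[0] = vx; th.vel[1] = vy; th.vel[2] = vz;
    tethers.push_back(th);
  }

  void do_step() {
    g.predict();
    last_e = eval_forces(t, g.r0, f, &nl);
    // tether springs (m = 1)
    double tnow = 0;  // anchors advanced incrementally below
    (void)tnow;
    for (auto& th : tethers) {
      for (int m = 0; m < 3; ++m) {
        th.anchor[m] += th.vel[m] * dt;
        f[3 * th.bead + m] += th.k * (th.anchor[m] - g.r0[3 * th.bead + m]);
      }
    }
    if (noise_sd > 0)
      for (int i = 0; i < 3 * t.n; ++i) noise[i] = noise_sd * norm_rand();
    for (int i = 0; i < 3 * t.n; ++i) {
      double v = g.r1[i] / dt;
      acc[i] = f[i] - gamma * v + (noise_sd > 0 ? noise[i] : 0.0);
    }
    g.correct(acc);
    ++step_count;
    if ((step_count & 1023) == 0) {
      for (int i = 0; i < 3 * t.n; ++i)
        if (!std::isfinite(g.r0[i]) || std::fabs(g.r0[i]) > 1e6)
          stop("numeric blow-up at step %ld", step_count);
    }
  }

  double kinetic() const {
    double ke = 0;
    for (int i = 0; i < 3 * t.n; ++i) {
      double v = g.r1[i] / dt;
      ke += 0.5 * v * v;
    }
    return ke;
  }

  // fraction of native contacts present (r < cut_mult * sigma) and
  // whether all are present
  void contact_state(double cut_mult, int& n_present, int& n_total) const {
    n_present = 0;
    n_total = (int)t.ci.size();
    for (size_t k = 0; k < t.ci.size(); ++k) {
      int i = t.ci[k], j = t.cj[k];
      double dx = g.r0[3 * i] - g.r0[3 * j];
      double dy = g.r0[3 * i + 1] - g.r0[3 * j + 1];
      double dz = g.r0[3 * i + 2] - g.r0[3 * j + 2];
      double cut = cut_mult * t.sigma[k];
      if (dx * dx + dy * dy + dz * dz < cut * cut) ++n_present;
    }
  }
};

// generic integration driver: returns sampled frames and diagnostics
// [[Rcpp::export]]
List integrate_cpp(List topo, NumericMatrix start, double T, double gamma,
                   double dt, int steps, int stride,
                   Nullable<List> tethers_ = R_NilValue) {
  Topo t = parse_topo(topo);
  if (start.nrow() != t.n) stop("start coordinates do not match topology");
  std::vector<double> x0(3 * t.n);
  for (int i = 0; i < t.n; ++i)
    for (int d = 0; d < 3; ++d) x0[3 * i + d] = start(i, d);
  SimEngine eng;
  eng.init(t, x0, T, gamma, dt);
  if (tethers_.isNotNull()) {
    List tl(tethers_);
    IntegerVector bead = tl["bead"];
    NumericMatrix anchor = tl["anchor"];
    NumericVector kk = tl["k"];
    for (int i = 0; i < bead.size(); ++i)
      eng.add_tether(bead[i] - 1, anchor(i, 0), anchor(i, 1), anchor(i, 2),
                     kk[i]);
  }
  int n_frames = steps / stride;
  NumericMatrix frames(n_frames, 3 * t.n);
  NumericVector ke(n_frames), etot(n_frames), q(n_frames), times(n_frames);
  int fr = 0;
  for (int s = 1; s <= steps; ++s) {
    eng.do_step();
    if (s % stride == 0 && fr < n_frames) {
      for (int i = 0; i < 3 * t.n; ++i) frames(fr, i) = eng.g.r0[i];
      ke[fr] = eng.kinetic();
      etot[fr] = eng.last_e.total() + ke[fr];
      int np, nt;
      eng.contact_state(1.5, np, nt);
      q[fr] = nt > 0 ? (double)np / nt : 1.0;
      times[fr] = s * dt;
      ++fr;
    }
  }
  return List::create(_["frames"] = frames, _["kinetic"] = ke,
                      _["total_energy"] = etot, _["q"] = q,
                      _["time"] = times);
}

// equilibrium thermal-stability sampling: P0 / Q accumulators
// [[Rcpp::export]]
List run_thermal_cpp(List topo, double T, double gamma, double dt,
                     int equil_steps, int steps, int stride) {
  Topo t = parse_topo(topo);
  SimEngine eng;
  eng.init(t, t.x0, T, gamma, dt);
  for (int s = 0; s < equil_steps; ++s) eng.do_step();
  long n_frames = 0, n_all = 0;
  double sum_q = 0, sum_ke = 0;
  for (int s = 1; s <= steps; ++s) {
    eng.do_step();
    if (s % stride == 0) {
      int np, nt;
      eng.contact_state(1.5, np, nt);
      ++n_frames;
      if (np == nt) ++n_all;
      sum_q += nt > 0 ? (double)np / nt : 1.0;
      sum_ke += eng.kinetic();
    }
  }
  return List::create(_["n_frames"] = (double)n_frames,
                      _["n_all_present"] = (double)n_all,
                      _["sum_q"] = sum_q,
                      _["mean_ke_per_dof"] =
                          n_frames ? sum_ke / n_frames / (3.0 * t.n) : NA_REAL);
}

// thermal unfolding: first time all nonlocal contacts are broken
// [[Rcpp::export]]
List run_unfold_cpp(List topo, double T, double gamma, double dt,
                    long max_steps, int check_stride) {
  Topo t = parse_topo(topo);
  std::vector<int> nonloc;
  for (size_t k = 0; k < t.ci.size(); ++k)
    if (t.nonlocal[k]) nonloc.push_back((int)k);
  if (nonloc.empty())
    return List::create(_["t_unf"] = 0.0, _["unfolded"] = true);
  SimEngine eng;
  eng.init(t, t.x0, T, gamma, dt);
  for (long s = 1; s <= max_steps; ++s) {
    eng.do_step();
    if (s % check_stride == 0) {
      bool any_present = false;
      for (int k : nonloc) {
        int i = t.ci[k], j = t.cj[k];
        double dx = eng.g.r0[3 * i] - eng.g.r0[3 * j];
        double dy = eng.g.r0[3 * i + 1] - eng.g.r0[3 * j + 1];
        double dz = eng.g.r0[3 * i + 2] - eng.g.r0[3 * j + 2];
        double cut = 1.5 * t.sigma[k];
        if (dx * dx + dy * dy + dz * dz < cut * cut) {
          any_present = true;
          break;
        }
      }
      if (!any_present)
        return List::create(_["t_unf"] = s * dt, _["unfolded"] = true);
    }
  }
  return List::create(_["t_unf"] = NA_REAL, _["unfolded"] = false);
}

// constant-speed pulling with windowed force and contact-break log
// [[Rcpp::export]]
List run_pull_cpp(List topo, int fixed_bead, int pulled_bead, double K,
                  double vp, double T, double gamma, double dt,
                  double window, double max_d, double sustain) {
  Topo t = parse_topo(topo);
  SimEngine eng;
  eng.init(t, t.x0, T, gamma, dt);
  // pulling direction: from fixed to pulled attachment (native positions)
  double dir[3] = {0, 0, 1};
  if (fixed_bead >= 0) {
    double nrm = 0;
    for (int m = 0; m < 3; ++m) {
      dir[m] = t.x0[3 * pulled_bead + m] - t.x0[3 * fixed_bead + m];
      nrm += dir[m] * dir[m];
    }
    nrm = std::sqrt(nrm);
    if (nrm < 1e-9) stop("pulling springs attached to coincident beads");
    for (int m = 0; m < 3; ++m) dir[m] /= nrm;
    eng.add_tether(fixed_bead, t.x0[3 * fixed_bead], t.x0[3 * fixed_bead + 1],
                   t.x0[3 * fixed_bead + 2], K);
  }
  eng.add_tether(pulled_bead, t.x0[3 * pulled_bead],
                 t.x0[3 * pulled_bead + 1], t.x0[3 * pulled_bead + 2], K,
                 vp * dir[0], vp * dir[1], vp * dir[2]);
  Tether& mov = eng.tethers.back();

  const int nc = (int)t.ci.size();
  std::vector<bool> broken(nc, false);
  std::vector<double> last_break(nc, NA_REAL);
  std::vector<double> first_break(nc, NA_REAL);
  std::vector<int> n_breaks(nc, 0);
  std::vector<int> iface;
  for (int k = 0; k < nc; ++k)
    if (t.interface[k]) iface.push_back(k);

  std::vector<double> win_d, win_f;
  double win_sum = 0;
  long win_n = 0;
  double next_win = window;
  double f_max = -1e300;
  double all_broken_since = -1;  // displacement where interface fully broke
  double dissoc_d = NA_REAL;
  long max_steps = (long)std::ceil(max_d / (vp * dt));

  for (long s = 1; s <= max_steps; ++s) {
    eng.do_step();
    double d = vp * dt * (double)s;
    // spring force component along the pulling direction
    double fs = 0;
    for (int m = 0; m < 3; ++m)
      fs += K * (mov.anchor[m] - eng.g.r0[3 * pulled_bead + m]) * dir[m];
    win_sum += fs;
    ++win_n;
    if (d >= next_win) {
      win_d.push_back(next_win - window / 2);
      double fw = win_sum / win_n;
      win_f.push_back(fw);
      if (fw > f_max) f_max = fw;
      win_sum = 0;
      win_n = 0;
      next_win += window;
    }
    // contact bookkeeping every 10 steps
    if (s % 10 == 0) {
      for (int k = 0; k < nc; ++k) {
        int i = t.ci[k], j = t.cj[k];
        double dx = eng.g.r0[3 * i] - eng.g.r0[3 * j];
        double dy = eng.g.r0[3 * i + 1] - eng.g.r0[3 * j + 1];
        double dz = eng.g.r0[3 * i + 2] - eng.g.r0[3 * j + 2];
        double cut = 1.5 * t.sigma[k];
        bool now_broken = dx * dx + dy * dy + dz * dz > cut * cut;
        if (now_broken && !broken[k]) {
          last_break[k] = d;
          if (n_breaks[k] == 0) first_break[k] = d;
          ++n_breaks[k];
        }
        broken[k] = now_broken;
      }
      if (!iface.empty()) {
        bool all_b = true;
        for (int k : iface)
          if (!broken[k]) {
            all_b = false;
            break;
          }
        if (all_b) {
          if (all_broken_since < 0) all_broken_since = d;
          if (d - all_broken_since >= sustain) {
            dissoc_d = all_broken_since;
            break;
          }
        } else {
          all_broken_since = -1;
        }
      }
    }
  }
  NumericVector lb(nc), fb(nc);
  IntegerVector nb(nc);
  for (int k = 0; k < nc; ++k) {
    lb[k] = last_break[k];
    fb[k] = first_break[k];
    nb[k] = n_breaks[k];
  }
  return List::create(
      _["window_d"] = wrap(win_d), _["window_F"] = wrap(win_f),
      _["F_max"] = (win_f.empty() ? NA_REAL : f_max),
      _["last_break_d"] = lb, _["first_break_d"] = fb, _["n_breaks"] = nb,
      _["dissociation_d"] = dissoc_d,
      _["final_d"] = vp * dt * (double)std::min(max_steps, eng.step_count));
}
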