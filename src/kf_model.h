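#ifndef KF_MODEL_H
#define KF_MODEL_H

#include "kf_common.h"

// Coarse-grained C-alpha force field: harmonic pseudo-bonds, double-well
// pseudo-angles, 4-term pseudo-torsion series keyed by the middle residue
// pair, a 12-10-6 Go well on native pairs, quasi-chemical Lennard-Jones
// attraction/repulsion on non-native pairs, and Debye-Hueckel screened
// electrostatics.  All energies in thermal units (kT = 1).

struct KfModel {
  int N;
  std::vector<int> seq;             // residue types 0..19
  // native contacts
  std::vector<int> ci, cj;          // 0-based, ci < cj, cj - ci >= 3
  std::vector<double> cr0, ceps;
  std::vector<int> nat_id;          // N*N lookup: -1 or contact index
  // non-native
  std::vector<double> nn_eps;       // 20x20 effective eps (negative = attractive)
  std::vector<double> sigma;        // per-residue diameter (A)
  std::vector<double> charge;
  // bonded
  double kbond, b0;
  double ang_gamma, ang_ka, ang_ta, ang_ea, ang_kb, ang_tb;
  std::vector<double> tor_amp;      // 400 x 4 (pair = a*20+b)
  std::vector<double> tor_pha;      // 400 x 4
  // optional native-derived bonded reference (Clementi-style): harmonic
  // angles about theta0[i] and 1+3 cosine torsions about phi0[k]
  bool native_bonded;
  std::vector<double> th0, ph0;
  double nat_k_ang, nat_k_dih1, nat_k_dih3;
  // electrostatics
  double dh_pref;                   // kT*A per unit charge product
  double debye;
  double elec_cut;
  // misc
  double ev_eps;                    // excluded-volume strength, native-only mode
  double ev_sigma;                  // excluded-volume core diameter (A)
  double nn_cut_factor;             // cutoff = factor * sigma_ij
  double temperature;               // global factor on kT (default 1)
  bool native_only;
  mutable long degenerate_torsions;

  void init(const Rcpp::List &m) {
    using namespace Rcpp;
    NumericMatrix nnm = m["nonnative_eps"];
    IntegerVector sq = m["sequence_int"];
    N = sq.size();
    seq.assign(sq.begin(), sq.end());
    IntegerMatrix cp = m["contact_pairs"];
    NumericVector r0 = m["contact_r0"], ep = m["contact_eps"];
    int M = cp.nrow();
    ci.resize(M); cj.resize(M); cr0.resize(M); ceps.resize(M);
    nat_id.assign((size_t)N * N, -1);
    for (int k = 0; k < M; ++k) {
      int a = cp(k, 0) - 1, b = cp(k, 1) - 1;
      if (a > b) std::swap(a, b);
      ci[k] = a; cj[k] = b; cr0[k] = r0[k]; ceps[k] = ep[k];
      nat_id[(size_t)a * N + b] = k;
      nat_id[(size_t)b * N + a] = k;
    }
    nn_eps.assign(400, 0.0);
    for (int a = 0; a < 20; ++a)
      for (int b = 0; b < 20; ++b) nn_eps[a * 20 + b] = nnm(a, b);
    NumericVector sg = m["sigma"], ch = m["charge"];
    sigma.assign(sg.begin(), sg.end());
    charge.assign(ch.begin(), ch.end());
    List bp = m["bonded"];
    kbond = bp["k_bond"]; b0 = bp["b0"];
    ang_gamma = bp["ang_gamma"]; ang_ka = bp["ang_k_alpha"]; ang_ta = bp["ang_theta_alpha"];
    ang_ea = bp["ang_eps_alpha"]; ang_kb = bp["ang_k_beta"]; ang_tb = bp["ang_theta_beta"];
    NumericMatrix ta = bp["torsion_amp"], tp = bp["torsion_phase"];
    tor_amp.resize(1600); tor_pha.resize(1600);
    for (int p = 0; p < 400; ++p)
      for (int ntr = 0; ntr < 4; ++ntr) {
        tor_amp[p * 4 + ntr] = ta(p, ntr);
        tor_pha[p * 4 + ntr] = tp(p, ntr);
      }
    native_bonded = false;
    nat_k_ang = 20.0; nat_k_dih1 = 1.0; nat_k_dih3 = 0.5;
    if (bp.containsElementNamed("theta0")) {
      NumericVector t0 = bp["theta0"];
      if (t0.size() == N - 2) {
        NumericVector f0 = bp["phi0"];
        th0.assign(t0.begin(), t0.end());
        ph0.assign(f0.begin(), f0.end());
        native_bonded = true;
        nat_k_ang = bp["nat_k_ang"];
        nat_k_dih1 = bp["nat_k_dih1"];
        nat_k_dih3 = bp["nat_k_dih3"];
      }
    }
    dh_pref = m["dh_prefactor"]; debye = m["debye_length"];
    elec_cut = 4.0 * debye;
    ev_eps = m["ev_eps"];
    ev_sigma = m.containsElementNamed("ev_sigma") ? as<double>(m["ev_sigma"]) : 4.0;
    nn_cut_factor = m["nn_cut_factor"];
    temperature = m["temperature"];
    native_only = as<bool>(m["native_only"]);
    degenerate_torsions = 0;
  }

  // ---- pair terms --------------------------------------------------------

  // 12-10-6 Go well: minimum -eps exactly at r = r0
  static double go_native(double r, double r0, double eps) {
    double x = r0 / r, x2 = x * x, x6 = x2 * x2 * x2, x10 = x6 * x2 * x2, x12 = x10 * x2;
    return eps * (13.0 * x12 - 18.0 * x10 + 4.0 * x6);
  }

  // quasi-chemical non-native term; eps < 0 attractive (LJ well of depth
  // |eps| at sigma_ij), eps > 0 repulsive (monotone, value eps at sigma_ij)
  static double kh_nonnative(double r, double sig, double eps) {
    double x = sig / r, x2 = x * x, x6 = x2 * x2 * x2, x12 = x6 * x6;
    double lj = x12 - 2.0 * x6;  // min -1 at r = sig
    if (eps < 0) return -eps * lj;          // depth |eps|
    if (r < sig) return eps * lj + 2.0 * eps;
    return -eps * lj;
  }

  static double ev_repulsion(double r, double sig, double eps) {
    double x = sig / r, x2 = x * x, x6 = x2 * x2 * x2;
    return eps * x6 * x6;
  }

  double elec(double r, int i, int j) const {
    double qq = charge[i] * charge[j];
    if (qq == 0.0 || r > elec_cut) return 0.0;
    return dh_pref * qq * std::exp(-r / debye) / r;
  }

  double sig_ij(int i, int j) const { return 0.5 * (sigma[seq[i]] + sigma[seq[j]]); }

  // non-bonded energy of a single (i, j) pair, split into components
  inline void pair_energy(int i, int j, double r, double &e_nat, double &e_nn,
                          double &e_el) const {
    int id = nat_id[(size_t)i * N + j];
    if (id >= 0) {
      e_nat += go_native(r, cr0[id], ceps[id]);
    } else {
      if (native_only) {
        if (r < 2.5 * ev_sigma) e_nn += ev_repulsion(r, ev_sigma, ev_eps);
      } else {
        double sig = sig_ij(i, j);
        if (r < nn_cut_factor * sig)
          e_nn += kh_nonnative(r, sig, nn_eps[seq[i] * 20 + seq[j]]);
      }
    }
    if (!native_only) e_el += elec(r, i, j);
  }

  // squared-distance fast path: identical terms and cutoffs, sqrt deferred
  // until a term is actually inside its cutoff
  inline void pair_energy_r2(int i, int j, double r2, double &e_nat, double &e_nn,
                             double &e_el) const {
    int id = nat_id[(size_t)i * N + j];
    if (id >= 0) {
      double r = std::sqrt(r2);
      e_nat += go_native(r, cr0[id], ceps[id]);
      if (!native_only) e_el += elec(r, i, j);
      return;
    }
    double sig = native_only ? ev_sigma : sig_ij(i, j);
    double cut = native_only ? 2.5 * ev_sigma : nn_cut_factor * sig;
    bool charged = !native_only && charge[i] * charge[j] != 0.0;
    if (r2 < cut * cut) {
      double r = std::sqrt(r2);
      if (native_only) e_nn += ev_repulsion(r, ev_sigma, ev_eps);
      else e_nn += kh_nonnative(r, sig, nn_eps[seq[i] * 20 + seq[j]]);
      if (charged) e_el += elec(r, i, j);
    } else if (charged && r2 < elec_cut * elec_cut) {
      e_el += elec(std::sqrt(r2), i, j);
    }
  }

  // ---- bonded terms ------------------------------------------------------

  double bond_term(const Vec3 &a, const Vec3 &b) const {
    double d = dist(a, b) - b0;
    return kbond * d * d;
  }

  // center = index of the middle bead (1..N-2)
  double angle_term(int center, const Vec3 &a, const Vec3 &b, const Vec3 &c) const {
    Vec3 u = a - b, v = c - b;
    double nu = norm(u), nv = norm(v);
    if (nu < 1e-12 || nv < 1e-12) return 0.0;
    double ct = dot(u, v) / (nu * nv);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    if (native_bonded) {
      double d = th - th0[center - 1];
      return nat_k_ang * d * d;
    }
    double da = th - ang_ta, db = th - ang_tb;
    double ea = ang_ka * da * da + ang_ea;
    double eb = ang_kb * db * db;
    // numerically stable double-well: -(1/g) log(exp(-g ea) + exp(-g eb))
    double m = std::min(ea, eb);
    return m - std::log(std::exp(-ang_gamma * (ea - m)) +
                        std::exp(-ang_gamma * (eb - m))) / ang_gamma;
  }

  // k = index of the first bead of the quadruplet (0..N-4)
  double torsion_term(int k, const Vec3 &p0, const Vec3 &p1, const Vec3 &p2,
                      const Vec3 &p3, int t1, int t2) const {
    Vec3 b1 = p1 - p0, b2 = p2 - p1, b3 = p3 - p2;
    Vec3 n1 = cross(b1, b2), n2 = cross(b2, b3);
    double ln1 = norm(n1), ln2 = norm(n2), lb2 = norm(b2);
    if (ln1 < 1e-10 || ln2 < 1e-10 || lb2 < 1e-12) {
      ++degenerate_torsions;  // collinear triple: dihedral undefined, term -> 0
      return 0.0;
    }
    double x = dot(n1, n2);
    double y = dot(cross(n1, n2), (1.0 / lb2) * b2);
    double phi = std::atan2(y, x);
    if (native_bonded) {
      double d = phi - ph0[k];
      return nat_k_dih1 * (1.0 - std::cos(d)) + nat_k_dih3 * (1.0 - std::cos(3.0 * d));
    }
    int p = t1 * 20 + t2;
    double e = 0.0;
    for (int nn = 0; nn < 4; ++nn)
      e += tor_amp[p * 4 + nn] * (1.0 + std::cos((nn + 1) * phi - tor_pha[p * 4 + nn]));
    return e;
  }

  // ---- totals ------------------------------------------------------------

  void total_energy(const std::vector<Vec3> &p, double out[5]) const {
    double eb = 0, en = 0, enn = 0, eel = 0;
    for (int i = 0; i < N - 1; ++i) eb += bond_term(p[i], p[i + 1]);
    for (int i = 1; i < N - 1; ++i) eb += angle_term(i, p[i - 1], p[i], p[i + 1]);
    for (int i = 0; i + 3 < N; ++i)
      eb += torsion_term(i, p[i], p[i + 1], p[i + 2], p[i + 3], seq[i + 1], seq[i + 2]);
    for (int i = 0; i < N; ++i)
      for (int j = i + 3; j < N; ++j) {
        double dx = p[i].x - p[j].x, dy = p[i].y - p[j].y, dz = p[i].z - p[j].z;
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < 0.01) Rcpp::stop("unphysical state: beads %d and %d overlap (r = %g A)",
                                  i + 1, j + 1, std::sqrt(r2));
        pair_energy_r2(i, j, r2, en, enn, eel);
      }
    out[0] = eb; out[1] = en; out[2] = enn; out[3] = eel;
    out[4] = eb + en + enn + eel;
  }

  // energy of all terms involving the contiguous window [a, b] (0-based),
  // evaluated on positions p; used for incremental Metropolis updates
  void window_energy(const std::vector<Vec3> &p, int a, int b, double out[4],
                     bool &overlap) const {
    double eb = 0, en = 0, enn = 0, eel = 0;
    overlap = false;
    int blo = std::max(0, a - 1), bhi = std::min(N - 2, b);
    for (int k = blo; k <= bhi; ++k) eb += bond_term(p[k], p[k + 1]);
    int alo = std::max(1, a - 1), ahi = std::min(N - 2, b + 1);
    for (int k = alo; k <= ahi; ++k) eb += angle_term(k, p[k - 1], p[k], p[k + 1]);
    int tlo = std::max(0, a - 3), thi = std::min(N - 4, b);
    for (int k = tlo; k <= thi; ++k)
      eb += torsion_term(k, p[k], p[k + 1], p[k + 2], p[k + 3], seq[k + 1], seq[k + 2]);
    // pairs with exactly one end inside [a, b]
    for (int i = a; i <= b; ++i) {
      const Vec3 &pi_ = p[i];
      for (int j = 0; j < a; ++j) {
        if (i - j < 3) continue;
        double dx = pi_.x - p[j].x, dy = pi_.y - p[j].y, dz = pi_.z - p[j].z;
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < 0.01) { overlap = true; return; }
        pair_energy_r2(j, i, r2, en, enn, eel);
      }
      for (int j = b + 1; j < N; ++j) {
        if (j - i < 3) continue;
        double dx = pi_.x - p[j].x, dy = pi_.y - p[j].y, dz = pi_.z - p[j].z;
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < 0.01) { overlap = true; return; }
        pair_energy_r2(i, j, r2, en, enn, eel);
      }
    }
    // pairs with both ends inside: only needed for non-rigid windows; a
    // single-bead window has none, and rigid windows preserve them exactly,
    // but include them whenever the window is small so the delta is exact
    if (b - a >= 3 && b - a <= 8) {
      for (int i = a; i <= b; ++i)
        for (int j = i + 3; j <= b; ++j) {
          double dx = p[i].x - p[j].x, dy = p[i].y - p[j].y, dz = p[i].z - p[j].z;
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 < 0.01) { overlap = true; return; }
          pair_energy_r2(i, j, r2, en, enn, eel);
        }
    }
    out[0] = eb; out[1] = en; out[2] = enn; out[3] = eel;
  }
};

#endif
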