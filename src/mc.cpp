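#include "kf_model.h"
using namespace Rcpp;

// ---- move proposals -------------------------------------------------------
// Each proposal yields a contiguous window [a, b] (0-based) of new positions.

struct Proposal {
  int a, b;
  std::vector<Vec3> newpos;
  bool rigid;
};

static bool propose_crankshaft(const std::vector<Vec3> &p, KfRng &rng, double amp,
                               Proposal &pr) {
  int N = (int)p.size();
  if (N < 3) return false;
  int i = 1 + rng.unif_int(N - 2);  // interior bead
  Vec3 axis = p[i + 1] - p[i - 1];
  double na = norm(axis);
  if (na < 1e-8) return false;
  double th = rng.unif(-amp, amp);
  pr.a = pr.b = i;
  pr.newpos.assign(1, rotate_about(p[i], p[i - 1], (1.0 / na) * axis, th));
  pr.rigid = false;
  return true;
}

static bool propose_cartesian(const std::vector<Vec3> &p, KfRng &rng, double radius,
                              Proposal &pr) {
  int N = (int)p.size();
  int i = rng.unif_int(N);
  pr.a = pr.b = i;
  pr.newpos.assign(1, p[i] + rng.in_ball(radius));
  pr.rigid = false;
  return true;
}

static bool propose_pivot(const std::vector<Vec3> &p, KfRng &rng, double amp,
                          Proposal &pr) {
  int N = (int)p.size();
  int i = rng.unif_int(N);
  bool suffix = rng.unif() < 0.5;
  int a, b;
  if (suffix) { a = i + 1; b = N - 1; } else { a = 0; b = i - 1; }
  if (a > b) return false;  // nothing to rotate
  Vec3 axis = rng.unit_sphere();
  double th = rng.unif(-amp, amp);
  pr.a = a; pr.b = b;
  pr.newpos.resize(b - a + 1);
  for (int k = a; k <= b; ++k) pr.newpos[k - a] = rotate_about(p[k], p[i], axis, th);
  pr.rigid = true;
  return true;
}

static bool propose_endpoint(const std::vector<Vec3> &p, KfRng &rng, double amp,
                             int seg_len, Proposal &pr) {
  int N = (int)p.size();
  if (N <= seg_len) return false;
  bool cterm = rng.unif() < 0.5;
  int pivot = cterm ? N - seg_len : seg_len - 1;  // most interior bead of the segment
  int a = cterm ? N - seg_len + 1 : 0;
  int b = cterm ? N - 1 : seg_len - 2;
  Vec3 axis = rng.unit_sphere();
  double th = rng.unif(-amp, amp);
  pr.a = a; pr.b = b;
  pr.newpos.resize(b - a + 1);
  for (int k = a; k <= b; ++k) pr.newpos[k - a] = rotate_about(p[k], p[pivot], axis, th);
  pr.rigid = true;
  return true;
}

// deterministic single-move wrappers for geometry tests ---------------------

// [[Rcpp::export(name = ".crankshaft_once_cpp")]]
NumericMatrix crankshaft_once_cpp(NumericMatrix coords, int bead, double angle) {
  std::vector<Vec3> p = mat_to_vec(coords);
  int i = bead - 1;
  Vec3 axis = unit(p[i + 1] - p[i - 1]);
  p[i] = rotate_about(p[i], p[i - 1], axis, angle);
  return vec_to_mat(p);
}

// [[Rcpp::export(name = ".segment_rotate_cpp")]]
NumericMatrix segment_rotate_cpp(NumericMatrix coords, int from, int to, int pivot,
                                 NumericVector axis, double angle) {
  std::vector<Vec3> p = mat_to_vec(coords);
  Vec3 ax = unit(Vec3(axis[0], axis[1], axis[2]));
  for (int k = from - 1; k <= to - 1; ++k)
    p[k] = rotate_about(p[k], p[pivot - 1], ax, angle);
  return vec_to_mat(p);
}

// [[Rcpp::export(name = ".draw_moves_cpp")]]
List draw_moves_cpp(NumericMatrix coords, int n, double cart_radius, int seed,
                    std::string kind) {
  // draws n independent proposals of one kind, reporting chosen bead /
  // terminus / displacement for distributional tests
  std::vector<Vec3> p = mat_to_vec(coords);
  KfRng rng((uint64_t)seed);
  NumericVector disp(n);
  IntegerVector which(n);
  for (int k = 0; k < n; ++k) {
    Proposal pr;
    if (kind == "cartesian") {
      propose_cartesian(p, rng, cart_radius, pr);
      disp[k] = dist(pr.newpos[0], p[pr.a]);
      which[k] = pr.a + 1;
    } else if (kind == "endpoint") {
      if (!propose_endpoint(p, rng, 0.5, 10, pr)) stop("chain too short");
      which[k] = pr.b == (int)p.size() - 1 ? 1 : 0;  // 1 = C-terminal
      disp[k] = 0;
    } else if (kind == "pivot") {
      if (!propose_pivot(p, rng, M_PI, pr)) { --k; continue; }
      which[k] = pr.b == (int)p.size() - 1 ? 1 : 0;  // 1 = suffix
      disp[k] = 0;
    } else stop("unknown kind");
  }
  return List::create(_["which"] = which, _["disp"] = disp);
}

// [[Rcpp::export(name = ".metropolis_trials_cpp")]]
double metropolis_trials_cpp(double delta_e, int n, int seed, double temperature = 1.0) {
  KfRng rng((uint64_t)seed);
  long acc = 0;
  for (int k = 0; k < n; ++k) {
    if (delta_e <= 0 || rng.unif() < std::exp(-delta_e / temperature)) ++acc;
  }
  return (double)acc / n;
}

// ---- crossing audit (shared with topology.cpp) ----------------------------
bool kf_audit_bead_move(const std::vector<Vec3> &chain, int i, const Vec3 &oldp,
                        const Vec3 &newp);

// implemented here against the current chain (open)
bool kf_audit_bead_move(const std::vector<Vec3> &chain, int i, const Vec3 &oldp,
                        const Vec3 &newp) {
  int n = (int)chain.size();
  int prev = i - 1, next = i + 1;
  for (int t = 0; t < 2; ++t) {
    int nb = t == 0 ? prev : next;
    if (nb < 0 || nb >= n) continue;
    const Vec3 &C = chain[nb];
    for (int j = 0; j < n - 1; ++j) {
      int j2 = j + 1;
      if (j == i || j2 == i) continue;
      bool sP = (dist(chain[j], C) < 1e-12);
      bool sQ = (dist(chain[j2], C) < 1e-12);
      Vec3 P = chain[j], Q = chain[j2];
      const double f = 1e-6;
      if (sP) P = P + f * (Q - P);
      if (sQ) Q = Q + f * (P - Q);
      if (tri_seg_intersect(oldp, newp, C, P, Q)) return true;
    }
  }
  return false;
}

// ---- trajectory runner ----------------------------------------------------

// [[Rcpp::export(name = ".run_mc_cpp")]]
List run_mc_cpp(NumericMatrix coords, List model, List config) {
  KfModel m; m.init(model);
  std::vector<Vec3> p = mat_to_vec(coords);
  int N = m.N;
  if ((int)p.size() != N) stop("coordinate/sequence length mismatch");

  double total_units = config["total_units"];
  double snap_int = config["snapshot_interval"];
  double log_int = config["log_interval"];
  double amp_crank = config["amp_crank"], amp_pivot = config["amp_pivot"];
  double amp_end = config["amp_end"], cart_radius = config["cart_radius"];
  int end_seg = config["end_seg_len"];
  NumericVector p1 = config["p_phase1"], p2 = config["p_phase2"];
  double piv_thresh = config["pivot_acc_threshold"];
  int piv_window = config["pivot_window"];
  double audit_frac = config["audit_frac"];
  double q_cut = config["q_cutoff"];
  double max_relax = config.containsElementNamed("max_relax_units") ?
      as<double>(config["max_relax_units"]) : R_PosInf;
  uint64_t seed = (uint64_t)as<double>(config["seed"]);
  double temperature = m.temperature;

  KfRng rng(seed);
  double E[5];
  m.total_energy(p, E);
  double cached[4] = {E[0], E[1], E[2], E[3]};

  long moves_per_unit = 100L * N;
  long total_moves = (long)(total_units * moves_per_unit);
  long snap_every = std::max(1L, (long)(snap_int * moves_per_unit));
  long log_every = std::max(1L, (long)(log_int * moves_per_unit));

  // pivot acceptance sliding window
  std::vector<char> piv_buf(piv_window, 0);
  int piv_n = 0, piv_head = 0, piv_acc_in_win = 0;
  int phase = 1;
  double switch_time = NA_REAL;

  long att[4] = {0, 0, 0, 0}, acc[4] = {0, 0, 0, 0};  // crank, cart, pivot, end
  long crossings = 0, audited = 0;

  std::vector<NumericMatrix> snaps;
  std::vector<double> snap_times;
  std::vector<std::vector<double> > logrows;

  auto q_now = [&]() {
    int M = (int)m.ci.size(), c = 0;
    for (int k = 0; k < M; ++k)
      if (dist(p[m.ci[k]], p[m.cj[k]]) < q_cut) ++c;
    return M > 0 ? (double)c / M : NA_REAL;
  };
  auto rg_now = [&]() {
    Vec3 c(0, 0, 0);
    for (int i = 0; i < N; ++i) c = c + p[i];
    c = (1.0 / N) * c;
    double s = 0;
    for (int i = 0; i < N; ++i) s += dot(p[i] - c, p[i] - c);
    return std::sqrt(s / N);
  };
  auto log_state = [&](double tnow) {
    std::vector<double> row = {tnow, cached[0], cached[1], cached[2], cached[3],
                               cached[0] + cached[1] + cached[2] + cached[3],
                               q_now(), rg_now(), (double)phase};
    logrows.push_back(row);
  };
  auto take_snap = [&](double tnow) {
    snaps.push_back(vec_to_mat(p));
    snap_times.push_back(tnow);
  };

  log_state(0.0);
  take_snap(0.0);

  Proposal pr;
  pr.newpos.reserve(N);
  std::vector<Vec3> oldw;
  oldw.reserve(N);

  for (long mv = 1; mv <= total_moves; ++mv) {
    if (phase == 1 && R_FINITE(max_relax) &&
        (double)mv / moves_per_unit >= max_relax) {
      phase = 2;
      switch_time = (double)mv / moves_per_unit;
    }
    double u = rng.unif();
    int kind;  // 0 crank, 1 cart, 2 pivot, 3 end
    if (phase == 1) kind = u < p1[0] ? 0 : (u < p1[0] + p1[1] ? 1 : 2);
    else kind = u < p2[0] ? 0 : (u < p2[0] + p2[1] ? 1 : 3);

    bool ok = false;
    switch (kind) {
      case 0: ok = propose_crankshaft(p, rng, amp_crank, pr); break;
      case 1: ok = propose_cartesian(p, rng, cart_radius, pr); break;
      case 2: ok = propose_pivot(p, rng, amp_pivot, pr); break;
      case 3: ok = propose_endpoint(p, rng, amp_end, end_seg, pr); break;
    }
    ++att[kind];
    bool accepted = false;
    if (ok) {
      double before[4], after[4];
      bool ov = false;
      m.window_energy(p, pr.a, pr.b, before, ov);
      oldw.assign(p.begin() + pr.a, p.begin() + pr.b + 1);
      for (int k = pr.a; k <= pr.b; ++k) p[k] = pr.newpos[k - pr.a];
      m.window_energy(p, pr.a, pr.b, after, ov);
      double dE = 0;
      if (ov) dE = R_PosInf;
      else for (int k = 0; k < 4; ++k) dE += after[k] - before[k];
      if (R_FINITE(dE) && (dE <= 0 || rng.unif() < std::exp(-dE / temperature))) {
        accepted = true;
        for (int k = 0; k < 4; ++k) cached[k] += after[k] - before[k];
        ++acc[kind];
        // a-posteriori crossing audit on a fraction of accepted local moves
        if ((kind == 0 || kind == 1) && audit_frac > 0 && rng.unif() < audit_frac) {
          ++audited;
          if (kf_audit_bead_move(p, pr.a, oldw[0], p[pr.a])) ++crossings;
        }
      } else {
        for (int k = pr.a; k <= pr.b; ++k) p[k] = oldw[k - pr.a];  // bit-exact restore
      }
    }
    if (kind == 2) {  // update pivot acceptance window
      if (piv_n == piv_window) piv_acc_in_win -= piv_buf[piv_head];
      piv_buf[piv_head] = accepted ? 1 : 0;
      piv_acc_in_win += piv_buf[piv_head];
      piv_head = (piv_head + 1) % piv_window;
      if (piv_n < piv_window) ++piv_n;
      if (phase == 1 && piv_n == piv_window &&
          (double)piv_acc_in_win / piv_window < piv_thresh) {
        phase = 2;
        switch_time = (double)mv / moves_per_unit;
      }
    }
    if (mv % log_every == 0) log_state((double)mv / moves_per_unit);
    if (mv % snap_every == 0) take_snap((double)mv / moves_per_unit);
    if (mv % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  // final full recomputation: drift diagnostic for the incremental updates
  double Efin[5];
  m.total_energy(p, Efin);
  double drift = std::fabs((cached[0] + cached[1] + cached[2] + cached[3]) - Efin[4]);

  NumericMatrix logm(logrows.size(), 9);
  for (size_t r = 0; r < logrows.size(); ++r)
    for (int c = 0; c < 9; ++c) logm(r, c) = logrows[r][c];
  colnames(logm) = CharacterVector::create("time", "bonded", "native", "nonnative",
                                           "electrostatic", "total", "Q", "Rg", "phase");

  List snl(snaps.size());
  for (size_t i = 0; i < snaps.size(); ++i) snl[i] = snaps[i];

  return List::create(
    _["final"] = vec_to_mat(p),
    _["log"] = logm,
    _["snapshots"] = snl,
    _["snapshot_times"] = NumericVector(snap_times.begin(), snap_times.end()),
    _["attempts"] = NumericVector::create(_["crankshaft"] = (double)att[0],
                                          _["cartesian"] = (double)att[1],
                                          _["pivot"] = (double)att[2],
                                          _["endpoint"] = (double)att[3]),
    _["accepts"] = NumericVector::create(_["crankshaft"] = (double)acc[0],
                                         _["cartesian"] = (double)acc[1],
                                         _["pivot"] = (double)acc[2],
                                         _["endpoint"] = (double)acc[3]),
    _["phase_switch_time"] = switch_time,
    _["energy_drift"] = drift,
    _["crossings_flagged"] = (double)crossings,
    _["moves_audited"] = (double)audited,
    _["final_energy"] = NumericVector::create(
        _["bonded"] = Efin[0], _["native"] = Efin[1], _["nonnative"] = Efin[2],
        _["electrostatic"] = Efin[3], _["total"] = Efin[4]));
}

// ---- 3-bead pseudo-angle sampler (Boltzmann correctness check) ------------

// [[Rcpp::export(name = ".sample_angle_chain_cpp")]]
NumericVector sample_angle_chain_cpp(List model, int n_samples, int thin,
                                     double cart_radius, int seed) {
  KfModel m; m.init(model);
  if (m.N != 3) stop("sampler requires a 3-bead model");
  std::vector<Vec3> p(3);
  p[0] = Vec3(0, 0, 0); p[1] = Vec3(m.b0, 0, 0); p[2] = Vec3(2 * m.b0, 0.5, 0);
  KfRng rng((uint64_t)seed);
  NumericVector out(n_samples);
  double temperature = m.temperature;
  auto energy = [&]() {
    return m.bond_term(p[0], p[1]) + m.bond_term(p[1], p[2]) +
           m.angle_term(1, p[0], p[1], p[2]);
  };
  double E = energy();
  long burn = 2000;
  long total = burn + (long)n_samples * thin;
  int got = 0;
  for (long mv = 0; mv < total; ++mv) {
    int i = rng.unif_int(3);
    Vec3 old = p[i];
    p[i] = p[i] + rng.in_ball(cart_radius);
    double En = energy();
    if (En <= E || rng.unif() < std::exp(-(En - E) / temperature)) E = En;
    else p[i] = old;
    if (mv >= burn && (mv - burn) % thin == 0 && got < n_samples) {
      Vec3 u = p[0] - p[1], v = p[2] - p[1];
      double ct = dot(u, v) / (norm(u) * norm(v));
      out[got++] = std::acos(std::max(-1.0, std::min(1.0, ct)));
    }
  }
  return out;
}
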