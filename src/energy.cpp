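#include "kf_model.h"
using namespace Rcpp;

// [[Rcpp::export(name = ".total_energy_cpp")]]
NumericVector total_energy_cpp(NumericMatrix coords, List model) {
  KfModel m; m.init(model);
  std::vector<Vec3> p = mat_to_vec(coords);
  if ((int)p.size() != m.N) stop("coordinate/sequence length mismatch");
  double out[5];
  m.total_energy(p, out);
  NumericVector r = NumericVector::create(
    _["bonded"] = out[0], _["native"] = out[1], _["nonnative"] = out[2],
    _["electrostatic"] = out[3], _["total"] = out[4]);
  r.attr("degenerate_torsions") = (double)m.degenerate_torsions;
  return r;
}

// [[Rcpp::export(name = ".bonded_energy_cpp")]]
NumericVector bonded_energy_cpp(NumericMatrix coords, List model) {
  KfModel m; m.init(model);
  std::vector<Vec3> p = mat_to_vec(coords);
  double eb = 0, ea = 0, et = 0;
  for (int i = 0; i < m.N - 1; ++i) eb += m.bond_term(p[i], p[i + 1]);
  for (int i = 1; i < m.N - 1; ++i) ea += m.angle_term(i, p[i - 1], p[i], p[i + 1]);
  for (int i = 0; i + 3 < m.N; ++i)
    et += m.torsion_term(i, p[i], p[i + 1], p[i + 2], p[i + 3], m.seq[i + 1], m.seq[i + 2]);
  NumericVector r = NumericVector::create(
    _["bond"] = eb, _["angle"] = ea, _["torsion"] = et, _["total"] = eb + ea + et);
  r.attr("degenerate_torsions") = (double)m.degenerate_torsions;
  return r;
}

// Incremental energy difference for a contiguous window move: new coordinates
// for beads [a, b] (1-based), everything else unchanged.
// [[Rcpp::export(name = ".local_delta_cpp")]]
NumericVector local_delta_cpp(NumericMatrix coords, NumericMatrix new_window,
                              int a, int b, List model) {
  KfModel m; m.init(model);
  std::vector<Vec3> p = mat_to_vec(coords);
  int a0 = a - 1, b0 = b - 1;
  double before[4], after[4];
  bool ov = false;
  m.window_energy(p, a0, b0, before, ov);
  if (ov) stop("unphysical starting state: bead overlap");
  for (int i = a0; i <= b0; ++i)
    p[i] = Vec3(new_window(i - a0, 0), new_window(i - a0, 1), new_window(i - a0, 2));
  m.window_energy(p, a0, b0, after, ov);
  if (ov)
    return NumericVector::create(_["bonded"] = R_PosInf, _["native"] = R_PosInf,
                                 _["nonnative"] = R_PosInf, _["electrostatic"] = R_PosInf,
                                 _["total"] = R_PosInf);
  double d[4];
  for (int k = 0; k < 4; ++k) d[k] = after[k] - before[k];
  return NumericVector::create(_["bonded"] = d[0], _["native"] = d[1],
                               _["nonnative"] = d[2], _["electrostatic"] = d[3],
                               _["total"] = d[0] + d[1] + d[2] + d[3]);
}

// Interaction energy between a residue segment [from, to] (1-based) and the
// rest of the chain, restricted to one component: non-native quasi-chemical
// pairs or electrostics, |i - j| >= 3, native pairs excluded from the
// non-native sum.
// [[Rcpp::export(name = ".segment_energy_cpp")]]
double segment_energy_cpp(NumericMatrix coords, List model, int from, int to,
                          std::string mode) {
  KfModel m; m.init(model);
  std::vector<Vec3> p = mat_to_vec(coords);
  int a = from - 1, b = to - 1;
  bool want_nn = (mode == "nonnative");
  if (!want_nn && mode != "electrostatic") stop("mode must be nonnative or electrostatic");
  double e = 0.0;
  for (int i = a; i <= b; ++i)
    for (int j = 0; j < m.N; ++j) {
      if (j >= a && j <= b) continue;
      if (std::abs(i - j) < 3) continue;
      double r = dist(p[i], p[j]);
      if (want_nn) {
        if (m.nat_id[(size_t)i * m.N + j] >= 0) continue;
        if (m.native_only) {
          if (r < 2.5 * m.ev_sigma) e += KfModel::ev_repulsion(r, m.ev_sigma, m.ev_eps);
        } else {
          double sig = m.sig_ij(i, j);
          if (r < m.nn_cut_factor * sig)
            e += KfModel::kh_nonnative(r, sig, m.nn_eps[m.seq[i] * 20 + m.seq[j]]);
        }
      } else {
        e += m.elec(r, i, j);
      }
    }
  return e;
}

// vectorized pair-potential evaluators (for tests and plotting)

// [[Rcpp::export(name = ".native_pair_energy_cpp")]]
NumericVector native_pair_energy_cpp(NumericVector r, double r0, double eps) {
  NumericVector out(r.size());
  for (int i = 0; i < r.size(); ++i) out[i] = KfModel::go_native(r[i], r0, eps);
  return out;
}

// [[Rcpp::export(name = ".nonnative_pair_energy_cpp")]]
NumericVector nonnative_pair_energy_cpp(NumericVector r, double sigma, double eps) {
  NumericVector out(r.size());
  for (int i = 0; i < r.size(); ++i) out[i] = KfModel::kh_nonnative(r[i], sigma, eps);
  return out;
}

// [[Rcpp::export(name = ".angle_potential_cpp")]]
NumericVector angle_potential_cpp(NumericVector theta, List bonded) {
  double g = bonded["ang_gamma"], ka = bonded["ang_k_alpha"], ta = bonded["ang_theta_alpha"];
  double ea0 = bonded["ang_eps_alpha"], kb = bonded["ang_k_beta"], tb = bonded["ang_theta_beta"];
  NumericVector out(theta.size());
  for (int i = 0; i < theta.size(); ++i) {
    double da = theta[i] - ta, db = theta[i] - tb;
    double ea = ka * da * da + ea0, eb = kb * db * db;
    double mn = std::min(ea, eb);
    out[i] = mn - std::log(std::exp(-g * (ea - mn)) + std::exp(-g * (eb - mn))) / g;
  }
  return out;
}
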