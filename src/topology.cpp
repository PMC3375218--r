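#include "kf_common.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// KMT-style chain rectification: repeatedly delete vertex i when the triangle
// (i-1, i, i+1) is pierced by no other chain segment; preserves the knot type
// of the (open or closed) chain while drastically shrinking the vertex count.
// ---------------------------------------------------------------------------

// segments incident to the triangle corners are tested with the shared end
// pulled back slightly so that mere vertex contact does not count as piercing
static bool seg_blocks_triangle(const Vec3 &A, const Vec3 &B, const Vec3 &C,
                                Vec3 P, Vec3 Q, bool shrinkP, bool shrinkQ) {
  const double f = 1e-6;
  if (shrinkP) P = P + f * (Q - P);
  if (shrinkQ) Q = Q + f * (P - Q);
  return tri_seg_intersect(A, B, C, P, Q);
}

static void kmt_pass(std::vector<Vec3> &pts, std::vector<int> &idx, bool closed,
                     bool &changed) {
  changed = false;
  int n = (int)pts.size();
  int i = closed ? 0 : 1;
  while (true) {
    n = (int)pts.size();
    if (closed ? (n <= 3) : (n <= 2)) return;
    if (closed ? (i >= n) : (i >= n - 1)) return;
    int a = (i - 1 + n) % n, b = (i + 1) % n;
    if (!closed && (i == 0 || i == n - 1)) { ++i; continue; }
    const Vec3 &A = pts[a], &I = pts[i], &B = pts[b];
    bool blocked = false;
    for (int j = 0; j < (closed ? n : n - 1) && !blocked; ++j) {
      int j2 = (j + 1) % n;
      if (j == a || j == i) continue;                 // segments (a,i) and (i,b)
      if (j2 == a || j == b) {                        // segments touching a or b
        bool sP = (j == b);                           // shared vertex at P end
        bool sQ = (j2 == a);
        if (seg_blocks_triangle(A, I, B, pts[j], pts[j2], sP, sQ)) blocked = true;
        continue;
      }
      if (tri_seg_intersect(A, I, B, pts[j], pts[j2])) blocked = true;
    }
    if (!blocked) {
      pts.erase(pts.begin() + i);
      idx.erase(idx.begin() + i);
      changed = true;
      // do not advance: the next vertex slides into slot i
    } else {
      ++i;
    }
  }
}

// [[Rcpp::export(name = ".kmt_simplify_cpp")]]
List kmt_simplify_cpp(NumericMatrix coords, bool closed) {
  std::vector<Vec3> pts = mat_to_vec(coords);
  std::vector<int> idx(pts.size());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = (int)(i + 1);  // 1-based
  bool changed = true;
  int guard = 0;
  while (changed && ++guard < 10000) kmt_pass(pts, idx, closed, changed);
  return List::create(_["coords"] = vec_to_mat(pts),
                      _["orig_index"] = IntegerVector(idx.begin(), idx.end()));
}

// ---------------------------------------------------------------------------
// Alexander determinants |Delta(-1)|, |Delta(-2)| of a closed polygon, from
// the crossing pattern of a generic planar projection.
// ---------------------------------------------------------------------------

struct Crossing {
  double under_pos;  // traversal parameter (segment index + fraction) of under strand
  double over_pos;
  int sign;          // +1 / -1 crossing handedness
};

// returns false if the projection is non-generic and must be retried
static bool find_crossings(const std::vector<Vec3> &pts, const Vec3 &dir,
                           std::vector<Crossing> &out) {
  out.clear();
  int n = (int)pts.size();
  // orthonormal basis
  Vec3 w = unit(dir);
  Vec3 any = std::fabs(w.x) < 0.9 ? Vec3(1, 0, 0) : Vec3(0, 1, 0);
  Vec3 u = unit(cross(w, any)), v = cross(w, u);
  std::vector<double> px(n), py(n), ph(n);
  for (int i = 0; i < n; ++i) {
    px[i] = dot(pts[i], u); py[i] = dot(pts[i], v); ph[i] = dot(pts[i], w);
  }
  const double eps = 1e-9;
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 1; j < n; ++j) {
      int j2 = (j + 1) % n;
      if (j == i || j2 == i || j == i2) continue;  // adjacent segments
      double rx = px[i2] - px[i], ry = py[i2] - py[i];
      double sx = px[j2] - px[j], sy = py[j2] - py[j];
      double den = rx * sy - ry * sx;
      double qpx = px[j] - px[i], qpy = py[j] - py[i];
      if (std::fabs(den) < eps) {
        // parallel in projection: if they also overlap we must retry
        double c1 = qpx * ry - qpy * rx;
        if (std::fabs(c1) < eps) return false;
        continue;
      }
      double t = (qpx * sy - qpy * sx) / den;
      double s2 = (qpx * ry - qpy * rx) / den;
      if (t <= -eps || t >= 1 + eps || s2 <= -eps || s2 >= 1 + eps) continue;
      if (t < eps || t > 1 - eps || s2 < eps || s2 > 1 - eps) return false;  // endpoint hit
      double hi = ph[i] + t * (ph[i2] - ph[i]);
      double hj = ph[j] + s2 * (ph[j2] - ph[j]);
      if (std::fabs(hi - hj) < eps) return false;  // strands touch in 3-D? degenerate
      Crossing c;
      bool i_over = hi > hj;
      double posi = i + t, posj = j + s2;
      // crossing sign: orientation of (over direction, under direction)
      double cz = rx * sy - ry * sx;  // cross of segment i dir with segment j dir
      int sgn = i_over ? (cz > 0 ? 1 : -1) : (cz > 0 ? 1 : -1);
      // sign convention: sign of det[d_over, d_under]
      if (!i_over) sgn = -sgn;
      c.sign = sgn;
      c.under_pos = i_over ? posj : posi;
      c.over_pos = i_over ? posi : posj;
      out.push_back(c);
    }
  }
  return true;
}

static double det_abs(std::vector<std::vector<double> > m) {
  int n = (int)m.size();
  if (n == 0) return 1.0;
  double det = 1.0;
  for (int c = 0; c < n; ++c) {
    int piv = -1; double best = 0;
    for (int r = c; r < n; ++r)
      if (std::fabs(m[r][c]) > best) { best = std::fabs(m[r][c]); piv = r; }
    if (piv < 0 || best < 1e-12) return 0.0;
    if (piv != c) { std::swap(m[piv], m[c]); det = -det; }
    det *= m[c][c];
    for (int r = c + 1; r < n; ++r) {
      double f = m[r][c] / m[c][c];
      for (int k = c; k < n; ++k) m[r][k] -= f * m[c][k];
    }
  }
  return std::fabs(det);
}

// Alexander determinant |Delta(t)| from the ordered underpass list.
static double alexander_at(const std::vector<Crossing> &cr, double t) {
  int n = (int)cr.size();
  if (n <= 1) return 1.0;
  // underpasses sorted by traversal position
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return cr[a].under_pos < cr[b].under_pos;
  });
  std::vector<double> upos(n);
  for (int k = 0; k < n; ++k) upos[k] = cr[ord[k]].under_pos;
  // generator arcs: arc k (0-based) runs from underpass k to underpass k+1;
  // the arc containing traversal position p is the largest k with upos[k] < p
  auto arc_of = [&](double p) {
    int lo = 0, hi = n;  // find first upos > p
    while (lo < hi) { int mid = (lo + hi) / 2; if (upos[mid] < p) lo = mid + 1; else hi = mid; }
    return (lo - 1 + n) % n;  // arc starting at underpass lo-1
  };
  std::vector<std::vector<double> > M(n, std::vector<double>(n, 0.0));
  for (int k = 0; k < n; ++k) {
    const Crossing &c = cr[ord[k]];
    int k1 = (k + 1) % n;
    // over-arc index: incoming under-arc is arc k-1 -> ends at underpass k.
    // Generator numbering: generator g_k = arc starting at underpass k.
    int io = arc_of(c.over_pos);
    int gin = (k - 1 + n) % n;   // generator of incoming under strand
    int gout = k;                // generator of outgoing under strand
    if (io == gin || io == gout) {
      M[k][gin] += -1.0;
      M[k][gout] += 1.0;
    } else if (c.sign > 0) {
      M[k][gin] += 1.0;
      M[k][gout] += -t;
      M[k][io] += t - 1.0;
    } else {
      M[k][gin] += -t;
      M[k][gout] += 1.0;
      M[k][io] += t - 1.0;
    }
  }
  // delete last row and column
  std::vector<std::vector<double> > Mm(n - 1, std::vector<double>(n - 1));
  for (int r = 0; r < n - 1; ++r)
    for (int cI = 0; cI < n - 1; ++cI) Mm[r][cI] = M[r][cI];
  return det_abs(Mm);
}

static long normalize_det(double d, double t) {
  long v = (long)std::llround(d);
  if (v <= 0) v = 1;
  long base = (long)std::llround(std::fabs(t));
  if (base >= 2) {
    while (v % base == 0) v /= base;  // Delta defined up to +/- t^k
  }
  return v;
}

// [[Rcpp::export(name = ".alexander_cpp")]]
IntegerVector alexander_cpp(NumericMatrix ring, int max_retries = 50,
                            int proj_seed = 12345) {
  std::vector<Vec3> pts0 = mat_to_vec(ring);
  // simplify first: far fewer crossings, and determinants stay in double range
  {
    std::vector<int> idx(pts0.size());
    for (size_t i = 0; i < idx.size(); ++i) idx[i] = (int)i;
    bool ch = true; int guard = 0;
    while (ch && ++guard < 10000) kmt_pass(pts0, idx, true, ch);
  }
  if ((int)pts0.size() <= 3) return IntegerVector::create(1, 1);
  KfRng rng((uint64_t)proj_seed);
  std::vector<Crossing> cr;
  for (int attempt = 0; attempt < max_retries; ++attempt) {
    Vec3 dir = attempt == 0 ? Vec3(0.137, 0.377, 0.917) : rng.unit_sphere();
    if (find_crossings(pts0, unit(dir), cr)) {
      long d1 = normalize_det(alexander_at(cr, -1.0), 1.0);   // |Delta(-1)| exact
      long d2 = normalize_det(alexander_at(cr, -2.0), -2.0);  // |Delta(-2)| mod powers of 2
      return IntegerVector::create((int)d1, (int)d2);
    }
  }
  stop("no generic projection found after %d retries", max_retries);
}

// ---------------------------------------------------------------------------
// Gauss writhe of a closed polygon (Klenin-Vologodskii exact segment-pair
// solid-angle formula); its sign on a trefoil core gives the handedness.
// ---------------------------------------------------------------------------

static double writhe_pair(const Vec3 &p1, const Vec3 &p2, const Vec3 &p3, const Vec3 &p4) {
  Vec3 r13 = p3 - p1, r14 = p4 - p1, r23 = p3 - p2, r24 = p4 - p2;
  Vec3 n1 = cross(r13, r14), n2 = cross(r14, r24), n3 = cross(r24, r23), n4 = cross(r23, r13);
  double l1 = norm(n1), l2 = norm(n2), l3 = norm(n3), l4 = norm(n4);
  if (l1 < 1e-12 || l2 < 1e-12 || l3 < 1e-12 || l4 < 1e-12) return 0.0;
  n1 = (1 / l1) * n1; n2 = (1 / l2) * n2; n3 = (1 / l3) * n3; n4 = (1 / l4) * n4;
  auto asafe = [](double x) { return std::asin(std::max(-1.0, std::min(1.0, x))); };
  double omega = asafe(dot(n1, n2)) + asafe(dot(n2, n3)) +
                 asafe(dot(n3, n4)) + asafe(dot(n4, n1));
  Vec3 r34 = p4 - p3, r12 = p2 - p1;
  double sgn = dot(cross(r34, r12), r13) >= 0 ? 1.0 : -1.0;
  return omega * sgn / (4.0 * M_PI);
}

// [[Rcpp::export(name = ".writhe_cpp")]]
double writhe_cpp(NumericMatrix coords, bool closed) {
  std::vector<Vec3> p = mat_to_vec(coords);
  int n = (int)p.size();
  int nseg = closed ? n : n - 1;
  double w = 0.0;
  for (int i = 0; i < nseg; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 2; j < nseg; ++j) {
      int j2 = (j + 1) % n;
      if (j2 == i) continue;  // adjacent around the ring
      w += 2.0 * writhe_pair(p[i], p[i2], p[j], p[j2]);
    }
  }
  return w;
}

// ---------------------------------------------------------------------------
// A-posteriori chain-crossing detection for single-bead moves: the swept
// triangles (old bead, new bead, fixed neighbour) must not be pierced by any
// non-adjacent chain segment.
// ---------------------------------------------------------------------------

static bool bead_move_crosses(const std::vector<Vec3> &chain, bool closed,
                              int i, const Vec3 &oldp, const Vec3 &newp) {
  int n = (int)chain.size();
  int nseg = closed ? n : n - 1;
  int prev = (i - 1 + n) % n, next = (i + 1) % n;
  bool has_prev = closed || i > 0, has_next = closed || i < n - 1;
  for (int t = 0; t < 2; ++t) {
    if (t == 0 && !has_prev) continue;
    if (t == 1 && !has_next) continue;
    Vec3 A = oldp, B = newp, C = chain[t == 0 ? prev : next];
    for (int j = 0; j < nseg; ++j) {
      int j2 = (j + 1) % n;
      if (j == i || j2 == i) continue;           // segments at the moved bead
      if (j == prev || j2 == prev || j == next || j2 == next) {
        // shares the fixed neighbour vertex: pull back the shared end
        Vec3 P = chain[j], Q = chain[j2];
        bool sP = (j == prev || j == next) && ((t == 0 && j == prev) || (t == 1 && j == next) ||
                                               dist(chain[j], C) < 1e-12);
        bool sQ = (j2 == prev || j2 == next) && (dist(chain[j2], C) < 1e-12);
        (void)sP; (void)sQ;
        if (seg_blocks_triangle(A, B, C, P, Q,
                                dist(P, C) < 1e-12, dist(Q, C) < 1e-12))
          return true;
        continue;
      }
      if (tri_seg_intersect(A, B, C, chain[j], chain[j2])) return true;
    }
  }
  return false;
}

// [[Rcpp::export(name = ".detect_crossing_cpp")]]
bool detect_crossing_cpp(NumericMatrix before, NumericMatrix after,
                         IntegerVector moved, bool closed = false) {
  std::vector<Vec3> b = mat_to_vec(before), a = mat_to_vec(after);
  // audit each moved bead against the *unmoved* environment: use the "after"
  // chain but with the moved bead itself swept from old to new
  for (int k = 0; k < moved.size(); ++k) {
    int i = moved[k] - 1;  // 1-based in R
    if (dist(a[i], b[i]) < 1e-14) continue;
    std::vector<Vec3> env = a;
    env[i] = b[i];  // neighbours at new positions; bead i still old
    if (bead_move_crosses(env, closed, i, b[i], a[i])) return true;
  }
  return false;
}

// ---------------------------------------------------------------------------
// Topology-conservation workhorse: evolve a closed ring by random single-
// vertex displacements, rejecting any move that sweeps through another
// segment or distorts the adjacent bonds beyond bounds.  Used to certify
// that the crossing auditor preserves knot type over ~1e6 moves.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".evolve_ring_cpp")]]
List evolve_ring_cpp(NumericMatrix coords, int n_moves, double max_disp,
                     double bond_lo, double bond_hi, int seed) {
  std::vector<Vec3> p = mat_to_vec(coords);
  int n = (int)p.size();
  KfRng rng((uint64_t)seed);
  long accepted = 0, rejected_bond = 0, rejected_cross = 0;
  for (int m = 0; m < n_moves; ++m) {
    int i = rng.unif_int(n);
    Vec3 d = rng.in_ball(max_disp);
    Vec3 np = p[i] + d;
    int prev = (i - 1 + n) % n, next = (i + 1) % n;
    double b1 = dist(np, p[prev]), b2 = dist(np, p[next]);
    if (b1 < bond_lo || b1 > bond_hi || b2 < bond_lo || b2 > bond_hi) {
      ++rejected_bond; continue;
    }
    if (bead_move_crosses(p, true, i, p[i], np)) { ++rejected_cross; continue; }
    p[i] = np;
    ++accepted;
  }
  return List::create(_["coords"] = vec_to_mat(p),
                      _["accepted"] = (double)accepted,
                      _["rejected_bond"] = (double)rejected_bond,
                      _["rejected_crossing"] = (double)rejected_cross);
}

// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".gyration_radius_cpp")]]
double gyration_radius_cpp(NumericMatrix coords) {
  int n = coords.nrow();
  if (n == 0) return 0.0;
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < n; ++i) { cx += coords(i, 0); cy += coords(i, 1); cz += coords(i, 2); }
  cx /= n; cy /= n; cz /= n;
  double s = 0;
  for (int i = 0; i < n; ++i) {
    double dx = coords(i, 0) - cx, dy = coords(i, 1) - cy, dz = coords(i, 2) - cz;
    s += dx * dx + dy * dy + dz * dz;
  }
  return std::sqrt(s / n);
}
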