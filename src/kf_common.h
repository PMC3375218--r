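#ifndef KF_COMMON_H
#define KF_COMMON_H

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

// ---- small 3-vector ------------------------------------------------------

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
};

inline Vec3 operator+(const Vec3 &a, const Vec3 &b) { return Vec3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline Vec3 operator-(const Vec3 &a, const Vec3 &b) { return Vec3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline Vec3 operator*(double s, const Vec3 &a) { return Vec3(s * a.x, s * a.y, s * a.z); }
inline double dot(const Vec3 &a, const Vec3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }
inline double dist(const Vec3 &a, const Vec3 &b) { return norm(a - b); }
inline Vec3 unit(const Vec3 &a) {
  double n = norm(a);
  return n > 0 ? (1.0 / n) * a : Vec3(0, 0, 0);
}

// Rodrigues rotation of point p about an axis (unit vector k) through origin o
inline Vec3 rotate_about(const Vec3 &p, const Vec3 &o, const Vec3 &k, double theta) {
  Vec3 v = p - o;
  double c = std::cos(theta), s = std::sin(theta);
  Vec3 r = c * v + s * cross(k, v) + (dot(k, v) * (1.0 - c)) * k;
  return o + r;
}

inline std::vector<Vec3> mat_to_vec(const Rcpp::NumericMatrix &m) {
  std::vector<Vec3> v(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) v[i] = Vec3(m(i, 0), m(i, 1), m(i, 2));
  return v;
}

inline Rcpp::NumericMatrix vec_to_mat(const std::vector<Vec3> &v) {
  Rcpp::NumericMatrix m(v.size(), 3);
  for (size_t i = 0; i < v.size(); ++i) { m(i, 0) = v[i].x; m(i, 1) = v[i].y; m(i, 2) = v[i].z; }
  return m;
}

// ---- deterministic RNG ---------------------------------------------------
// Self-contained 64-bit generator (splitmix-seeded xoshiro256**) so that
// trajectories are bit-reproducible for a given seed across platforms,
// independent of the C++ standard library's distribution implementations.

struct KfRng {
  uint64_t s[4];
  explicit KfRng(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double unif(double a, double b) { return a + (b - a) * unif(); }
  int unif_int(int n) { return (int)(unif() * n) % n; }  // 0..n-1
  Vec3 unit_sphere() {
    // Marsaglia rejection
    for (;;) {
      double u = unif(-1, 1), v = unif(-1, 1);
      double s2 = u * u + v * v;
      if (s2 < 1.0 && s2 > 1e-12) {
        double f = 2.0 * std::sqrt(1.0 - s2);
        return Vec3(u * f, v * f, 1.0 - 2.0 * s2);
      }
    }
  }
  Vec3 in_ball(double radius) {
    for (;;) {
      double x = unif(-1, 1), y = unif(-1, 1), z = unif(-1, 1);
      if (x * x + y * y + z * z <= 1.0)
        return Vec3(radius * x, radius * y, radius * z);
    }
  }
};

// ---- geometric predicates -------------------------------------------------

// Does segment PQ intersect triangle ABC?  Conservative on coplanar/edge
// cases (reports an intersection), except that degenerate (area ~ 0)
// triangles obstruct nothing.
inline bool tri_seg_intersect(const Vec3 &A, const Vec3 &B, const Vec3 &C,
                              const Vec3 &P, const Vec3 &Q, double eps = 1e-10) {
  Vec3 n = cross(B - A, C - A);
  double nn = norm(n);
  double scale = dist(A, B) + dist(A, C) + 1e-30;
  if (nn < eps * scale * scale) return false;  // degenerate triangle: no spanned disc
  n = (1.0 / nn) * n;
  double dP = dot(n, P - A), dQ = dot(n, Q - A);
  double seg = dist(P, Q) + 1e-30;
  double tol = eps * seg;
  if (dP > tol && dQ > tol) return false;
  if (dP < -tol && dQ < -tol) return false;
  if (std::fabs(dP - dQ) < 1e-14 * seg) {
    // segment (nearly) parallel to the triangle plane
    if (std::fabs(dP) > tol) return false;
    // coplanar: conservative 2-D overlap test by edge crossings / containment
    Vec3 u = unit(B - A), w = unit(cross(n, u));
    double px = dot(P - A, u), py = dot(P - A, w);
    double qx = dot(Q - A, u), qy = dot(Q - A, w);
    double ax = 0, ay = 0, bx = dot(B - A, u), by = dot(B - A, w);
    double cx = dot(C - A, u), cy = dot(C - A, w);
    auto cross2 = [](double ox, double oy, double ax_, double ay_, double bx_, double by_) {
      return (ax_ - ox) * (by_ - oy) - (ay_ - oy) * (bx_ - ox);
    };
    auto seg2 = [&](double x1, double y1, double x2, double y2,
                    double x3, double y3, double x4, double y4) {
      double d1 = cross2(x3, y3, x4, y4, x1, y1);
      double d2 = cross2(x3, y3, x4, y4, x2, y2);
      double d3 = cross2(x1, y1, x2, y2, x3, y3);
      double d4 = cross2(x1, y1, x2, y2, x4, y4);
      return ((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0));
    };
    if (seg2(px, py, qx, qy, ax, ay, bx, by)) return true;
    if (seg2(px, py, qx, qy, bx, by, cx, cy)) return true;
    if (seg2(px, py, qx, qy, cx, cy, ax, ay)) return true;
    // containment of P
    double s1 = cross2(ax, ay, bx, by, px, py);
    double s2 = cross2(bx, by, cx, cy, px, py);
    double s3 = cross2(cx, cy, ax, ay, px, py);
    return (s1 >= 0 && s2 >= 0 && s3 >= 0) || (s1 <= 0 && s2 <= 0 && s3 <= 0);
  }
  double t = dP / (dP - dQ);
  if (t < -eps || t > 1 + eps) return false;
  Vec3 X = P + t * (Q - P);
  // barycentric containment with small tolerance
  Vec3 v0 = B - A, v1 = C - A, v2 = X - A;
  double d00 = dot(v0, v0), d01 = dot(v0, v1), d11 = dot(v1, v1);
  double d20 = dot(v2, v0), d21 = dot(v2, v1);
  double den = d00 * d11 - d01 * d01;
  if (std::fabs(den) < 1e-30) return false;
  double v = (d11 * d20 - d01 * d21) / den;
  double w = (d00 * d21 - d01 * d20) / den;
  double u = 1.0 - v - w;
  double btol = 1e-9;
  return (u >= -btol && v >= -btol && w >= -btol);
}

#endif
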