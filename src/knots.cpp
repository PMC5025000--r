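// Topological analysis of closed polygonal curves:
//  - centre-of-mass triangle closure of open chains
//  - Koniaris-Muthukumar topology-preserving vertex elision
//  - Alexander polynomial determinants |Delta(-1)|, |Delta(-2)| from a
//    generic planar projection of the crossing diagram
//
// Determinant convention: the Alexander matrix determinant equals
// +/- t^k * Delta(t).  At t = -1 the unit t^k has modulus 1, so |det| is the
// knot determinant directly.  At t = -2 the result carries a factor 2^k,
// which is stripped by dividing out all factors of two (Delta(1) = +/-1
// forces the remaining odd part to be well defined).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

typedef std::array<double, 3> V3;

static inline V3 sub(const V3& a, const V3& b) {
  return V3{a[0] - b[0], a[1] - b[1], a[2] - b[2]};
}
static inline V3 add(const V3& a, const V3& b) {
  return V3{a[0] + b[0], a[1] + b[1], a[2] + b[2]};
}
static inline V3 scale(const V3& a, double s) {
  return V3{a[0] * s, a[1] * s, a[2] * s};
}
static inline double dot(const V3& a, const V3& b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline V3 cross(const V3& a, const V3& b) {
  return V3{a[1] * b[2] - a[2] * b[1],
            a[2] * b[0] - a[0] * b[2],
            a[0] * b[1] - a[1] * b[0]};
}
static inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

static std::vector<V3> mat_to_vec(const NumericMatrix& m) {
  std::vector<V3> v(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) v[i] = V3{m(i, 0), m(i, 1), m(i, 2)};
  return v;
}
static NumericMatrix vec_to_mat(const std::vector<V3>& v) {
  NumericMatrix m(v.size(), 3);
  for (size_t i = 0; i < v.size(); ++i) {
    m(i, 0) = v[i][0]; m(i, 1) = v[i][1]; m(i, 2) = v[i][2];
  }
  return m;
}

// ---------------------------------------------------------------------------
// COM-triangle closure

// minimal distance between segments (p0,p1) and (q0,q1)
static double seg_seg_dist(const V3& p0, const V3& p1,
                           const V3& q0, const V3& q1) {
  V3 u = sub(p1, p0), v = sub(q1, q0), w = sub(p0, q0);
  double a = dot(u, u), b = dot(u, v), c = dot(v, v);
  double d = dot(u, w), e = dot(v, w);
  double D = a * c - b * b;
  double sc, tc;
  if (D < 1e-14 * a * c + 1e-300) {  // nearly parallel
    sc = 0.0;
    tc = (c > 0 ? e / c : 0.0);
  } else {
    sc = (b * e - c * d) / D;
    tc = (a * e - b * d) / D;
  }
  sc = std::min(1.0, std::max(0.0, sc));
  tc = std::min(1.0, std::max(0.0, tc));
  // re-clamp the other parameter after clamping one
  V3 ps = add(p0, scale(u, sc));
  double t2 = c > 0 ? dot(sub(ps, q0), v) / c : 0.0;
  t2 = std::min(1.0, std::max(0.0, t2));
  V3 qt = add(q0, scale(v, t2));
  double s2 = a > 0 ? dot(sub(qt, p0), u) / a : 0.0;
  s2 = std::min(1.0, std::max(0.0, s2));
  V3 ps2 = add(p0, scale(u, s2));
  return norm(sub(ps2, qt));
}

// does the extension segment from chain end `e` to far point `f` pass within
// tol of any chain segment (ignoring contact at `e` itself)?
static bool extension_interferes(const std::vector<V3>& r, const V3& e,
                                 const V3& f, double tol) {
  int n = (int)r.size();
  for (int k = 0; k < n - 1; ++k) {
    double d = seg_seg_dist(e, f, r[k], r[k + 1]);
    if (d < tol) {
      // contact at the chain end itself is expected for its own bonds
      double de = std::min(norm(sub(r[k], e)), norm(sub(r[k + 1], e)));
      if (de > tol) return true;
    }
  }
  return false;
}

std::vector<V3> close_chain_impl(const std::vector<V3>& r) {
  int n = (int)r.size();
  V3 com{0, 0, 0};
  for (const V3& p : r) com = add(com, p);
  com = scale(com, 1.0 / n);
  double rmax = 0.0;
  for (const V3& p : r) rmax = std::max(rmax, norm(sub(p, com)));
  double rfar = 10.0 * rmax;
  if (rfar <= 0.0) rfar = 1.0;  // all beads coincide with COM (degenerate)

  auto ray = [&](const V3& p) -> V3 {
    V3 u = sub(p, com);
    double nu = norm(u);
    if (nu < 1e-12 * (rmax > 0 ? rmax : 1.0)) {
      Rcpp::warning("chain endpoint coincides with the centre of mass; using a fixed fallback direction");
      u = V3{0, 0, 1}; nu = 1.0;
    }
    return scale(u, 1.0 / nu);
  };
  V3 u0 = ray(r.front()), u1 = ray(r.back());
  // exactly structured conformations (lattice-like or symmetric synthetic
  // curves) can place chain vertices exactly on an extension ray; nudge the
  // ray direction deterministically until the added segment is clear
  auto clear_ray = [&](V3 u, const V3& e) -> V3 {
    double tol = 1e-6 * rfar;
    V3 axis = std::fabs(u[0]) < 0.9 ? V3{1, 0, 0} : V3{0, 1, 0};
    V3 w = cross(u, axis);
    w = scale(w, 1.0 / norm(w));
    double delta = 1e-5;
    for (int tries = 0; tries < 40; ++tries) {
      V3 f = add(com, scale(u, rfar));
      if (!extension_interferes(r, e, f, tol)) return u;
      V3 u2 = add(u, scale(w, delta));
      u = scale(u2, 1.0 / norm(u2));
      delta *= 2.0;
    }
    Rcpp::warning("closure ray could not fully clear the chain volume");
    return u;
  };
  u0 = clear_ray(u0, r.front());
  u1 = clear_ray(u1, r.back());
  V3 f0 = add(com, scale(u0, rfar));
  V3 f1 = add(com, scale(u1, rfar));
  V3 bis = add(u0, u1);
  double nb = norm(bis);
  if (nb < 1e-9) {  // antipodal rays: pick a deterministic perpendicular
    V3 axis = std::fabs(u0[0]) < 0.9 ? V3{1, 0, 0} : V3{0, 1, 0};
    bis = cross(u0, axis);
    nb = norm(bis);
  }
  bis = scale(bis, 1.0 / nb);
  V3 apex = add(com, scale(bis, 2.0 * rfar));

  // closed polygon: chain, far point of last bead, apex, far point of first
  std::vector<V3> out(r);
  out.push_back(f1);
  out.push_back(apex);
  out.push_back(f0);
  return out;
}

// [[Rcpp::export]]
NumericMatrix close_chain_cpp(NumericMatrix coords) {
  if (coords.nrow() < 3) stop("closure requires at least 3 beads");
  return vec_to_mat(close_chain_impl(mat_to_vec(coords)));
}

// ---------------------------------------------------------------------------
// Koniaris-Muthukumar elision
//
// A vertex b with neighbours a, c may be removed when no other segment of
// the polygon passes through the triangle (a, b, c).  Removal sweeps the
// strand a-b-c across that triangle, an isotopy, so the knot type is kept.
// Ambiguous (near-degenerate) cases block removal: over-conservative checks
// only cost reduction, never correctness.

static const double KM_EPS = 1e-9;

// proper 2D segment intersection with parameters strictly inside (0,1)
static bool seg2d_proper_cross(double ax, double ay, double bx, double by,
                               double cx, double cy, double dx, double dy) {
  double rX = bx - ax, rY = by - ay, sX = dx - cx, sY = dy - cy;
  double den = rX * sY - rY * sX;
  double scl = std::max({std::fabs(rX), std::fabs(rY), std::fabs(sX), std::fabs(sY), 1e-300});
  if (std::fabs(den) < 1e-14 * scl * scl) return false;
  double qpX = cx - ax, qpY = cy - ay;
  double t = (qpX * sY - qpY * sX) / den;
  double u = (qpX * rY - qpY * rX) / den;
  return t > KM_EPS && t < 1 - KM_EPS && u > KM_EPS && u < 1 - KM_EPS;
}

// segment (p,q) vs triangle (a,b,c); strict=true demands a crossing through
// the open interior (used for segments sharing a triangle vertex), otherwise
// any touch of the closed triangle blocks.
static bool seg_blocks_triangle(const V3& p, const V3& q,
                                const V3& a, const V3& b, const V3& c,
                                double scale_len, bool strict) {
  V3 n = cross(sub(b, a), sub(c, a));
  double nn = norm(n);
  double area_eps = 1e-12 * scale_len * scale_len;
  if (nn < area_eps) return true;  // degenerate triangle: never elide via it
  V3 d = sub(q, p);
  double denom = dot(n, d);
  double hp = dot(n, sub(p, a));
  double hq = dot(n, sub(q, a));
  double plane_eps = 1e-10 * nn * scale_len;
  if (std::fabs(denom) < 1e-12 * nn * scale_len) {
    // segment parallel to the triangle plane
    if (std::fabs(hp) > plane_eps && std::fabs(hq) > plane_eps) return false;
    // coplanar: work in 2D on the dominant axes of n
    int ax0 = 0, ax1 = 1;
    double anx = std::fabs(n[0]), any = std::fabs(n[1]), anz = std::fabs(n[2]);
    if (anx >= any && anx >= anz) { ax0 = 1; ax1 = 2; }
    else if (any >= anx && any >= anz) { ax0 = 0; ax1 = 2; }
    auto X = [&](const V3& v) { return v[ax0]; };
    auto Y = [&](const V3& v) { return v[ax1]; };
    // endpoint strictly inside the 2D triangle?
    auto inside = [&](double px, double py) {
      double d1 = (X(b) - X(a)) * (py - Y(a)) - (Y(b) - Y(a)) * (px - X(a));
      double d2 = (X(c) - X(b)) * (py - Y(b)) - (Y(c) - Y(b)) * (px - X(b));
      double d3 = (X(a) - X(c)) * (py - Y(c)) - (Y(a) - Y(c)) * (px - X(c));
      double m = 1e-9 * scale_len * scale_len;
      bool pos = d1 > m && d2 > m && d3 > m;
      bool neg = d1 < -m && d2 < -m && d3 < -m;
      return pos || neg;
    };
    if (inside(X(p), Y(p)) || inside(X(q), Y(q))) return true;
    const V3* tv[4] = {&a, &b, &c, &a};
    for (int e = 0; e < 3; ++e)
      if (seg2d_proper_cross(X(p), Y(p), X(q), Y(q),
                             X(*tv[e]), Y(*tv[e]), X(*tv[e + 1]), Y(*tv[e + 1])))
        return true;
    return false;
  }
  double t = -hp / denom;
  double t_lo = strict ? KM_EPS : -KM_EPS;
  double t_hi = strict ? 1 - KM_EPS : 1 + KM_EPS;
  if (t < t_lo || t > t_hi) return false;
  V3 x = add(p, scale(d, t));
  // barycentric via projected areas
  V3 w = sub(x, a);
  V3 v0 = sub(b, a), v1 = sub(c, a);
  double d00 = dot(v0, v0), d01 = dot(v0, v1), d11 = dot(v1, v1);
  double dw0 = dot(w, v0), dw1 = dot(w, v1);
  double den2 = d00 * d11 - d01 * d01;
  double bb = (d11 * dw0 - d01 * dw1) / den2;
  double bc = (d00 * dw1 - d01 * dw0) / den2;
  double ba = 1.0 - bb - bc;
  double m = strict ? KM_EPS : -KM_EPS;
  return ba > m && bb > m && bc > m;
}

std::vector<V3> simplify_closed_impl(std::vector<V3> v) {
  double scale_len = 1.0;
  for (const V3& p : v) scale_len = std::max(scale_len, std::fabs(p[0]) + std::fabs(p[1]) + std::fabs(p[2]));
  double margin = 1e-9 * scale_len;
  bool changed = true;
  while (changed && v.size() > 3) {
    changed = false;
    int n = (int)v.size();
    for (int i = 0; i < n && n > 3; ++i) {
      int ia = (i - 1 + n) % n, ic = (i + 1) % n;
      const V3 &a = v[ia], &b = v[i], &c = v[ic];
      // a vertex collinear with and between its neighbours is redundant:
      // removing it leaves the curve unchanged as a point set
      {
        V3 ab = sub(b, a), bc = sub(c, b);
        V3 cr = cross(ab, bc);
        if (norm(cr) < 1e-12 * scale_len * scale_len && dot(ab, bc) > 0) {
          v.erase(v.begin() + i);
          --i; --n;
          changed = true;
          continue;
        }
      }
      // bounding box of the triangle, for cheap segment rejection
      double lo[3], hi[3];
      for (int ax = 0; ax < 3; ++ax) {
        lo[ax] = std::min({a[ax], b[ax], c[ax]}) - margin;
        hi[ax] = std::max({a[ax], b[ax], c[ax]}) + margin;
      }
      bool blocked = false;
      for (int k = 0; k < n && !blocked; ++k) {
        int k2 = (k + 1) % n;
        if (k == ia || k == i) continue;  // the two segments of the triangle
        const V3 &p = v[k], &q = v[k2];
        if ((p[0] < lo[0] && q[0] < lo[0]) || (p[0] > hi[0] && q[0] > hi[0]) ||
            (p[1] < lo[1] && q[1] < lo[1]) || (p[1] > hi[1] && q[1] > hi[1]) ||
            (p[2] < lo[2] && q[2] < lo[2]) || (p[2] > hi[2] && q[2] > hi[2]))
          continue;
        bool strict = (k2 == ia) || (k == ic);  // share a triangle vertex
        if (seg_blocks_triangle(p, q, a, b, c, scale_len, strict))
          blocked = true;
      }
      if (!blocked) {
        v.erase(v.begin() + i);
        --i; --n;
        changed = true;
      }
    }
  }
  return v;
}

// [[Rcpp::export]]
NumericMatrix simplify_closed_cpp(NumericMatrix coords) {
  if (coords.nrow() < 3) stop("a closed curve needs at least 3 vertices");
  return vec_to_mat(simplify_closed_impl(mat_to_vec(coords)));
}

// ---------------------------------------------------------------------------
// Alexander determinants from a generic projection

struct Crossing {
  double pos_under;  // parameter along the curve of the underpass strand
  double pos_over;
  int sign;          // orientation sign of (over, under) in the plane
};

// returns false if the projection direction is degenerate
static bool build_crossings(const std::vector<V3>& v, const V3& dir,
                            std::vector<Crossing>& out) {
  int n = (int)v.size();
  // orthonormal frame
  V3 axis = std::fabs(dir[0]) < 0.9 ? V3{1, 0, 0} : V3{0, 1, 0};
  V3 e1 = cross(dir, axis);
  e1 = scale(e1, 1.0 / norm(e1));
  V3 e2 = cross(dir, e1);
  std::vector<double> x(n), y(n), z(n);
  double scl = 1e-300;
  for (int i = 0; i < n; ++i) {
    x[i] = dot(v[i], e1); y[i] = dot(v[i], e2); z[i] = dot(v[i], dir);
    scl = std::max(scl, std::fabs(x[i]) + std::fabs(y[i]));
  }
  const double eps = 1e-10;
  out.clear();
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    double rX = x[i2] - x[i], rY = y[i2] - y[i];
    for (int j = i + 1; j < n; ++j) {
      int j2 = (j + 1) % n;
      if (j == i || j2 == i || j == i2) continue;  // adjacent segments
      double sX = x[j2] - x[j], sY = y[j2] - y[j];
      double den = rX * sY - rY * sX;
      double qpX = x[j] - x[i], qpY = y[j] - y[i];
      // quick reject via bounding boxes
      if (std::max(x[i], x[i2]) < std::min(x[j], x[j2]) ||
          std::max(x[j], x[j2]) < std::min(x[i], x[i2]) ||
          std::max(y[i], y[i2]) < std::min(y[j], y[j2]) ||
          std::max(y[j], y[j2]) < std::min(y[i], y[i2]))
        continue;
      if (std::fabs(den) < 1e-13 * scl * scl) {
        // near-parallel: harmless if the supporting lines are separated
        if (std::fabs(qpX * rY - qpY * rX) > 1e-10 * scl * scl) continue;
        // near-collinear with overlapping boxes: genuinely degenerate
        return false;
      }
      double t = (qpX * sY - qpY * sX) / den;
      double u = (qpX * rY - qpY * rX) / den;
      if (t < -eps || t > 1 + eps || u < -eps || u > 1 + eps) continue;
      if (t < eps || t > 1 - eps || u < eps || u > 1 - eps) return false;
      double zi = z[i] + t * (z[(i + 1) % n] - z[i]);
      double zj = z[j] + u * (z[j2] - z[j]);
      if (std::fabs(zi - zj) < 1e-9 * (std::fabs(zi) + std::fabs(zj) + 1.0))
        return false;
      Crossing c;
      int sgn = den > 0 ? 1 : -1;  // sign of cross(seg_i, seg_j)
      if (zi > zj) {               // segment i passes over
        c.pos_over = i + t; c.pos_under = j + u; c.sign = sgn;
      } else {
        c.pos_over = j + u; c.pos_under = i + t; c.sign = -sgn;
      }
      out.push_back(c);
    }
  }
  return true;
}

// evaluate |det| of the reduced Alexander matrix at t, by long double LU
static long double alex_det(const std::vector<Crossing>& cr, double t) {
  int c = (int)cr.size();
  // order crossings by underpass position -> generator numbering
  std::vector<int> ord(c);
  for (int i = 0; i < c; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return cr[a].pos_under < cr[b].pos_under;
  });
  std::vector<double> upos(c);
  for (int k = 0; k < c; ++k) upos[k] = cr[ord[k]].pos_under;
  // generator containing curve position p: arcs run between consecutive
  // underpasses; generator k (1-based) ends at underpass k
  auto generator = [&](double p) {
    int lo = (int)(std::upper_bound(upos.begin(), upos.end(), p) - upos.begin());
    return lo % c;  // 0-based: arc that ends at underpass lo (wrapping)
  };
  int m = c;
  std::vector<std::vector<long double>> M(m, std::vector<long double>(m, 0.0L));
  for (int k = 0; k < c; ++k) {
    const Crossing& x = cr[ord[k]];
    int kk = k;                 // underpass k: incoming generator k
    int k1 = (k + 1) % c;       // outgoing generator k+1
    int ov = generator(x.pos_over);
    if (ov == kk || ov == k1) {
      M[k][kk] += -1.0L;
      M[k][k1] += 1.0L;
    } else if (x.sign > 0) {
      M[k][kk] += 1.0L;
      M[k][k1] += -(long double)t;
      M[k][ov] += (long double)t - 1.0L;
    } else {
      M[k][kk] += -(long double)t;
      M[k][k1] += 1.0L;
      M[k][ov] += (long double)t - 1.0L;
    }
  }
  // delete last row and column; LU with partial pivoting
  int d = m - 1;
  long double det = 1.0L;
  for (int col = 0; col < d; ++col) {
    int piv = col;
    for (int r = col + 1; r < d; ++r)
      if (std::fabs((double)M[r][col]) > std::fabs((double)M[piv][col])) piv = r;
    if (std::fabs((double)M[piv][col]) < 1e-30) return 0.0L;
    if (piv != col) { std::swap(M[piv], M[col]); det = -det; }
    det *= M[col][col];
    for (int r = col + 1; r < d; ++r) {
      long double f = M[r][col] / M[col][col];
      for (int cc = col; cc < d; ++cc) M[r][cc] -= f * M[col][cc];
    }
  }
  return det < 0 ? -det : det;
}

// returns {|Delta(-1)|, odd part of |Delta(-2)|, n_crossings}; retries the
// projection until generic
static std::array<long long, 3> alexander_impl(const std::vector<V3>& v,
                                               Xoshiro& rng, int max_tries) {
  int n = (int)v.size();
  if (n <= 3) return {1, 1, 0};
  for (int attempt = 0; attempt < max_tries; ++attempt) {
    V3 dir;
    rng.unit_vector(dir.data());
    std::vector<Crossing> cr;
    if (!build_crossings(v, dir, cr)) continue;
    int c = (int)cr.size();
    if (c < 3) return {1, 1, c};
    long double d1 = alex_det(cr, -1.0);
    long double d2 = alex_det(cr, -2.0);
    if (d1 > 9.0e17L || d2 > 9.0e17L) return {-1, -1, c};  // overflow guard
    long long i1 = (long long)std::llroundl(d1);
    long long i2 = (long long)std::llroundl(d2);
    if (i1 % 2 == 0) continue;  // knot determinant is odd: bad diagram, retry
    while (i2 > 0 && i2 % 2 == 0) i2 /= 2;
    if (i2 == 0) continue;
    return {i1, i2, c};
  }
  stop("no generic projection found after %d attempts", max_tries);
}

// [[Rcpp::export]]
List alexander_cpp(NumericMatrix coords, int seed, int max_tries = 25) {
  std::vector<V3> v = mat_to_vec(coords);
  Xoshiro rng((uint64_t)seed);
  std::array<long long, 3> r = alexander_impl(v, rng, max_tries);
  return List::create(_["det1"] = (double)r[0], _["det2"] = (double)r[1],
                      _["n_crossings"] = (double)r[2]);
}

// closure + simplification + Alexander for an open chain
static std::array<long long, 3> analyze_open_impl(const std::vector<V3>& r,
                                                  Xoshiro& rng) {
  std::vector<V3> closed = close_chain_impl(r);
  std::vector<V3> simp = simplify_closed_impl(closed);
  return alexander_impl(simp, rng, 25);
}

// bridge used by the sampler (mc.cpp) to classify frames without R round-trips
std::array<long long, 3> mc_analyze_hook(const std::vector<V3>& r, Xoshiro& rng) {
  return analyze_open_impl(r, rng);
}

// [[Rcpp::export]]
List analyze_open_cpp(NumericMatrix coords, int seed) {
  if (coords.nrow() < 3) stop("need at least 3 beads");
  Xoshiro rng((uint64_t)seed);
  std::array<long long, 3> r = analyze_open_impl(mat_to_vec(coords), rng);
  return List::create(_["det1"] = (double)r[0], _["det2"] = (double)r[1],
                      _["n_crossings"] = (double)r[2]);
}

// [[Rcpp::export]]
List analyze_open_many_cpp(List frames, int seed) {
  int n = frames.size();
  NumericVector d1(n), d2(n), nc(n);
  Xoshiro rng((uint64_t)seed);
  for (int i = 0; i < n; ++i) {
    NumericMatrix m = frames[i];
    std::array<long long, 3> r = analyze_open_impl(mat_to_vec(m), rng);
    d1[i] = (double)r[0]; d2[i] = (double)r[1]; nc[i] = (double)r[2];
  }
  return List::create(_["det1"] = d1, _["det2"] = d2, _["n_crossings"] = nc);
}

// ---------------------------------------------------------------------------
// Knot localization by end trimming
//
// Beads are removed one at a time from the first end, the remainder re-closed
// and re-analysed, until the knot disappears; the bead whose removal unknots
// the chain is the boundary.  Repeat from the other terminus.

static bool is_knotted(const std::vector<V3>& r, Xoshiro& rng) {
  if (r.size() < 3) return false;
  std::array<long long, 3> d = analyze_open_impl(r, rng);
  return !(d[0] == 1 && d[1] == 1);
}

// [[Rcpp::export]]
IntegerVector locate_knot_cpp(NumericMatrix coords, int seed) {
  std::vector<V3> v = mat_to_vec(coords);
  int n = (int)v.size();
  Xoshiro rng((uint64_t)seed);
  if (!is_knotted(v, rng)) return IntegerVector::create(-1, -1);
  // trim from the first end
  int a = -1;
  for (int k = 0; k < n - 2; ++k) {
    std::vector<V3> sub(v.begin() + k + 1, v.end());
    if (!is_knotted(sub, rng)) { a = k; break; }
  }
  if (a < 0) a = n - 3;
  // trim from the other end on the retained chain [a, n-1]
  int b = -1;
  for (int m = n - 1; m > a + 1; --m) {
    std::vector<V3> sub(v.begin() + a, v.begin() + m);
    if (!is_knotted(sub, rng)) { b = m; break; }
  }
  if (b < 0) b = a + 2;
  return IntegerVector::create(a, b);
}
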