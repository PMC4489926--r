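// Knot identification for closed polygonal chains.
//
// Two stages: (1) geometric simplification that repeatedly deletes a vertex
// whose adjacent triangle is pierced by no other edge (an ambient isotopy,
// so the knot type is preserved); (2) projection of the reduced polygon to
// a generic plane, extraction of the crossing diagram, and evaluation of
// Alexander-matrix determinants.
//
// The determinant of the (n-1)-minor of the Alexander matrix equals
// +/- t^k Delta(t) with an unknown shift k.  We remove the ambiguity by
// sampling the determinant on the complex unit circle, where |t^k| = 1:
// |P(e^{i theta})|^2 = R(e^{i theta}) with R(t) = Delta(t) Delta(1/t) a
// Laurent polynomial with integer coefficients, symmetric in t <-> 1/t.
// A discrete Fourier transform recovers R exactly; palindromicity of the
// knot Alexander polynomial then gives Delta(-2)^2 = R(-2) * 2^{2g} with
// 2g = deg R.  This yields |Delta(-1)|, |Delta(-2)| in the convention
// where Delta has nonzero constant term (Rolfsen normalization).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <complex>
#include <algorithm>
#include <cmath>
#include "rng.h"

using namespace Rcpp;
typedef std::complex<double> cplx;

struct V3 { double x, y, z; };

static inline V3 sub(const V3& a, const V3& b) { return { a.x - b.x, a.y - b.y, a.z - b.z }; }
static inline V3 cross(const V3& a, const V3& b) {
  return { a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x };
}
static inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }

// --- KMT-style reduction ------------------------------------------------

// Does segment p->q intersect triangle (a,b,c)?  Conservative: ambiguous
// (near-degenerate) cases count as an intersection so the vertex is kept.
// t_lo/t_hi restrict the admissible segment parameter (used to ignore a
// shared endpoint).
static bool seg_hits_tri(const V3& a, const V3& b, const V3& c,
                         const V3& p, const V3& q,
                         double t_lo, double t_hi) {
  const double eps = 1e-10;
  V3 e1 = sub(b, a), e2 = sub(c, a), d = sub(q, p);
  V3 h = cross(d, e2);
  double det = dot(e1, h);
  double scale = std::sqrt(dot(e1, e1)) * std::sqrt(dot(e2, e2)) * std::sqrt(dot(d, d)) + 1e-300;
  if (std::fabs(det) < 1e-12 * scale) {
    // segment parallel to the triangle plane
    V3 nrm = cross(e1, e2);
    double nn = std::sqrt(dot(nrm, nrm));
    if (nn < 1e-14) return false; // degenerate (flat) triangle blocks nothing
    double d1 = std::fabs(dot(sub(p, a), nrm)) / nn;
    double d2 = std::fabs(dot(sub(q, a), nrm)) / nn;
    double span = std::sqrt(dot(e1, e1)) + std::sqrt(dot(e2, e2));
    if (d1 > 1e-9 * span || d2 > 1e-9 * span) return false; // off-plane
    // coplanar: exact 2D overlap test in the triangle plane so planar
    // polygons still reduce.  Effective segment restricted to [t_lo,t_hi].
    V3 u = e1;
    double ul = std::sqrt(dot(u, u));
    u = { u.x / ul, u.y / ul, u.z / ul };
    V3 w = cross(nrm, u);
    double wl = std::sqrt(dot(w, w));
    w = { w.x / wl, w.y / wl, w.z / wl };
    auto to2 = [&](const V3& v) {
      V3 r = sub(v, a);
      return std::array<double, 2>{ dot(r, u), dot(r, w) };
    };
    auto A2 = to2(a), B2 = to2(b), C2 = to2(c);
    V3 pe = { p.x + t_lo * d.x, p.y + t_lo * d.y, p.z + t_lo * d.z };
    V3 qe = { p.x + t_hi * d.x, p.y + t_hi * d.y, p.z + t_hi * d.z };
    auto P2 = to2(pe), Q2 = to2(qe);
    auto cross2 = [](const std::array<double, 2>& o,
                     const std::array<double, 2>& s,
                     const std::array<double, 2>& t) {
      return (s[0] - o[0]) * (t[1] - o[1]) - (s[1] - o[1]) * (t[0] - o[0]);
    };
    const double g = 1e-9 * span * span;
    auto inside = [&](const std::array<double, 2>& x) {
      double c1 = cross2(A2, B2, x), c2 = cross2(B2, C2, x), c3 = cross2(C2, A2, x);
      return (c1 > -g && c2 > -g && c3 > -g) || (c1 < g && c2 < g && c3 < g);
    };
    if (inside(P2) || inside(Q2)) return true;
    auto segx = [&](const std::array<double, 2>& s1, const std::array<double, 2>& s2) {
      double d1a = cross2(P2, Q2, s1), d2a = cross2(P2, Q2, s2);
      double d3a = cross2(s1, s2, P2), d4a = cross2(s1, s2, Q2);
      return ((d1a > g && d2a < -g) || (d1a < -g && d2a > g)) &&
             ((d3a > g && d4a < -g) || (d3a < -g && d4a > g));
    };
    return segx(A2, B2) || segx(B2, C2) || segx(C2, A2);
  }
  double inv = 1.0 / det;
  V3 s = sub(p, a);
  double u = inv * dot(s, h);
  if (u < -eps || u > 1.0 + eps) return false;
  V3 qv = cross(s, e1);
  double v = inv * dot(d, qv);
  if (v < -eps || u + v > 1.0 + eps) return false;
  double t = inv * dot(e2, qv);
  return (t >= t_lo - eps && t <= t_hi + eps);
}

// [[Rcpp::export]]
List cpp_kmt(NumericMatrix verts, IntegerVector protected1) {
  const int m0 = verts.nrow();
  std::vector<V3> pt(m0);
  for (int i = 0; i < m0; ++i) pt[i] = { verts(i, 0), verts(i, 1), verts(i, 2) };
  std::vector<char> keep_forced(m0, 0);
  for (int k = 0; k < protected1.size(); ++k) {
    int idx = protected1[k] - 1;
    if (idx >= 0 && idx < m0) keep_forced[idx] = 1;
  }
  std::vector<int> alive(m0);
  for (int i = 0; i < m0; ++i) alive[i] = i;

  bool changed = true;
  while (changed && (int)alive.size() > 3) {
    changed = false;
    for (size_t pos = 0; pos < alive.size() && alive.size() > 3; ++pos) {
      const int m = (int)alive.size();
      const int ip = (int)((pos + m - 1) % m), in = (int)((pos + 1) % m);
      const int cur = alive[pos];
      if (keep_forced[cur]) continue;
      const V3& A = pt[alive[ip]];
      const V3& B = pt[cur];
      const V3& C = pt[alive[in]];
      // area guard: (near-)degenerate triangles are only removed when the
      // vertex lies between its neighbors (collinear shortcut is exact)
      V3 ar = cross(sub(B, A), sub(C, A));
      double area2 = std::sqrt(dot(ar, ar));
      double ab = std::sqrt(dot(sub(B, A), sub(B, A)));
      double cb = std::sqrt(dot(sub(C, B), sub(C, B)));
      if (area2 < 1e-12 * ab * cb) {
        double t = dot(sub(B, A), sub(C, A)) / (dot(sub(C, A), sub(C, A)) + 1e-300);
        if (t > 0.0 && t < 1.0) { alive.erase(alive.begin() + pos); --pos; changed = true; }
        continue;
      }
      bool blocked = false;
      for (int e = 0; e < m && !blocked; ++e) {
        // edge from alive[e] to alive[e+1]; skip the two edges of the triangle
        if (e == ip || e == (int)pos) continue;
        const int en = (e + 1) % m;
        const V3& P = pt[alive[e]];
        const V3& Q = pt[alive[en]];
        double t_lo = 0.0, t_hi = 1.0;
        if (en == ip) t_hi = 1.0 - 1e-7;  // edge ends at triangle vertex A
        if (e == in) t_lo = 1e-7;         // edge starts at triangle vertex C
        if (seg_hits_tri(A, B, C, P, Q, t_lo, t_hi)) blocked = true;
      }
      if (!blocked) {
        alive.erase(alive.begin() + pos);
        --pos;
        changed = true;
      }
    }
  }

  NumericMatrix out((int)alive.size(), 3);
  IntegerVector kept((int)alive.size());
  for (size_t i = 0; i < alive.size(); ++i) {
    out(i, 0) = pt[alive[i]].x; out(i, 1) = pt[alive[i]].y; out(i, 2) = pt[alive[i]].z;
    kept[i] = alive[i] + 1;
  }
  return List::create(_["vertices"] = out, _["kept"] = kept);
}

// --- crossing diagram and Alexander determinants ------------------------

struct Passage {
  int edge;      // edge index along the chain
  double par;    // parameter along the edge
  int crossing;  // crossing id
  bool over;
};

struct Crossing {
  int sign;           // +1 / -1 (handedness of the 2D crossing)
  int under_id;       // underpass number, 1-based, in traversal order
  int over_arc;       // arc carrying the overpass
};

// uniform random rotation from a quaternion
static void random_rotation(Xoshiro& rng, double R[3][3]) {
  double u1 = rng.unif(), u2 = rng.unif(), u3 = rng.unif();
  double q0 = std::sqrt(1 - u1) * std::sin(2 * M_PI * u2);
  double q1 = std::sqrt(1 - u1) * std::cos(2 * M_PI * u2);
  double q2 = std::sqrt(u1) * std::sin(2 * M_PI * u3);
  double q3 = std::sqrt(u1) * std::cos(2 * M_PI * u3);
  R[0][0] = 1 - 2 * (q2 * q2 + q3 * q3); R[0][1] = 2 * (q1 * q2 - q0 * q3); R[0][2] = 2 * (q1 * q3 + q0 * q2);
  R[1][0] = 2 * (q1 * q2 + q0 * q3); R[1][1] = 1 - 2 * (q1 * q1 + q3 * q3); R[1][2] = 2 * (q2 * q3 - q0 * q1);
  R[2][0] = 2 * (q1 * q3 - q0 * q2); R[2][1] = 2 * (q2 * q3 + q0 * q1); R[2][2] = 1 - 2 * (q1 * q1 + q2 * q2);
}

// complex determinant by LU with partial pivoting (in place)
static cplx cdet(std::vector<cplx>& a, int n) {
  if (n == 0) return cplx(1.0, 0.0);
  cplx det(1.0, 0.0);
  for (int c = 0; c < n; ++c) {
    int piv = c;
    double best = std::abs(a[c * n + c]);
    for (int r = c + 1; r < n; ++r) {
      double v = std::abs(a[r * n + c]);
      if (v > best) { best = v; piv = r; }
    }
    if (best == 0.0) return cplx(0.0, 0.0);
    if (piv != c) {
      for (int k = c; k < n; ++k) std::swap(a[piv * n + k], a[c * n + k]);
      det = -det;
    }
    det *= a[c * n + c];
    for (int r = c + 1; r < n; ++r) {
      cplx f = a[r * n + c] / a[c * n + c];
      for (int k = c; k < n; ++k) a[r * n + k] -= f * a[c * n + k];
    }
  }
  return det;
}

// Build the n x n Alexander matrix at parameter t, drop last row/column,
// return the determinant.
static cplx alex_det_at(const std::vector<Crossing>& cr, int n, cplx t) {
  const int m = n - 1;
  if (m <= 0) return cplx(1.0, 0.0);
  std::vector<cplx> M((size_t)m * m, cplx(0.0, 0.0));
  auto put = [&](int r, int c, cplx v) {
    if (r < m && c < m) M[(size_t)r * m + c] += v;
  };
  for (int k = 0; k < n; ++k) {
    // row for underpass k+1: incoming arc k+1, outgoing arc k+2, overpass arc i
    const int rk = k;            // row index 0-based
    const int ak = k;            // column of arc k+1, 0-based
    const int ak1 = (k + 1) % n; // column of arc k+2
    const int ai = cr[k].over_arc - 1;
    if (ai == ak || ai == ak1) {
      put(rk, ak, cplx(-1.0, 0.0));
      put(rk, ak1, cplx(1.0, 0.0));
    } else if (cr[k].sign > 0) {
      put(rk, ak, cplx(1.0, 0.0));
      put(rk, ak1, -t);
      put(rk, ai, t - cplx(1.0, 0.0));
    } else {
      put(rk, ak, -t);
      put(rk, ak1, cplx(1.0, 0.0));
      put(rk, ai, t - cplx(1.0, 0.0));
    }
  }
  return cdet(M, m);
}

// One projection attempt.  Returns false on a degenerate projection.
static bool diagram_from_projection(const std::vector<V3>& v, Xoshiro& rng,
                                    std::vector<Crossing>& out_cr) {
  const int M = (int)v.size();
  double R[3][3];
  random_rotation(rng, R);
  std::vector<double> px(M), py(M), pz(M);
  double span = 0.0;
  for (int i = 0; i < M; ++i) {
    px[i] = R[0][0] * v[i].x + R[0][1] * v[i].y + R[0][2] * v[i].z;
    py[i] = R[1][0] * v[i].x + R[1][1] * v[i].y + R[1][2] * v[i].z;
    pz[i] = R[2][0] * v[i].x + R[2][1] * v[i].y + R[2][2] * v[i].z;
    span = std::max(span, std::fabs(px[i]) + std::fabs(py[i]));
  }
  const double teps = 1e-9, zeps = 1e-9 * std::max(span, 1.0);

  std::vector<Passage> ps;
  int ncr = 0;
  for (int i = 0; i < M; ++i) {
    const int i1 = (i + 1) % M;
    for (int j = i + 1; j < M; ++j) {
      const int j1 = (j + 1) % M;
      if (j == i1 || j1 == i) continue; // adjacent edges share a vertex
      const double rx = px[i1] - px[i], ry = py[i1] - py[i];
      const double sx = px[j1] - px[j], sy = py[j1] - py[j];
      const double den = rx * sy - ry * sx;
      const double qpx = px[j] - px[i], qpy = py[j] - py[i];
      if (std::fabs(den) < 1e-14 * (std::fabs(rx) + std::fabs(ry)) * (std::fabs(sx) + std::fabs(sy)) + 1e-300) {
        // near-parallel: degenerate only if they actually come close
        continue;
      }
      const double tt = (qpx * sy - qpy * sx) / den;
      const double uu = (qpx * ry - qpy * rx) / den;
      if (tt <= -teps || tt >= 1 + teps || uu <= -teps || uu >= 1 + teps) continue;
      if (tt < teps || tt > 1 - teps || uu < teps || uu > 1 - teps) return false; // endpoint hit
      const double zi = pz[i] + tt * (pz[i1] - pz[i]);
      const double zj = pz[j] + uu * (pz[j1] - pz[j]);
      if (std::fabs(zi - zj) < zeps) return false;
      const bool i_over = zi > zj;
      ps.push_back({ i, tt, ncr, i_over });
      ps.push_back({ j, uu, ncr, !i_over });
      ++ncr;
    }
  }

  out_cr.assign(ncr, Crossing{ 0, 0, 0 });
  if (ncr == 0) return true;

  // crossing sign from 2D directions (over x under), consistent convention
  std::vector<std::array<double, 2>> edir(M);
  for (int i = 0; i < M; ++i) {
    const int i1 = (i + 1) % M;
    edir[i] = { px[i1] - px[i], py[i1] - py[i] };
  }
  std::vector<int> over_edge(ncr, -1), under_edge(ncr, -1);
  for (const auto& p : ps) (p.over ? over_edge : under_edge)[p.crossing] = p.edge;
  for (int c = 0; c < ncr; ++c) {
    const auto& o = edir[over_edge[c]];
    const auto& u = edir[under_edge[c]];
    const double cz = o[0] * u[1] - o[1] * u[0];
    if (std::fabs(cz) < 1e-300) return false;
    out_cr[c].sign = (cz > 0) ? 1 : -1;
  }

  // traversal order of passages
  std::sort(ps.begin(), ps.end(), [](const Passage& a, const Passage& b) {
    if (a.edge != b.edge) return a.edge < b.edge;
    return a.par < b.par;
  });
  const int np = (int)ps.size();
  // number underpasses in traversal order
  int uid = 0;
  std::vector<int> passage_underid(np, 0); // underpass number at that passage (if under)
  for (int q = 0; q < np; ++q) {
    if (!ps[q].over) {
      ++uid;
      passage_underid[q] = uid;
      out_cr[ps[q].crossing].under_id = uid;
    }
  }
  if (uid != ncr) return false; // should not happen
  // arc of each overpass: arc k is the stretch ending at underpass k, so
  // an overpass at sorted position q lies in the arc of the next underpass
  // at or after q (cyclically; past the last underpass it wraps to arc 1).
  std::vector<int> next_under(np, 0);
  int carry = 1;
  for (int q = np - 1; q >= 0; --q) {
    if (!ps[q].over) carry = passage_underid[q];
    next_under[q] = carry;
  }
  for (int q = 0; q < np; ++q) {
    if (ps[q].over) out_cr[ps[q].crossing].over_arc = next_under[q];
  }

  // reorder crossings by underpass id so row k corresponds to underpass k+1
  std::vector<Crossing> ordered(ncr);
  for (int c = 0; c < ncr; ++c) ordered[out_cr[c].under_id - 1] = out_cr[c];
  out_cr = ordered;
  return true;
}

// Recover (|Delta(-1)|, |Delta(-2)|) from determinants on the unit circle.
// Returns false if the reconstruction looks unreliable for this projection.
static bool dets_from_diagram(const std::vector<Crossing>& cr,
                              double& d1, double& d2, bool& too_big) {
  const int n = (int)cr.size();
  too_big = false;
  if (n <= 2) { d1 = 1.0; d2 = 1.0; return true; }
  const int m = n - 1;
  const int L = 2 * m + 1;
  std::vector<double> mag2(L);
  double mx = 0.0;
  for (int j = 0; j < L; ++j) {
    const double th = 2.0 * M_PI * j / L;
    cplx t(std::cos(th), std::sin(th));
    cplx Pj = alex_det_at(cr, n, t);
    mag2[j] = std::norm(Pj);
    mx = std::max(mx, mag2[j]);
  }
  if (mx > 1e12) { too_big = true; d1 = -1; d2 = -1; return true; }
  // cosine series: mag2(theta) = c0 + 2 sum_r c_r cos(r theta)
  std::vector<double> cr_coef(m + 1, 0.0);
  for (int r = 0; r <= m; ++r) {
    double s = 0.0;
    for (int j = 0; j < L; ++j) s += mag2[j] * std::cos(2.0 * M_PI * r * j / L);
    cr_coef[r] = s / L;
  }
  // integrality check and degree
  int deg = 0;
  for (int r = 0; r <= m; ++r) {
    double rc = std::round(cr_coef[r]);
    if (std::fabs(cr_coef[r] - rc) > 1e-3 * std::max(1.0, std::fabs(rc))) return false;
    cr_coef[r] = rc;
    if (r > 0 && rc != 0.0) deg = r;
  }
  if (deg > 24) { too_big = true; d1 = -1; d2 = -1; return true; }
  // R(-1) = Delta(-1)^2 ; R(-2) * 2^deg = Delta(-2)^2  (palindromic Delta)
  double rm1 = cr_coef[0], rm2 = cr_coef[0];
  for (int r = 1; r <= deg; ++r) {
    rm1 += 2.0 * cr_coef[r] * ((r % 2) ? -1.0 : 1.0);
    const double p2 = std::pow(-2.0, r) + std::pow(-2.0, -r);
    rm2 += cr_coef[r] * p2;
  }
  if (rm1 < -0.5 || rm2 * std::pow(2.0, deg) < -0.5) return false;
  const double d1c = std::sqrt(std::max(0.0, rm1));
  const double d2c = std::sqrt(std::max(0.0, rm2 * std::pow(2.0, deg)));
  if (std::fabs(d1c - std::round(d1c)) > 1e-4 * std::max(1.0, d1c)) return false;
  if (std::fabs(d2c - std::round(d2c)) > 1e-4 * std::max(1.0, d2c)) return false;
  d1 = std::round(d1c);
  d2 = std::round(d2c);
  return true;
}

// [[Rcpp::export]]
List cpp_alexander(NumericMatrix verts, int max_tries, double seed) {
  const int M = verts.nrow();
  std::vector<V3> v(M);
  for (int i = 0; i < M; ++i) v[i] = { verts(i, 0), verts(i, 1), verts(i, 2) };
  Xoshiro rng(static_cast<uint64_t>(seed));
  for (int attempt = 0; attempt < max_tries; ++attempt) {
    std::vector<Crossing> cr;
    if (!diagram_from_projection(v, rng, cr)) continue;
    double d1, d2;
    bool too_big;
    if (!dets_from_diagram(cr, d1, d2, too_big)) continue;
    return List::create(_["det_minus1"] = d1, _["det_minus2"] = d2,
                        _["n_crossings"] = (int)cr.size(),
                        _["tries"] = attempt + 1,
                        _["overflow"] = too_big);
  }
  stop("no valid projection found after %d attempts", max_tries);
}
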