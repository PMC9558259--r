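// Spatial kernels shared by the whole pipeline: uniform-grid hashing for
// neighbor queries, greedy radius downsampling, kNN mean distances (outlier
// removal), color-constrained region growing, z-buffer visibility, and the
// Gabriel-style greedy surface triangulation used for total leaf area.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

typedef long long ll;

static inline double sq(double x) { return x * x; }

// 3D uniform grid over point indices; cells keyed by 21-bit packed coords.
struct Grid {
  double cell, ox, oy, oz;
  std::unordered_map<ll, std::vector<int> > cells;

  static ll key(int i, int j, int k) {
    return (((ll)(i + 1048576)) << 42) | (((ll)(j + 1048576)) << 21) |
           (ll)(k + 1048576);
  }

  void build(const NumericMatrix& P, double cell_) {
    cell = cell_;
    int n = P.nrow();
    ox = oy = oz = 0.0;
    if (n > 0) { ox = P(0, 0); oy = P(0, 1); oz = P(0, 2); }
    for (int i = 0; i < n; ++i) insert(P(i, 0), P(i, 1), P(i, 2), i);
  }

  void insert(double x, double y, double z, int idx) {
    int i = (int)std::floor((x - ox) / cell);
    int j = (int)std::floor((y - oy) / cell);
    int k = (int)std::floor((z - oz) / cell);
    cells[key(i, j, k)].push_back(idx);
  }

  // collect indices of points lying in cells overlapping the ball (c, r)
  void gather(double x, double y, double z, double r,
              std::vector<int>& out) const {
    int i0 = (int)std::floor((x - r - ox) / cell);
    int i1 = (int)std::floor((x + r - ox) / cell);
    int j0 = (int)std::floor((y - r - oy) / cell);
    int j1 = (int)std::floor((y + r - oy) / cell);
    int k0 = (int)std::floor((z - r - oz) / cell);
    int k1 = (int)std::floor((z + r - oz) / cell);
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        for (int k = k0; k <= k1; ++k) {
          std::unordered_map<ll, std::vector<int> >::const_iterator it =
              cells.find(key(i, j, k));
          if (it != cells.end())
            out.insert(out.end(), it->second.begin(), it->second.end());
        }
  }
};

static inline double dist3(const NumericMatrix& P, int a, int b) {
  return std::sqrt(sq(P(a, 0) - P(b, 0)) + sq(P(a, 1) - P(b, 1)) +
                   sq(P(a, 2) - P(b, 2)));
}

static double default_cell(const NumericMatrix& P) {
  int n = P.nrow();
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      if (P(i, d) < lo[d]) lo[d] = P(i, d);
      if (P(i, d) > hi[d]) hi[d] = P(i, d);
    }
  double ext = 0.0;
  for (int d = 0; d < 3; ++d) ext = std::max(ext, hi[d] - lo[d]);
  if (ext <= 0) ext = 1.0;
  return ext / 64.0;
}

// Greedy in-order radius downsampling: keep a point iff every already-kept
// point is >= radius away. Returns 1-based indices of kept points.
// [[Rcpp::export]]
IntegerVector cpp_radius_downsample(NumericMatrix P, double radius) {
  int n = P.nrow();
  Grid g;
  g.cell = radius;
  g.ox = g.oy = g.oz = 0.0;
  if (n > 0) { g.ox = P(0, 0); g.oy = P(0, 1); g.oz = P(0, 2); }
  std::vector<int> kept;
  std::vector<int> cand;
  for (int i = 0; i < n; ++i) {
    cand.clear();
    g.gather(P(i, 0), P(i, 1), P(i, 2), radius, cand);
    bool ok = true;
    for (size_t c = 0; c < cand.size(); ++c)
      if (dist3(P, i, cand[c]) < radius) { ok = false; break; }
    if (ok) {
      kept.push_back(i + 1);
      g.insert(P(i, 0), P(i, 1), P(i, 2), i);
    }
  }
  return wrap(kept);
}

// Mean distance from each point to its k nearest neighbors (self excluded).
// [[Rcpp::export]]
NumericVector cpp_knn_mean_dist(NumericMatrix P, int k) {
  int n = P.nrow();
  if (k >= n) stop("k must be smaller than the number of points");
  Grid g;
  g.build(P, default_cell(P));
  NumericVector out(n);
  std::vector<int> cand;
  std::vector<double> d;
  for (int i = 0; i < n; ++i) {
    double r = g.cell;
    for (;;) {
      cand.clear();
      g.gather(P(i, 0), P(i, 1), P(i, 2), r, cand);
      d.clear();
      for (size_t c = 0; c < cand.size(); ++c) {
        if (cand[c] == i) continue;
        double dd = dist3(P, i, cand[c]);
        if (dd <= r) d.push_back(dd);
      }
      if ((int)d.size() >= k) break;
      r *= 1.7;
    }
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    double s = 0.0;
    for (int q = 0; q < k; ++q) s += d[q];
    out[i] = s / k;
  }
  return out;
}

// Connected components of the graph with an edge between points closer than
// `radius` whose RGB colors differ by at most `color_thr` (Euclidean).
// Returns 1-based component labels.
// [[Rcpp::export]]
IntegerVector cpp_region_grow(NumericMatrix P, NumericMatrix C, double radius,
                              double color_thr) {
  int n = P.nrow();
  Grid g;
  g.build(P, radius);
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> stack, cand;
  double ct2 = sq(color_thr);
  for (int s = 0; s < n; ++s) {
    if (lab[s] != 0) continue;
    lab[s] = ++next;
    stack.assign(1, s);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      cand.clear();
      g.gather(P(cur, 0), P(cur, 1), P(cur, 2), radius, cand);
      for (size_t c = 0; c < cand.size(); ++c) {
        int j = cand[c];
        if (lab[j] != 0) continue;
        if (dist3(P, cur, j) > radius) continue;
        double cd2 = sq(C(cur, 0) - C(j, 0)) + sq(C(cur, 1) - C(j, 1)) +
                     sq(C(cur, 2) - C(j, 2));
        if (cd2 > ct2) continue;
        lab[j] = next;
        stack.push_back(j);
      }
    }
  }
  return lab;
}

// Top-view z-buffer: keep points with z >= (max z of their xy cell) - tol.
// [[Rcpp::export]]
LogicalVector cpp_zbuffer_keep(NumericMatrix P, double cell, double tol) {
  int n = P.nrow();
  double ox = n ? P(0, 0) : 0.0, oy = n ? P(0, 1) : 0.0;
  std::unordered_map<ll, double> zmax;
  for (int i = 0; i < n; ++i) {
    int cx = (int)std::floor((P(i, 0) - ox) / cell);
    int cy = (int)std::floor((P(i, 1) - oy) / cell);
    ll k = Grid::key(cx, cy, 0);
    std::unordered_map<ll, double>::iterator it = zmax.find(k);
    if (it == zmax.end() || P(i, 2) > it->second) zmax[k] = P(i, 2);
  }
  LogicalVector keep(n);
  for (int i = 0; i < n; ++i) {
    int cx = (int)std::floor((P(i, 0) - ox) / cell);
    int cy = (int)std::floor((P(i, 1) - oy) / cell);
    keep[i] = P(i, 2) >= zmax[Grid::key(cx, cy, 0)] - tol;
  }
  return keep;
}

// Index (1-based) of the nearest point in `ref` for each row of `query`.
// [[Rcpp::export]]
IntegerVector cpp_nearest_index(NumericMatrix query, NumericMatrix ref) {
  int nq = query.nrow(), nr = ref.nrow();
  if (nr == 0) stop("empty reference cloud");
  Grid g;
  g.build(ref, default_cell(ref));
  IntegerVector out(nq);
  std::vector<int> cand;
  for (int i = 0; i < nq; ++i) {
    double x = query(i, 0), y = query(i, 1), z = query(i, 2);
    double r = g.cell;
    int best = -1;
    double bd = R_PosInf;
    for (;;) {
      cand.clear();
      g.gather(x, y, z, r, cand);
      for (size_t c = 0; c < cand.size(); ++c) {
        double dd = std::sqrt(sq(x - ref(cand[c], 0)) + sq(y - ref(cand[c], 1)) +
                              sq(z - ref(cand[c], 2)));
        if (dd < bd) { bd = dd; best = cand[c]; }
      }
      if (best >= 0 && bd <= r) break;
      r *= 1.7;
    }
    out[i] = best + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Greedy Gabriel-style triangulation.
//
// Candidates: triples within each point's capped nearest neighborhood with
// all edges <= max_edge, non-degenerate area, and no other point strictly
// inside the triangle's minimum enclosing ball. Candidates are then accepted
// greedily by increasing ball radius, refusing any triangle that would give
// an edge more than two incident triangles or whose edge properly crosses an
// already-accepted edge (this resolves the diagonal ambiguity on regular
// samplings and suppresses overlapping duplicate patches).
// ---------------------------------------------------------------------------

struct Cand {
  int a, b, c;
  double r;  // min enclosing ball radius
};

static bool cand_less(const Cand& x, const Cand& y) {
  if (x.r != y.r) return x.r < y.r;
  if (x.a != y.a) return x.a < y.a;
  if (x.b != y.b) return x.b < y.b;
  return x.c < y.c;
}

// squared distance between segments p1-q1 and p2-q2 with closest params s,t
static double seg_seg_dist2(const double* p1, const double* q1,
                            const double* p2, const double* q2, double& s,
                            double& t) {
  double d1[3], d2[3], r[3];
  for (int i = 0; i < 3; ++i) {
    d1[i] = q1[i] - p1[i];
    d2[i] = q2[i] - p2[i];
    r[i] = p1[i] - p2[i];
  }
  double a = d1[0] * d1[0] + d1[1] * d1[1] + d1[2] * d1[2];
  double e = d2[0] * d2[0] + d2[1] * d2[1] + d2[2] * d2[2];
  double f = d2[0] * r[0] + d2[1] * r[1] + d2[2] * r[2];
  const double EPS = 1e-18;
  if (a <= EPS && e <= EPS) { s = t = 0.0; }
  else if (a <= EPS) { s = 0.0; t = std::min(1.0, std::max(0.0, f / e)); }
  else {
    double cc = d1[0] * r[0] + d1[1] * r[1] + d1[2] * r[2];
    if (e <= EPS) { t = 0.0; s = std::min(1.0, std::max(0.0, -cc / a)); }
    else {
      double b = d1[0] * d2[0] + d1[1] * d2[1] + d1[2] * d2[2];
      double denom = a * e - b * b;
      s = denom > EPS ? std::min(1.0, std::max(0.0, (b * f - cc * e) / denom))
                      : 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) { t = 0.0; s = std::min(1.0, std::max(0.0, -cc / a)); }
      else if (t > 1.0) {
        t = 1.0;
        s = std::min(1.0, std::max(0.0, (b - cc) / a));
      }
    }
  }
  double c1[3], c2[3];
  double d2out = 0.0;
  for (int i = 0; i < 3; ++i) {
    c1[i] = p1[i] + d1[i] * s;
    c2[i] = p2[i] + d2[i] * t;
    d2out += sq(c1[i] - c2[i]);
  }
  return d2out;
}

// minimum enclosing ball of a triangle: circumball if acute, else the ball
// on the longest edge as diameter
static void min_ball(const double* A, const double* B, const double* C,
                     double* cen, double& rad) {
  double ab2 = sq(B[0] - A[0]) + sq(B[1] - A[1]) + sq(B[2] - A[2]);
  double ac2 = sq(C[0] - A[0]) + sq(C[1] - A[1]) + sq(C[2] - A[2]);
  double bc2 = sq(C[0] - B[0]) + sq(C[1] - B[1]) + sq(C[2] - B[2]);
  const double* p = A;
  const double* q = B;
  double longest = ab2, others = ac2 + bc2;
  if (ac2 > longest) { longest = ac2; others = ab2 + bc2; p = A; q = C; }
  if (bc2 > longest) { longest = bc2; others = ab2 + ac2; p = B; q = C; }
  if (longest >= others) {  // right or obtuse: diametral ball on longest edge
    for (int i = 0; i < 3; ++i) cen[i] = 0.5 * (p[i] + q[i]);
    rad = 0.5 * std::sqrt(longest);
    return;
  }
  double a[3], b[3];
  for (int i = 0; i < 3; ++i) { a[i] = B[i] - A[i]; b[i] = C[i] - A[i]; }
  double aa = ab2, bb = ac2;
  double ab = a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
  double det = aa * bb - ab * ab;
  double s = 0.5 * bb * (aa - ab) / det;
  double t = 0.5 * aa * (bb - ab) / det;
  rad = 0.0;
  for (int i = 0; i < 3; ++i) {
    cen[i] = A[i] + s * a[i] + t * b[i];
    rad += sq(cen[i] - A[i]);
  }
  rad = std::sqrt(rad);
}

// [[Rcpp::export]]
IntegerMatrix cpp_triangulate(NumericMatrix P, double max_edge, int kmax) {
  int n = P.nrow();
  if (n < 3) stop("need at least 3 points");
  Grid g;
  g.build(P, max_edge);

  // capped neighbor lists within max_edge
  std::vector<std::vector<int> > nb(n);
  {
    std::vector<int> cand;
    std::vector<std::pair<double, int> > dd;
    for (int i = 0; i < n; ++i) {
      cand.clear();
      g.gather(P(i, 0), P(i, 1), P(i, 2), max_edge, cand);
      dd.clear();
      for (size_t c = 0; c < cand.size(); ++c) {
        int j = cand[c];
        if (j == i) continue;
        double d = dist3(P, i, j);
        if (d <= max_edge) dd.push_back(std::make_pair(d, j));
      }
      if ((int)dd.size() > kmax) {
        std::partial_sort(dd.begin(), dd.begin() + kmax, dd.end());
        dd.resize(kmax);
      }
      nb[i].reserve(dd.size());
      for (size_t q = 0; q < dd.size(); ++q) nb[i].push_back(dd[q].second);
    }
  }

  // unique candidate triples passing edge/area/empty-ball tests
  std::unordered_set<ll> seen;
  std::vector<Cand> cands;
  std::vector<int> ballq;
  const double TOL = 1e-9;
  for (int i = 0; i < n; ++i) {
    const std::vector<int>& N = nb[i];
    for (size_t u = 0; u < N.size(); ++u)
      for (size_t v = u + 1; v < N.size(); ++v) {
        int a = i, b = N[u], c = N[v];
        if (b > c) std::swap(b, c);
        if (a > b) std::swap(a, b);
        if (b > c) std::swap(b, c);
        ll k = ((ll)a * n + b) * n + c;
        if (!seen.insert(k).second) continue;
        if (dist3(P, b, c) > max_edge || dist3(P, a, b) > max_edge ||
            dist3(P, a, c) > max_edge)
          continue;
        double A[3] = {P(a, 0), P(a, 1), P(a, 2)};
        double B[3] = {P(b, 0), P(b, 1), P(b, 2)};
        double Cc[3] = {P(c, 0), P(c, 1), P(c, 2)};
        // area via cross product
        double e1[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
        double e2[3] = {Cc[0] - A[0], Cc[1] - A[1], Cc[2] - A[2]};
        double cx = e1[1] * e2[2] - e1[2] * e2[1];
        double cy = e1[2] * e2[0] - e1[0] * e2[2];
        double cz = e1[0] * e2[1] - e1[1] * e2[0];
        double area2 = std::sqrt(cx * cx + cy * cy + cz * cz);
        if (area2 < 1e-14) continue;
        double cen[3], rad;
        min_ball(A, B, Cc, cen, rad);
        ballq.clear();
        g.gather(cen[0], cen[1], cen[2], rad, ballq);
        bool empty = true;
        for (size_t q = 0; q < ballq.size(); ++q) {
          int j = ballq[q];
          if (j == a || j == b || j == c) continue;
          double d = std::sqrt(sq(P(j, 0) - cen[0]) + sq(P(j, 1) - cen[1]) +
                               sq(P(j, 2) - cen[2]));
          if (d < rad - TOL) { empty = false; break; }
        }
        if (!empty) continue;
        Cand cd;
        cd.a = a; cd.b = b; cd.c = c; cd.r = rad;
        cands.push_back(cd);
      }
  }
  std::sort(cands.begin(), cands.end(), cand_less);

  // greedy acceptance
  std::unordered_map<ll, int> edge_count;
  std::vector<int> acc_e1, acc_e2;  // accepted edge endpoint indices
  Grid eg;                          // grid over accepted edge midpoints
  eg.cell = max_edge;
  eg.ox = eg.oy = eg.oz = 0.0;
  if (n > 0) { eg.ox = P(0, 0); eg.oy = P(0, 1); eg.oz = P(0, 2); }
  std::vector<int> tri;
  std::vector<int> nearby;
  for (size_t ci = 0; ci < cands.size(); ++ci) {
    int a = cands[ci].a, b = cands[ci].b, c = cands[ci].c;
    int ev1[3] = {a, a, b};
    int ev2[3] = {b, c, c};
    bool ok = true;
    for (int e = 0; e < 3 && ok; ++e) {
      ll k = (ll)ev1[e] * n + ev2[e];
      std::unordered_map<ll, int>::iterator it = edge_count.find(k);
      if (it != edge_count.end() && it->second >= 2) ok = false;
    }
    // proper-crossing test against nearby accepted edges
    for (int e = 0; e < 3 && ok; ++e) {
      int u = ev1[e], v = ev2[e];
      double pu[3] = {P(u, 0), P(u, 1), P(u, 2)};
      double pv[3] = {P(v, 0), P(v, 1), P(v, 2)};
      double mx = 0.5 * (pu[0] + pv[0]), my = 0.5 * (pu[1] + pv[1]),
             mz = 0.5 * (pu[2] + pv[2]);
      nearby.clear();
      eg.gather(mx, my, mz, max_edge, nearby);
      for (size_t q = 0; q < nearby.size() && ok; ++q) {
        int w1 = acc_e1[nearby[q]], w2 = acc_e2[nearby[q]];
        if (w1 == u || w1 == v || w2 == u || w2 == v) continue;
        double a1[3] = {P(w1, 0), P(w1, 1), P(w1, 2)};
        double a2[3] = {P(w2, 0), P(w2, 1), P(w2, 2)};
        double s, t;
        double d2 = seg_seg_dist2(pu, pv, a1, a2, s, t);
        if (d2 < 1e-18 &&
            ((s > 1e-6 && s < 1.0 - 1e-6) || (t > 1e-6 && t < 1.0 - 1e-6)))
          ok = false;
      }
    }
    if (!ok) continue;
    tri.push_back(a + 1);
    tri.push_back(b + 1);
    tri.push_back(c + 1);
    for (int e = 0; e < 3; ++e) {
      ll k = (ll)ev1[e] * n + ev2[e];
      int& cnt = edge_count[k];
      if (cnt == 0) {  // first time we see this edge: index it spatially
        acc_e1.push_back(ev1[e]);
        acc_e2.push_back(ev2[e]);
        double mx = 0.5 * (P(ev1[e], 0) + P(ev2[e], 0));
        double my = 0.5 * (P(ev1[e], 1) + P(ev2[e], 1));
        double mz = 0.5 * (P(ev1[e], 2) + P(ev2[e], 2));
        eg.insert(mx, my, mz, (int)acc_e1.size() - 1);
      }
      cnt += 1;
    }
  }
  int m = (int)tri.size() / 3;
  IntegerMatrix out(m, 3);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = tri[3 * i];
    out(i, 1) = tri[3 * i + 1];
    out(i, 2) = tri[3 * i + 2];
  }
  return out;
}
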