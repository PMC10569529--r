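// Spherical Voronoi tessellation.
//
// For points on a sphere the convex hull triangulation is the spherical
// Delaunay triangulation; the Voronoi diagram is its dual. Hull faces give
// Voronoi vertices (outward face normals projected to the sphere), hull
// edges give generator adjacency, and each generator's cell area is the
// spherical polygon of its incident face circumcenters.

#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <unordered_map>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
};
inline V3 sub(const V3 &a, const V3 &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline V3 cross(const V3 &a, const V3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline double norm(const V3 &a) { return std::sqrt(dot(a, a)); }
inline V3 unit(const V3 &a) {
  double n = norm(a);
  return {a.x / n, a.y / n, a.z / n};
}

struct Face {
  int a, b, c;
  V3 n; // outward unit normal
  double off;
  std::vector<int> out;
  bool alive = true;
};

struct Hull {
  const std::vector<V3> &P;
  std::vector<Face> F;
  double eps;

  explicit Hull(const std::vector<V3> &pts) : P(pts) {
    double scale = 0.0;
    for (const V3 &p : P) scale = std::max(scale, std::abs(p.x) + std::abs(p.y) + std::abs(p.z));
    eps = 1e-12 * std::max(1.0, scale);
  }

  double height(const Face &f, int i) const { return dot(f.n, P[i]) - f.off; }

  int add_face(int a, int b, int c, const V3 &inside) {
    Face f;
    f.a = a; f.b = b; f.c = c;
    V3 nn = cross(sub(P[b], P[a]), sub(P[c], P[a]));
    double nl = norm(nn);
    if (nl < 1e-300) stop("degenerate face in spherical tessellation (duplicate or collinear points)");
    f.n = {nn.x / nl, nn.y / nl, nn.z / nl};
    f.off = dot(f.n, P[a]);
    if (dot(f.n, inside) - f.off > 0) { // flip to outward orientation
      std::swap(f.b, f.c);
      f.n = {-f.n.x, -f.n.y, -f.n.z};
      f.off = -f.off;
    }
    F.push_back(std::move(f));
    return (int)F.size() - 1;
  }

  void build() {
    int n = (int)P.size();
    if (n < 4) stop("spherical tessellation needs at least 4 points");
    // initial simplex: extremes
    int i0 = 0, i1 = 0;
    for (int i = 1; i < n; ++i) {
      if (P[i].x < P[i0].x) i0 = i;
      if (P[i].x > P[i1].x) i1 = i;
    }
    if (i0 == i1) stop("degenerate input: all points coincide");
    int i2 = -1;
    double best = -1.0;
    V3 d01 = sub(P[i1], P[i0]);
    for (int i = 0; i < n; ++i) {
      double h = norm(cross(d01, sub(P[i], P[i0])));
      if (h > best) { best = h; i2 = i; }
    }
    if (best < eps) stop("degenerate input: points are collinear");
    int i3 = -1;
    best = -1.0;
    V3 nn = cross(d01, sub(P[i2], P[i0]));
    for (int i = 0; i < n; ++i) {
      double h = std::abs(dot(nn, sub(P[i], P[i0])));
      if (h > best) { best = h; i3 = i; }
    }
    if (best < eps) stop("degenerate input: points are coplanar");
    V3 inside = {
      (P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4,
      (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4,
      (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4
    };
    add_face(i0, i1, i2, inside);
    add_face(i0, i1, i3, inside);
    add_face(i0, i2, i3, inside);
    add_face(i1, i2, i3, inside);

    std::vector<int> pending;
    for (int i = 0; i < n; ++i) {
      if (i == i0 || i == i1 || i == i2 || i == i3) continue;
      for (size_t f = 0; f < F.size(); ++f) {
        if (height(F[f], i) > eps) { F[f].out.push_back(i); break; }
      }
    }
    for (size_t f = 0; f < F.size(); ++f) {
      if (!F[f].out.empty()) pending.push_back((int)f);
    }

    std::vector<char> visible;
    while (!pending.empty()) {
      int fi = pending.back();
      pending.pop_back();
      if (!F[fi].alive || F[fi].out.empty()) continue;
      // farthest outside point of this face
      int p = -1;
      double hb = -1.0;
      for (int q : F[fi].out) {
        double h = height(F[fi], q);
        if (h > hb) { hb = h; p = q; }
      }
      // visible faces
      visible.assign(F.size(), 0);
      std::vector<int> vis;
      for (size_t f = 0; f < F.size(); ++f) {
        if (F[f].alive && height(F[f], p) > eps) {
          visible[f] = 1;
          vis.push_back((int)f);
        }
      }
      // horizon: directed edges of visible faces whose reverse edge is not
      // in the visible set
      std::unordered_set<long long> edges;
      long long n2 = (long long)P.size();
      for (int f : vis) {
        int vv[3] = {F[f].a, F[f].b, F[f].c};
        for (int e = 0; e < 3; ++e) {
          edges.insert(vv[e] * n2 + vv[(e + 1) % 3]);
        }
      }
      std::vector<std::pair<int, int>> horizon;
      for (long long ed : edges) {
        int u = (int)(ed / n2), v = (int)(ed % n2);
        if (!edges.count((long long)v * n2 + u)) horizon.push_back({u, v});
      }
      // gather orphaned outside points, retire visible faces
      std::vector<int> orphans;
      for (int f : vis) {
        for (int q : F[f].out) {
          if (q != p) orphans.push_back(q);
        }
        F[f].alive = false;
        F[f].out.clear();
      }
      V3 inside2 = inside;
      std::vector<int> fresh;
      for (auto &e : horizon) {
        fresh.push_back(add_face(e.first, e.second, p, inside2));
      }
      for (int q : orphans) {
        for (int f : fresh) {
          if (height(F[f], q) > eps) { F[f].out.push_back(q); break; }
        }
      }
      for (int f : fresh) {
        if (!F[f].out.empty()) pending.push_back(f);
      }
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".ps_sphere_voronoi")]]
List ps_sphere_voronoi(NumericMatrix pts, double R) {
  int n = pts.nrow();
  std::vector<V3> P(n);
  for (int i = 0; i < n; ++i) {
    V3 p = {pts(i, 0), pts(i, 1), pts(i, 2)};
    P[i] = unit(p); // work on the unit sphere; scale areas by R^2 at the end
  }
  Hull H(P);
  H.build();

  // incident Voronoi vertices (face circumcenters) per generator
  std::vector<std::vector<V3>> inc(n);
  std::unordered_set<long long> edge_set;
  long long n2 = n;
  for (const Face &f : H.F) {
    if (!f.alive) continue;
    V3 cc = f.n; // outward normal = circumcenter direction on unit sphere
    inc[f.a].push_back(cc);
    inc[f.b].push_back(cc);
    inc[f.c].push_back(cc);
    int vv[3] = {f.a, f.b, f.c};
    for (int e = 0; e < 3; ++e) {
      int u = vv[e], v = vv[(e + 1) % 3];
      if (u > v) std::swap(u, v);
      edge_set.insert((long long)u * n2 + v);
    }
  }

  NumericVector areas(n);
  for (int i = 0; i < n; ++i) {
    std::vector<V3> &vs = inc[i];
    if (vs.size() < 3) { areas[i] = NA_REAL; continue; }
    // order circumcenters by angle around the generator direction
    V3 u = P[i];
    V3 a0 = (std::abs(u.x) < 0.9) ? V3{1, 0, 0} : V3{0, 1, 0};
    V3 e1 = unit({a0.x - dot(a0, u) * u.x, a0.y - dot(a0, u) * u.y,
                  a0.z - dot(a0, u) * u.z});
    V3 e2 = cross(u, e1);
    std::vector<std::pair<double, int>> ang(vs.size());
    for (size_t k = 0; k < vs.size(); ++k) {
      ang[k] = {std::atan2(dot(vs[k], e2), dot(vs[k], e1)), (int)k};
    }
    std::sort(ang.begin(), ang.end());
    // spherical polygon area via triangle fan from the generator
    // (cells are geodesically convex and contain their generator)
    double A = 0.0;
    for (size_t k = 0; k < ang.size(); ++k) {
      const V3 &b = vs[ang[k].second];
      const V3 &c = vs[ang[(k + 1) % ang.size()].second];
      double det = dot(u, cross(b, c));
      double denom = 1.0 + dot(u, b) + dot(b, c) + dot(c, u);
      double om = 2.0 * std::atan2(det, denom);
      A += om; // signed; convex ordering keeps terms non-negative
    }
    areas[i] = std::abs(A) * R * R;
  }

  IntegerMatrix edges((int)edge_set.size(), 2);
  int r = 0;
  for (long long ed : edge_set) {
    edges(r, 0) = (int)(ed / n2) + 1; // 1-based for R
    edges(r, 1) = (int)(ed % n2) + 1;
    ++r;
  }
  return List::create(_["areas"] = areas, _["edges"] = edges);
}
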