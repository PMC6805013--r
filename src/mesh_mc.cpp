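// Dynamically triangulated closed-membrane core: mesh construction on the
// sphere, discrete mean curvature, Helfrich-type energy with protein nodes,
// and a Metropolis Monte-Carlo engine (vertex moves, bond flips, protein
// hops) with hard bond-length windows, self-avoidance, and optional
// parallel-plate confinement.
//
// Length unit: l_min (hard-core diameter). Energy unit: kT0.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <unordered_map>
#include <unordered_set>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

typedef std::array<double, 3> Vec3;

static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) {
  return {a[0] - b[0], a[1] - b[1], a[2] - b[2]};
}
static inline Vec3 vadd(const Vec3 &a, const Vec3 &b) {
  return {a[0] + b[0], a[1] + b[1], a[2] + b[2]};
}
static inline Vec3 vscale(const Vec3 &a, double s) {
  return {a[0] * s, a[1] * s, a[2] * s};
}
static inline double vdot(const Vec3 &a, const Vec3 &b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a[1] * b[2] - a[2] * b[1],
          a[2] * b[0] - a[0] * b[2],
          a[0] * b[1] - a[1] * b[0]};
}
static inline double vnorm(const Vec3 &a) { return std::sqrt(vdot(a, a)); }
static inline Vec3 vunit(const Vec3 &a) {
  double n = vnorm(a);
  return (n > 0.0) ? vscale(a, 1.0 / n) : Vec3{0.0, 0.0, 0.0};
}

// ---------------------------------------------------------------------------
// Mesh with adjacency; supports edge split / edge flip while keeping a
// closed, consistently oriented genus-0 triangulation.
// ---------------------------------------------------------------------------
struct Mesh {
  std::vector<Vec3> x;
  std::vector<std::array<int, 3>> tri;     // CCW seen from outside
  std::vector<std::vector<int>> vnbr;      // bonded neighbours
  std::vector<std::vector<int>> vface;     // incident faces
  std::vector<std::array<int, 2>> edges;   // unique edges (a < b)

  int nv() const { return (int)x.size(); }
  int nf() const { return (int)tri.size(); }
  int ne() const { return (int)edges.size(); }

  void build_adjacency() {
    int V = nv();
    vnbr.assign(V, {});
    vface.assign(V, {});
    edges.clear();
    std::unordered_set<long long> seen;
    for (int f = 0; f < nf(); ++f) {
      for (int k = 0; k < 3; ++k) {
        int a = tri[f][k], b = tri[f][(k + 1) % 3];
        vface[a].push_back(f);
        int lo = std::min(a, b), hi = std::max(a, b);
        long long key = (long long)lo * V + hi;
        if (seen.insert(key).second) {
          edges.push_back({lo, hi});
          vnbr[lo].push_back(hi);
          vnbr[hi].push_back(lo);
        }
      }
    }
  }

  bool bonded(int a, int b) const {
    const std::vector<int> &nb = vnbr[a];
    return std::find(nb.begin(), nb.end(), b) != nb.end();
  }

  // the two faces sharing edge (a,b); f_ab has a followed by b (CCW)
  bool edge_faces(int a, int b, int &f_ab, int &f_ba) const {
    f_ab = f_ba = -1;
    for (int f : vface[a]) {
      for (int k = 0; k < 3; ++k) {
        if (tri[f][k] == a && tri[f][(k + 1) % 3] == b) f_ab = f;
        if (tri[f][k] == b && tri[f][(k + 1) % 3] == a) f_ba = f;
      }
    }
    return f_ab >= 0 && f_ba >= 0;
  }

  static int third_vertex(const std::array<int, 3> &t, int a, int b) {
    for (int k = 0; k < 3; ++k)
      if (t[k] != a && t[k] != b) return t[k];
    return -1;
  }

  void replace_in(std::vector<int> &v, int from, int to) {
    std::replace(v.begin(), v.end(), from, to);
  }
  void erase_val(std::vector<int> &v, int val) {
    v.erase(std::remove(v.begin(), v.end(), val), v.end());
  }

  // split edge e (index into edges) at midpoint (optionally projected to the
  // unit sphere); V+1, E+3, F+2
  void split_edge(int e, bool project_sphere) {
    int a = edges[e][0], b = edges[e][1];
    int f1, f2;
    if (!edge_faces(a, b, f1, f2)) stop("split: edge without two faces");
    int c = third_vertex(tri[f1], a, b);
    int d = third_vertex(tri[f2], a, b);
    Vec3 m = vscale(vadd(x[a], x[b]), 0.5);
    if (project_sphere) m = vunit(m);
    int v = nv();
    x.push_back(m);
    vnbr.push_back({a, b, c, d});
    vface.push_back({});
    // f1 = (a,b,c) -> (a,v,c); new face (v,b,c)
    // f2 = (b,a,d) -> (b,v,d); new face (v,a,d)
    int g1 = nf(), g2 = nf() + 1;
    tri[f1] = {a, v, c};
    tri[f2] = {b, v, d};
    tri.push_back({v, b, c});
    tri.push_back({v, a, d});
    // adjacency fixes
    erase_val(vnbr[a], b);
    erase_val(vnbr[b], a);
    vnbr[a].push_back(v);
    vnbr[b].push_back(v);
    vnbr[c].push_back(v);
    vnbr[d].push_back(v);
    erase_val(vface[b], f1);
    erase_val(vface[a], f2);
    vface[b].push_back(g1);
    vface[c].push_back(g1);
    vface[a].push_back(g2);
    vface[d].push_back(g2);
    vface[v] = {f1, f2, g1, g2};
    // edges: reuse slot e as (a,v); add (b,v), (c,v), (d,v)
    edges[e] = {std::min(a, v), std::max(a, v)};
    edges.push_back({std::min(b, v), std::max(b, v)});
    edges.push_back({std::min(c, v), std::max(c, v)});
    edges.push_back({std::min(d, v), std::max(d, v)});
  }

  // flip edge index e: (a,b) with opposite vertices (c,d) -> edge (c,d)
  // returns false (no change) if the flip is combinatorially invalid
  bool flip_edge(int e) {
    int a = edges[e][0], b = edges[e][1];
    int f1, f2;
    if (!edge_faces(a, b, f1, f2)) return false;
    int c = third_vertex(tri[f1], a, b);
    int d = third_vertex(tri[f2], a, b);
    if (bonded(c, d)) return false;                       // duplicate edge
    if (vnbr[a].size() <= 3 || vnbr[b].size() <= 3) return false;
    // f1 = (a,b,c) -> (a,d,c); f2 = (b,a,d) -> (d,b,c)
    tri[f1] = {a, d, c};
    tri[f2] = {d, b, c};
    erase_val(vnbr[a], b);
    erase_val(vnbr[b], a);
    vnbr[c].push_back(d);
    vnbr[d].push_back(c);
    erase_val(vface[b], f1);
    erase_val(vface[a], f2);
    vface[d].push_back(f1);
    vface[c].push_back(f2);
    edges[e] = {std::min(c, d), std::max(c, d)};
    return true;
  }

  void unflip_edge(int e, int a, int b, int c, int d) {
    // inverse of a successful flip_edge that turned edge slot e=(a,b) into (c,d)
    int f1 = -1, f2 = -1;
    for (int f : vface[c]) {
      int cnt = 0;
      for (int k = 0; k < 3; ++k)
        if (tri[f][k] == c || tri[f][k] == d) ++cnt;
      if (cnt == 2) {
        bool has_a = false, has_b = false;
        for (int k = 0; k < 3; ++k) {
          if (tri[f][k] == a) has_a = true;
          if (tri[f][k] == b) has_b = true;
        }
        if (has_a) f1 = f;
        if (has_b) f2 = f;
      }
    }
    tri[f1] = {a, b, c};
    tri[f2] = {b, a, d};
    erase_val(vnbr[c], d);
    erase_val(vnbr[d], c);
    vnbr[a].push_back(b);
    vnbr[b].push_back(a);
    erase_val(vface[d], f1);
    erase_val(vface[c], f2);
    vface[b].push_back(f1);
    vface[a].push_back(f2);
    edges[e] = {std::min(a, b), std::max(a, b)};
  }

  double face_area(int f) const {
    Vec3 u = vsub(x[tri[f][1]], x[tri[f][0]]);
    Vec3 v = vsub(x[tri[f][2]], x[tri[f][0]]);
    return 0.5 * vnorm(vcross(u, v));
  }
  Vec3 face_normal_raw(int f) const {  // area-weighted (not unit)
    Vec3 u = vsub(x[tri[f][1]], x[tri[f][0]]);
    Vec3 v = vsub(x[tri[f][2]], x[tri[f][0]]);
    return vscale(vcross(u, v), 0.5);
  }

  Vec3 vertex_normal(int i) const {
    Vec3 n = {0, 0, 0};
    for (int f : vface[i]) n = vadd(n, face_normal_raw(f));
    return vunit(n);
  }

  // mixed Voronoi vertex area (Meyer et al.): Voronoi area for non-obtuse
  // triangles, half/quarter of the face area when obtuse at/away from the
  // vertex; the mixed cells tile the surface exactly, so areas sum to the
  // total and the closed-sphere bending limit is preserved, while the
  // pointwise curvature is far more accurate at valence defects than with
  // barycentric thirds
  double vertex_area(int i) const {
    double A = 0.0;
    for (int f : vface[i]) {
      int a = tri[f][0], b = tri[f][1], c = tri[f][2];
      if (b == i) { int t = a; a = b; b = c; c = t; }
      else if (c == i) { int t = c; c = b; b = a; a = t; }
      Vec3 e_ib = vsub(x[b], x[a]);
      Vec3 e_ic = vsub(x[c], x[a]);
      double d_ib2 = vdot(e_ib, e_ib), d_ic2 = vdot(e_ic, e_ic);
      double cos_i = vdot(e_ib, e_ic);
      Vec3 b_to_i = vsub(x[a], x[b]);
      Vec3 b_to_c = vsub(x[c], x[b]);
      Vec3 c_to_i = vsub(x[a], x[c]);
      Vec3 c_to_b = vsub(x[b], x[c]);
      double area = face_area(f);
      if (area < 1e-300) continue;
      bool obtuse_i = cos_i < 0.0;
      bool obtuse_b = vdot(b_to_i, b_to_c) < 0.0;
      bool obtuse_c = vdot(c_to_i, c_to_b) < 0.0;
      if (!obtuse_i && !obtuse_b && !obtuse_c) {
        double cot_b = vdot(b_to_i, b_to_c) /
                       std::max(vnorm(vcross(b_to_i, b_to_c)), 1e-300);
        double cot_c = vdot(c_to_i, c_to_b) /
                       std::max(vnorm(vcross(c_to_i, c_to_b)), 1e-300);
        A += (d_ic2 * cot_b + d_ib2 * cot_c) / 8.0;
      } else if (obtuse_i) {
        A += area / 2.0;
      } else {
        A += area / 4.0;
      }
    }
    return A;
  }

  // signed discrete mean curvature (cotangent Laplace-Beltrami, barycentric
  // dual area); positive for a sphere with outward normals
  double mean_curvature(int i) const {
    Vec3 K = {0, 0, 0};
    double A = 0.0;
    for (int f : vface[i]) {
      int a = tri[f][0], b = tri[f][1], c = tri[f][2];
      // rotate so that a == i
      if (b == i) { int t = a; a = b; b = c; c = t; }
      else if (c == i) { int t = c; c = b; b = a; a = t; }
      const Vec3 &xi = x[a];
      const Vec3 &xb = x[b];
      const Vec3 &xc = x[c];
      // cot at c opposes edge (i,b); cot at b opposes edge (i,c)
      Vec3 cb = vsub(xi, xc), cb2 = vsub(xb, xc);
      double cot_c = vdot(cb, cb2) / std::max(vnorm(vcross(cb, cb2)), 1e-300);
      Vec3 bb = vsub(xi, xb), bb2 = vsub(xc, xb);
      double cot_b = vdot(bb, bb2) / std::max(vnorm(vcross(bb, bb2)), 1e-300);
      K = vadd(K, vadd(vscale(vsub(xi, xb), cot_c), vscale(vsub(xi, xc), cot_b)));
    }
    A = vertex_area(i);
    if (A <= 0) stop("degenerate one-ring (zero area)");
    K = vscale(K, 1.0 / (2.0 * A));
    return 0.5 * vdot(K, vertex_normal(i));
  }
};

// ---------------------------------------------------------------------------
// Cell list for self-avoidance / protein contacts
// ---------------------------------------------------------------------------
struct CellList {
  double h;
  std::unordered_map<long long, std::vector<int>> cells;
  std::vector<long long> key_of;

  static long long pack(int ix, int iy, int iz) {
    return (((long long)(ix + 1048576)) << 42) |
           (((long long)(iy + 1048576)) << 21) | (long long)(iz + 1048576);
  }
  long long key(const Vec3 &p) const {
    return pack((int)std::floor(p[0] / h), (int)std::floor(p[1] / h),
                (int)std::floor(p[2] / h));
  }
  void build(const std::vector<Vec3> &x, double spacing) {
    h = spacing;
    cells.clear();
    key_of.assign(x.size(), 0);
    for (size_t i = 0; i < x.size(); ++i) {
      long long k = key(x[i]);
      key_of[i] = k;
      cells[k].push_back((int)i);
    }
  }
  void move(int i, const Vec3 &newpos) {
    long long nk = key(newpos);
    if (nk == key_of[i]) return;
    std::vector<int> &old = cells[key_of[i]];
    old.erase(std::remove(old.begin(), old.end(), i), old.end());
    cells[nk].push_back(i);
    key_of[i] = nk;
  }
  template <typename Fn>
  void for_neighbours(const Vec3 &p, Fn fn) const {
    int ix = (int)std::floor(p[0] / h), iy = (int)std::floor(p[1] / h),
        iz = (int)std::floor(p[2] / h);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = cells.find(pack(ix + dx + 0, iy + dy + 0, iz + dz + 0));
          if (it == cells.end()) continue;
          for (int j : it->second) fn(j);
        }
  }
};

static Mesh mesh_from_r(const NumericMatrix &pos, const IntegerMatrix &faces) {
  Mesh m;
  int V = pos.nrow(), F = faces.nrow();
  m.x.resize(V);
  for (int i = 0; i < V; ++i) m.x[i] = {pos(i, 0), pos(i, 1), pos(i, 2)};
  m.tri.resize(F);
  for (int f = 0; f < F; ++f)
    m.tri[f] = {faces(f, 0) - 1, faces(f, 1) - 1, faces(f, 2) - 1};
  m.build_adjacency();
  return m;
}

static List mesh_to_r(const Mesh &m) {
  int V = m.nv(), F = m.nf();
  NumericMatrix pos(V, 3);
  for (int i = 0; i < V; ++i)
    for (int k = 0; k < 3; ++k) pos(i, k) = m.x[i][k];
  IntegerMatrix faces(F, 3);
  for (int f = 0; f < F; ++f)
    for (int k = 0; k < 3; ++k) faces(f, k) = m.tri[f][k] + 1;
  return List::create(_["positions"] = pos, _["faces"] = faces);
}

// ---------------------------------------------------------------------------
// Sphere mesh construction: icosahedron -> subdivision -> longest-edge splits
// to the exact vertex count -> valence flips + tangential smoothing.
// ---------------------------------------------------------------------------
static Mesh icosahedron() {
  Mesh m;
  double phi = (1.0 + std::sqrt(5.0)) / 2.0;
  double pts[12][3] = {
      {-1, phi, 0}, {1, phi, 0}, {-1, -phi, 0}, {1, -phi, 0},
      {0, -1, phi}, {0, 1, phi}, {0, -1, -phi}, {0, 1, -phi},
      {phi, 0, -1}, {phi, 0, 1}, {-phi, 0, -1}, {-phi, 0, 1}};
  int fc[20][3] = {{0, 11, 5},  {0, 5, 1},  {0, 1, 7},   {0, 7, 10}, {0, 10, 11},
                   {1, 5, 9},   {5, 11, 4}, {11, 10, 2}, {10, 7, 6}, {7, 1, 8},
                   {3, 9, 4},   {3, 4, 2},  {3, 2, 6},   {3, 6, 8},  {3, 8, 9},
                   {4, 9, 5},   {2, 4, 11}, {6, 2, 10},  {8, 6, 7},  {9, 8, 1}};
  m.x.resize(12);
  for (int i = 0; i < 12; ++i)
    m.x[i] = vunit(Vec3{pts[i][0], pts[i][1], pts[i][2]});
  m.tri.resize(20);
  for (int f = 0; f < 20; ++f) m.tri[f] = {fc[f][0], fc[f][1], fc[f][2]};
  m.build_adjacency();
  return m;
}

static void loop_subdivide_sphere(Mesh &m) {
  int V0 = m.nv();
  std::unordered_map<long long, int> mid;
  std::vector<std::array<int, 3>> newtri;
  newtri.reserve(m.nf() * 4);
  auto midpoint = [&](int a, int b) -> int {
    long long key = (long long)std::min(a, b) * V0 * 4 + std::max(a, b);
    auto it = mid.find(key);
    if (it != mid.end()) return it->second;
    Vec3 p = vunit(vscale(vadd(m.x[a], m.x[b]), 0.5));
    int idx = m.nv();
    m.x.push_back(p);
    mid[key] = idx;
    return idx;
  };
  for (auto &t : m.tri) {
    int a = t[0], b = t[1], c = t[2];
    int ab = midpoint(a, b), bc = midpoint(b, c), ca = midpoint(c, a);
    newtri.push_back({a, ab, ca});
    newtri.push_back({b, bc, ab});
    newtri.push_back({c, ca, bc});
    newtri.push_back({ab, bc, ca});
  }
  m.tri = newtri;
  m.build_adjacency();
}

// [[Rcpp::export]]
List cpp_mesh_geometry(NumericMatrix pos, IntegerMatrix faces) {
  Mesh m = mesh_from_r(pos, faces);
  int V = m.nv();
  NumericVector H(V), Av(V);
  NumericMatrix N(V, 3);
  for (int i = 0; i < V; ++i) {
    H[i] = m.mean_curvature(i);
    Av[i] = m.vertex_area(i);
    Vec3 n = m.vertex_normal(i);
    for (int k = 0; k < 3; ++k) N(i, k) = n[k];
  }
  NumericVector fa(m.nf());
  for (int f = 0; f < m.nf(); ++f) fa[f] = m.face_area(f);
  IntegerMatrix E(m.ne(), 2);
  for (int e = 0; e < m.ne(); ++e) {
    E(e, 0) = m.edges[e][0] + 1;
    E(e, 1) = m.edges[e][1] + 1;
  }
  return List::create(_["H"] = H, _["vertex_area"] = Av, _["normals"] = N,
                      _["face_area"] = fa, _["edges"] = E);
}

// ---------------------------------------------------------------------------
// Energy
// ---------------------------------------------------------------------------
struct Params {
  double kappa, kA, w, Fmag, c0, kT, l_min, l_max, a0, r0, wall_d;
  // soft-bond mode (mesh construction annealing): hard bond window replaced
  // by harmonic springs, plus a radial spring pinning vertices to a sphere
  bool soft = false;
  double k_bond = 0.0, l0_rest = 0.0, k_sphere = 0.0, R_sphere = 0.0;
};

static Params params_from_r(const List &p) {
  Params q;
  q.kappa = as<double>(p["kappa"]);
  q.kA = as<double>(p["k_A"]);
  q.w = as<double>(p["w"]);
  q.Fmag = as<double>(p["force"]);
  q.c0 = as<double>(p["c0"]);
  q.kT = as<double>(p["kT"]);
  q.l_min = as<double>(p["l_min"]);
  q.l_max = as<double>(p["l_max"]);
  q.a0 = as<double>(p["a0"]);
  q.r0 = as<double>(p["r0"]);
  q.wall_d = p.containsElementNamed("wall_d") ? as<double>(p["wall_d"]) : R_PosInf;
  return q;
}

struct EnergyParts {
  double WA = 0, Wb = 0, Wd = 0, WF = 0;
  double total() const { return WA + Wb + Wd + WF; }
};

// stretching of one face
static inline double stretch_term(const Mesh &m, int f, const Params &p) {
  double a = m.face_area(f);
  if (a <= 0) stop("degenerate (zero-area) triangle");
  double r = a / p.a0 - 1.0;
  return 0.5 * p.kA * r * r;
}
// area-weighted bending of one vertex
static inline double bend_term(const Mesh &m, int i, bool prot, const Params &p) {
  double H = m.mean_curvature(i);
  double C0 = prot ? p.c0 : 0.0;
  double d = 2.0 * H - C0;
  return 0.5 * p.kappa * m.vertex_area(i) * d * d;
}
// active-force term of one vertex (0 for membrane nodes)
static inline double force_term(const Mesh &m, int i, bool prot, const Params &p) {
  if (!prot || p.Fmag == 0.0) return 0.0;
  return -p.Fmag * vdot(m.vertex_normal(i), m.x[i]);
}

// full recomputation (O(V^2) pair term; used for scratch checks and init)
static EnergyParts energy_scratch(const Mesh &m, const std::vector<char> &prot,
                                  const Params &p) {
  EnergyParts E;
  for (int f = 0; f < m.nf(); ++f) E.WA += stretch_term(m, f, p);
  for (int i = 0; i < m.nv(); ++i) {
    E.Wb += bend_term(m, i, prot[i] != 0, p);
    E.WF += force_term(m, i, prot[i] != 0, p);
  }
  if (p.soft) {
    for (int i = 0; i < m.nv(); ++i) {
      double dr = vnorm(m.x[i]) - p.R_sphere;
      E.WA += p.k_sphere * dr * dr;
    }
    for (size_t e = 0; e < m.edges.size(); ++e) {
      double L = vnorm(vsub(m.x[m.edges[e][0]], m.x[m.edges[e][1]]));
      double d = L - p.l0_rest;
      E.WA += p.k_bond * d * d;
    }
  }
  double r2 = p.r0 * p.r0;
  for (int i = 0; i < m.nv(); ++i) {
    if (!prot[i]) continue;
    for (int j = i + 1; j < m.nv(); ++j) {
      if (!prot[j]) continue;
      Vec3 d = vsub(m.x[i], m.x[j]);
      if (vdot(d, d) < r2) E.Wd -= p.w;
    }
  }
  return E;
}

// [[Rcpp::export]]
List cpp_energy(NumericMatrix pos, IntegerMatrix faces, LogicalVector protein,
                List params) {
  Mesh m = mesh_from_r(pos, faces);
  Params p = params_from_r(params);
  std::vector<char> prot(m.nv());
  for (int i = 0; i < m.nv(); ++i) prot[i] = protein[i] ? 1 : 0;
  EnergyParts E = energy_scratch(m, prot, p);
  // raw (area-unweighted) bending sum, for comparison
  double wb_raw = 0.0;
  for (int i = 0; i < m.nv(); ++i) {
    double H = m.mean_curvature(i);
    double C0 = prot[i] ? p.c0 : 0.0;
    double d = 2.0 * H - C0;
    wb_raw += 0.5 * p.kappa * d * d;
  }
  return List::create(_["W_A"] = E.WA, _["W_b"] = E.Wb, _["W_d"] = E.Wd,
                      _["W_F"] = E.WF, _["W"] = E.total(),
                      _["W_b_raw"] = wb_raw);
}

// ---------------------------------------------------------------------------
// Monte-Carlo engine
// ---------------------------------------------------------------------------
struct Engine {
  Mesh m;
  std::vector<char> prot;
  std::vector<int> plist;    // indices of protein-occupied vertices
  Params p;
  CellList cl;
  EnergyParts E;             // running (incremental) breakdown
  double delta;              // vertex-move cube half-width
  long acc_move = 0, try_move = 0;
  long acc_flip = 0, try_flip = 0;
  long acc_hop = 0, try_hop = 0;

  void init() {
    cl.build(m.x, std::max(p.l_min, p.r0) + 1e-9);
    E = energy_scratch(m, prot, p);
    plist.clear();
    for (int i = 0; i < m.nv(); ++i)
      if (prot[i]) plist.push_back(i);
  }

  bool metropolis(double dE) {
    if (dE <= 0) return true;
    return unif_rand() < std::exp(-dE / p.kT);
  }

  // count protein contacts of vertex i (to other protein vertices), excluding
  // `skip`
  int contacts_of(int i, int skip = -1) const {
    if (!prot[i]) return 0;
    int n = 0;
    double r2 = p.r0 * p.r0;
    cl.for_neighbours(m.x[i], [&](int j) {
      if (j == i || j == skip || !prot[j]) return;
      Vec3 d = vsub(m.x[i], m.x[j]);
      if (vdot(d, d) < r2) ++n;
    });
    return n;
  }

  bool position_allowed(int i, const Vec3 &np) const {
    if (std::fabs(np[2]) > p.wall_d / 2.0) return false;     // hard walls
    // bond window (replaced by springs in soft mode)
    if (!p.soft) {
      for (int j : m.vnbr[i]) {
        double L = vnorm(vsub(np, m.x[j]));
        if (L <= p.l_min || L >= p.l_max) return false;
      }
    }
    // self-avoidance vs non-bonded
    bool ok = true;
    double lm2 = p.l_min * p.l_min;
    cl.for_neighbours(np, [&](int j) {
      if (!ok || j == i) return;
      if (m.bonded(i, j)) return;
      Vec3 d = vsub(np, m.x[j]);
      if (vdot(d, d) < lm2) ok = false;
    });
    return ok;
  }

  // local energy around vertex i: stretch of incident faces, bending+force of
  // i and its ring, contact count of i
  void local_energy(int i, EnergyParts &out) const {
    out = EnergyParts();
    for (int f : m.vface[i]) out.WA += stretch_term(m, f, p);
    out.Wb += bend_term(m, i, prot[i] != 0, p);
    out.WF += force_term(m, i, prot[i] != 0, p);
    for (int j : m.vnbr[i]) {
      out.Wb += bend_term(m, j, prot[j] != 0, p);
      out.WF += force_term(m, j, prot[j] != 0, p);
    }
    out.Wd = -p.w * contacts_of(i);
    if (p.soft) {
      for (int j : m.vnbr[i]) {
        double L = vnorm(vsub(m.x[i], m.x[j]));
        double d = L - p.l0_rest;
        out.WA += p.k_bond * d * d;
      }
      double dr = vnorm(m.x[i]) - p.R_sphere;
      out.WA += p.k_sphere * dr * dr;
    }
  }

  bool attempt_vertex_move() {
    ++try_move;
    int i = (int)(unif_rand() * m.nv());
    if (i >= m.nv()) i = m.nv() - 1;
    Vec3 np = m.x[i];
    for (int k = 0; k < 3; ++k) np[k] += delta * (2.0 * unif_rand() - 1.0);
    if (!position_allowed(i, np)) return false;
    EnergyParts before, after;
    local_energy(i, before);
    Vec3 old = m.x[i];
    m.x[i] = np;
    cl.move(i, np);
    local_energy(i, after);
    double dE = after.total() - before.total();
    if (metropolis(dE)) {
      E.WA += after.WA - before.WA;
      E.Wb += after.Wb - before.Wb;
      E.Wd += after.Wd - before.Wd;
      E.WF += after.WF - before.WF;
      ++acc_move;
      return true;
    }
    m.x[i] = old;
    cl.move(i, old);
    return false;
  }

  // energy pieces affected by a flip of (a,b)->(c,d): the two faces + bending
  // and force of a,b,c,d (W_d depends only on positions: unchanged)
  void quad_energy(int f1, int f2, int a, int b, int c, int d,
                   EnergyParts &out) const {
    out = EnergyParts();
    out.WA = stretch_term(m, f1, p) + stretch_term(m, f2, p);
    int vs[4] = {a, b, c, d};
    for (int v : vs) {
      out.Wb += bend_term(m, v, prot[v] != 0, p);
      out.WF += force_term(m, v, prot[v] != 0, p);
    }
  }

  bool attempt_bond_flip() {
    ++try_flip;
    int e = (int)(unif_rand() * m.ne());
    if (e >= m.ne()) e = m.ne() - 1;
    int a = m.edges[e][0], b = m.edges[e][1];
    int f1, f2;
    if (!m.edge_faces(a, b, f1, f2)) return false;
    int c = Mesh::third_vertex(m.tri[f1], a, b);
    int d = Mesh::third_vertex(m.tri[f2], a, b);
    if (m.bonded(c, d)) return false;
    if (m.vnbr[a].size() <= 3 || m.vnbr[b].size() <= 3) return false;
    double Lcd = vnorm(vsub(m.x[c], m.x[d]));
    if (!p.soft && (Lcd <= p.l_min || Lcd >= p.l_max)) return false;
    double Lab = vnorm(vsub(m.x[a], m.x[b]));
    // in soft mode the flipped-away pair (a,b) becomes non-bonded and must
    // not violate the hard core
    if (p.soft && Lab < p.l_min) return false;
    EnergyParts before, after;
    quad_energy(f1, f2, a, b, c, d, before);
    if (p.soft) {
      double da = Lab - p.l0_rest;
      before.WA += p.k_bond * da * da;
    }
    if (!m.flip_edge(e)) return false;
    // recover face ids post-flip (faces f1, f2 were reused)
    quad_energy(f1, f2, a, b, c, d, after);
    if (p.soft) {
      double dd = Lcd - p.l0_rest;
      after.WA += p.k_bond * dd * dd;
    }
    double dE = after.total() - before.total();
    if (metropolis(dE)) {
      E.WA += after.WA - before.WA;
      E.Wb += after.Wb - before.Wb;
      E.WF += after.WF - before.WF;
      ++acc_flip;
      return true;
    }
    m.unflip_edge(e, a, b, c, d);
    return false;
  }

  bool attempt_protein_hop() {
    if (plist.empty()) return false;
    ++try_hop;
    int pi = (int)(unif_rand() * plist.size()) % (int)plist.size();
    int i = plist[pi];
    const std::vector<int> &nb = m.vnbr[i];
    int j = nb[(int)(unif_rand() * nb.size()) % nb.size()];
    if (prot[j]) return false;
    EnergyParts before, after;
    before.Wb = bend_term(m, i, true, p) + bend_term(m, j, false, p);
    before.WF = force_term(m, i, true, p);
    before.Wd = -p.w * (contacts_of(i, j));
    prot[i] = 0;
    prot[j] = 1;
    after.Wb = bend_term(m, i, false, p) + bend_term(m, j, true, p);
    after.WF = force_term(m, j, true, p);
    after.Wd = -p.w * (contacts_of(j, i));
    double dE = after.total() - before.total();
    // Hastings factor: the forward proposal picks j among deg(i) neighbours,
    // the reverse picks i among deg(j)
    double hastings = (double)m.vnbr[i].size() / (double)m.vnbr[j].size();
    bool accept = (dE <= 0 && hastings >= 1.0) ||
                  unif_rand() < hastings * std::exp(-dE / p.kT);
    if (accept) {
      E.Wb += after.Wb - before.Wb;
      E.Wd += after.Wd - before.Wd;
      E.WF += after.WF - before.WF;
      plist[pi] = j;
      ++acc_hop;
      return true;
    }
    prot[i] = 1;
    prot[j] = 0;
    return false;
  }

  // one sweep: V vertex moves + E bond flips + (#protein) hops, interleaved
  // in random order by drawing the move kind with probability proportional
  // to its count
  void sweep(bool do_flips, bool do_hops) {
    int nprot = 0;
    for (char c : prot) nprot += c;
    long nv = m.nv(), ne = do_flips ? m.ne() : 0,
         nh = do_hops ? nprot : 0;
    long total = nv + ne + nh;
    for (long t = 0; t < total; ++t) {
      double u = unif_rand() * total;
      if (u < nv) attempt_vertex_move();
      else if (u < nv + ne) attempt_bond_flip();
      else attempt_protein_hop();
    }
  }
};

// shortest-edge collapses down to an exact vertex count; midpoint placement
// projected to the unit sphere; the link condition keeps the triangulation
// closed and manifold
static void collapse_to_count(Mesh &m, int target) {
  while (m.nv() > target) {
    m.build_adjacency();
    int best = -1;
    double bl = R_PosInf;
    for (int e = 0; e < m.ne(); ++e) {
      int a = m.edges[e][0], b = m.edges[e][1];
      // link condition: exactly two shared neighbours, both of degree >= 4
      int shared = 0;
      bool ok = true;
      for (int u : m.vnbr[a]) {
        if (std::find(m.vnbr[b].begin(), m.vnbr[b].end(), u) != m.vnbr[b].end()) {
          ++shared;
          if (m.vnbr[u].size() < 4) ok = false;
        }
      }
      if (!ok || shared != 2) continue;
      double L = vnorm(vsub(m.x[a], m.x[b]));
      if (L < bl) { bl = L; best = e; }
    }
    if (best < 0) stop("no collapsible edge found");
    int a = m.edges[best][0], b = m.edges[best][1];
    m.x[a] = vunit(vscale(vadd(m.x[a], m.x[b]), 0.5));
    std::vector<std::array<int, 3>> nf;
    nf.reserve(m.nf() - 2);
    for (auto &t : m.tri) {
      bool has_a = false, has_b = false;
      for (int k = 0; k < 3; ++k) {
        if (t[k] == a) has_a = true;
        if (t[k] == b) has_b = true;
      }
      if (has_a && has_b) continue;  // the two faces on the edge vanish
      std::array<int, 3> u = t;
      for (int k = 0; k < 3; ++k)
        if (u[k] == b) u[k] = a;
      nf.push_back(u);
    }
    // drop vertex b: move the last vertex into slot b
    int last = m.nv() - 1;
    if (b != last) {
      m.x[b] = m.x[last];
      for (auto &t : nf)
        for (int k = 0; k < 3; ++k)
          if (t[k] == last) t[k] = b;
    }
    m.x.pop_back();
    m.tri = nf;
  }
  m.build_adjacency();
}

static void delaunay_flips(Mesh &m, double scale3) {
  for (int pass = 0; pass < 5; ++pass) {
    int nflip = 0;
    for (int e = 0; e < m.ne(); ++e) {
      int a = m.edges[e][0], b = m.edges[e][1];
      int f1, f2;
      if (!m.edge_faces(a, b, f1, f2)) continue;
      int c = Mesh::third_vertex(m.tri[f1], a, b);
      int d = Mesh::third_vertex(m.tri[f2], a, b);
      Vec3 n = vcross(vsub(m.x[b], m.x[a]), vsub(m.x[c], m.x[a]));
      if (vdot(vsub(m.x[d], m.x[a]), n) > 1e-9 * scale3) {
        if (m.flip_edge(e)) ++nflip;
      }
    }
    if (nflip == 0) break;
  }
}

// flip passes + degree-normalized springs toward rest length l0 with strong
// rectified pull near the hard bond window; vertices live on a sphere whose
// radius adapts to keep the mean edge at l0
static void spring_relax(Mesh &m, double l0, double &Rt, int iters,
                         bool safe = false) {
  double u = l0 / 1.35;  // l_min in current units
  for (int it = 0; it < iters; ++it) {
    delaunay_flips(m, Rt * Rt * Rt);
    std::vector<Vec3> disp(m.nv(), Vec3{0, 0, 0});
    for (auto &e : m.edges) {
      int a = e[0], b = e[1];
      Vec3 d = vsub(m.x[b], m.x[a]);
      double L = vnorm(d);
      if (L < 1e-12) continue;
      double f = L - l0;
      if (L > 1.60 * u) f += 12.0 * (L - 1.60 * u);
      if (L < 1.10 * u) f -= 12.0 * (1.10 * u - L);
      Vec3 fv = vscale(d, f / L);
      disp[a] = vadd(disp[a], fv);
      disp[b] = vsub(disp[b], fv);
    }
    // hard-core repulsion between non-bonded near pairs: keeps the surface
    // from passing through itself when recovering from rough (post-anneal)
    // configurations
    if (safe) {
      CellList cl;
      double rr = 0.98 * u;
      cl.build(m.x, rr + 1e-9);
      for (int i = 0; i < m.nv(); ++i) {
        cl.for_neighbours(m.x[i], [&](int j) {
          if (j <= i || m.bonded(i, j)) return;
          Vec3 d = vsub(m.x[j], m.x[i]);
          double r = vnorm(d);
          if (r >= rr || r < 1e-12) return;
          Vec3 fv = vscale(d, 12.0 * (rr - r) / r);
          disp[i] = vsub(disp[i], fv);
          disp[j] = vadd(disp[j], fv);
        });
      }
    }
    for (int i = 0; i < m.nv(); ++i) {
      Vec3 step = vscale(disp[i], 0.25 / m.vnbr[i].size());
      double sn = vnorm(step);
      if (safe && sn > 0.1 * l0) step = vscale(step, 0.1 * l0 / sn);
      m.x[i] = vscale(vunit(vadd(m.x[i], step)), Rt);
    }
    if ((it + 1) % 50 == 0) {
      double me = 0.0;
      for (auto &e : m.edges) me += vnorm(vsub(m.x[e[0]], m.x[e[1]]));
      me /= m.ne();
      Rt *= l0 / me;
      for (auto &pt : m.x) pt = vscale(vunit(pt), Rt);
    }
  }
  // exact mean-edge rescale
  double me = 0.0;
  for (auto &e : m.edges) me += vnorm(vsub(m.x[e[0]], m.x[e[1]]));
  me /= m.ne();
  double s = l0 / me;
  Rt *= s;
  for (auto &pt : m.x) pt = vscale(pt, s);
}

// [[Rcpp::export]]
List cpp_build_sphere_mesh(int n_vertices, double l0, int relax_iters,
                           bool verbose = false) {
  if (n_vertices < 12) stop("need at least 12 vertices");
  // start from the icosphere level nearest the requested count (above or
  // below), then split longest edges up or collapse shortest edges down
  Mesh m = icosahedron();
  while (m.nv() < n_vertices) {
    int below = m.nv(), above = 4 * below - 6;
    if (above >= n_vertices) {
      // split up from below only when few splits are needed (splitting scars
      // the lattice more than collapsing); otherwise collapse down from above
      bool split_ok = (n_vertices - below) <= above - n_vertices &&
                      (n_vertices - below) * 4 <= below;
      if (!split_ok) loop_subdivide_sphere(m);
      break;
    }
    loop_subdivide_sphere(m);
  }
  if (m.nv() > n_vertices) collapse_to_count(m, n_vertices);
  while (m.nv() < n_vertices) {
    int best = -1;
    double bl = -1.0;
    for (int e = 0; e < m.ne(); ++e) {
      double L = vnorm(vsub(m.x[m.edges[e][0]], m.x[m.edges[e][1]]));
      if (L > bl) { bl = L; best = e; }
    }
    m.split_edge(best, true);
  }
  // relax on a sphere of the radius an all-equilateral (side l0) mesh of this
  // face count would enclose
  double Rt = std::sqrt(m.nf() * (std::sqrt(3.0) / 4.0) * l0 * l0 / (4.0 * M_PI));
  for (auto &pt : m.x) pt = vscale(vunit(pt), Rt);
  spring_relax(m, l0, Rt, relax_iters);
  // if edges still violate the hard window, anneal with the Monte-Carlo
  // engine in soft-bond mode (harmonic bond + radial springs, flips on):
  // thermal noise escapes the frustrated defect configurations that purely
  // deterministic relaxation cannot
  double u = l0 / 1.35;
  for (int round = 0; round < 6; ++round) {
    double emin0 = R_PosInf, emax0 = 0.0;
    for (auto &e : m.edges) {
      double L = vnorm(vsub(m.x[e[0]], m.x[e[1]]));
      emin0 = std::min(emin0, L);
      emax0 = std::max(emax0, L);
    }
    if (emin0 > 1.005 * u && emax0 < 1.695 * u) break;
    Engine eng;
    eng.m = m;
    eng.p.kappa = 0.0; eng.p.kA = 0.0; eng.p.w = 0.0; eng.p.Fmag = 0.0;
    eng.p.c0 = 0.0; eng.p.l_min = u; eng.p.l_max = R_PosInf;
    eng.p.a0 = 1.0; eng.p.r0 = u; eng.p.wall_d = R_PosInf;
    eng.p.soft = true; eng.p.k_bond = 20.0 / (u * u);
    eng.p.l0_rest = l0; eng.p.k_sphere = 20.0 / (u * u); eng.p.R_sphere = Rt;
    eng.delta = 0.12 * u;
    eng.prot.assign(m.nv(), 0);
    eng.init();
    double kts[5] = {0.5, 0.2, 0.08, 0.02, 0.005};
    int sweeps = 60 + 60 * round;
    for (int s = 0; s < 5; ++s) {
      eng.p.kT = kts[s];
      int ns = (s >= 3) ? 2 * sweeps : sweeps;  // linger in the cold stages
      for (int t = 0; t < ns; ++t) eng.sweep(true, false);
    }
    if (verbose) {
      double e0 = R_PosInf, e1 = 0.0;
      for (auto &e : eng.m.edges) {
        double L = vnorm(vsub(eng.m.x[e[0]], eng.m.x[e[1]]));
        e0 = std::min(e0, L); e1 = std::max(e1, L);
      }
      Rcout << "round " << round << " post-anneal edges [" << e0 << ", "
            << e1 << "] acc_move " << eng.acc_move << "/" << eng.try_move
            << " acc_flip " << eng.acc_flip << "/" << eng.try_flip << "\n";
    }
    m = eng.m;
    spring_relax(m, l0, Rt, 10, true);  // light tidy-up only
    if (verbose) {
      double e0 = R_PosInf, e1 = 0.0;
      for (auto &e : m.edges) {
        double L = vnorm(vsub(m.x[e[0]], m.x[e[1]]));
        e0 = std::min(e0, L); e1 = std::max(e1, L);
      }
      Rcout << "round " << round << " post-relax edges [" << e0 << ", "
            << e1 << "]\n";
    }
  }
  double emin = R_PosInf, emax = 0.0;
  for (auto &e : m.edges) {
    double L = vnorm(vsub(m.x[e[0]], m.x[e[1]]));
    emin = std::min(emin, L);
    emax = std::max(emax, L);
  }
  List out = mesh_to_r(m);
  out["edge_min"] = emin;
  out["edge_max"] = emax;
  return out;
}

static Engine engine_from_r(NumericMatrix pos, IntegerMatrix faces,
                            LogicalVector protein, List params, double delta) {
  Engine eng;
  eng.m = mesh_from_r(pos, faces);
  eng.p = params_from_r(params);
  eng.delta = delta;
  eng.prot.resize(eng.m.nv());
  for (int i = 0; i < eng.m.nv(); ++i) eng.prot[i] = protein[i] ? 1 : 0;
  eng.init();
  return eng;
}

static void gyration(const std::vector<Vec3> &x, double lam[3]) {
  int n = (int)x.size();
  Vec3 c = {0, 0, 0};
  for (auto &p : x) c = vadd(c, p);
  c = vscale(c, 1.0 / n);
  double S[3][3] = {{0}};
  for (auto &pt : x) {
    Vec3 d = vsub(pt, c);
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) S[a][b] += d[a] * d[b] / n;
  }
  // symmetric 3x3 eigenvalues (closed form)
  double p1 = S[0][1] * S[0][1] + S[0][2] * S[0][2] + S[1][2] * S[1][2];
  double q = (S[0][0] + S[1][1] + S[2][2]) / 3.0;
  double p2 = (S[0][0] - q) * (S[0][0] - q) + (S[1][1] - q) * (S[1][1] - q) +
              (S[2][2] - q) * (S[2][2] - q) + 2.0 * p1;
  double pp = std::sqrt(std::max(p2 / 6.0, 0.0));
  if (pp < 1e-300) { lam[0] = lam[1] = lam[2] = q; return; }
  double B[3][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) B[a][b] = (S[a][b] - (a == b ? q : 0.0)) / pp;
  double detB = B[0][0] * (B[1][1] * B[2][2] - B[1][2] * B[2][1]) -
                B[0][1] * (B[1][0] * B[2][2] - B[1][2] * B[2][0]) +
                B[0][2] * (B[1][0] * B[2][1] - B[1][1] * B[2][0]);
  double r = std::min(std::max(detB / 2.0, -1.0), 1.0);
  double phi = std::acos(r) / 3.0;
  lam[0] = q + 2.0 * pp * std::cos(phi);
  lam[2] = q + 2.0 * pp * std::cos(phi + 2.0 * M_PI / 3.0);
  lam[1] = 3.0 * q - lam[0] - lam[2];
}

// [[Rcpp::export]]
NumericVector cpp_gyration_eigen(NumericMatrix pos) {
  std::vector<Vec3> x(pos.nrow());
  for (int i = 0; i < pos.nrow(); ++i) x[i] = {pos(i, 0), pos(i, 1), pos(i, 2)};
  double lam[3];
  gyration(x, lam);
  return NumericVector::create(lam[0], lam[1], lam[2]);
}

// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix pos, IntegerMatrix faces, LogicalVector protein,
                List params, int n_sweeps, double delta, int sample_every,
                bool do_flips, bool do_hops) {
  Engine eng = engine_from_r(pos, faces, protein, params, delta);
  std::vector<double> s_WA, s_Wb, s_Wd, s_WF, s_A, s_asph, s_sweep;
  for (int s = 1; s <= n_sweeps; ++s) {
    eng.sweep(do_flips, do_hops);
    if (sample_every > 0 && s % sample_every == 0) {
      double A = 0.0;
      for (int f = 0; f < eng.m.nf(); ++f) A += eng.m.face_area(f);
      double lam[3];
      gyration(eng.m.x, lam);
      double tr = lam[0] + lam[1] + lam[2];
      double asph = ((lam[0] - lam[1]) * (lam[0] - lam[1]) +
                     (lam[1] - lam[2]) * (lam[1] - lam[2]) +
                     (lam[2] - lam[0]) * (lam[2] - lam[0])) /
                    (2.0 * tr * tr);
      s_sweep.push_back(s);
      s_WA.push_back(eng.E.WA);
      s_Wb.push_back(eng.E.Wb);
      s_Wd.push_back(eng.E.Wd);
      s_WF.push_back(eng.E.WF);
      s_A.push_back(A);
      s_asph.push_back(asph);
    }
  }
  List out = mesh_to_r(eng.m);
  LogicalVector pr(eng.m.nv());
  for (int i = 0; i < eng.m.nv(); ++i) pr[i] = eng.prot[i] != 0;
  out["protein"] = pr;
  out["energy"] = List::create(_["W_A"] = eng.E.WA, _["W_b"] = eng.E.Wb,
                               _["W_d"] = eng.E.Wd, _["W_F"] = eng.E.WF,
                               _["W"] = eng.E.total());
  out["acceptance"] = List::create(
      _["vertex_move"] = NumericVector::create((double)eng.acc_move, (double)eng.try_move),
      _["bond_flip"] = NumericVector::create((double)eng.acc_flip, (double)eng.try_flip),
      _["protein_hop"] = NumericVector::create((double)eng.acc_hop, (double)eng.try_hop));
  out["samples"] = DataFrame::create(
      _["sweep"] = wrap(s_sweep), _["W_A"] = wrap(s_WA), _["W_b"] = wrap(s_Wb),
      _["W_d"] = wrap(s_Wd), _["W_F"] = wrap(s_WF), _["area"] = wrap(s_A),
      _["asphericity"] = wrap(s_asph));
  return out;
}

// single-kind attempts (exposes the elementary move surface for testing)
// [[Rcpp::export]]
List cpp_mc_attempts(NumericMatrix pos, IntegerMatrix faces,
                     LogicalVector protein, List params, std::string kind,
                     int n_attempts, double delta) {
  Engine eng = engine_from_r(pos, faces, protein, params, delta);
  int accepted = 0;
  for (int t = 0; t < n_attempts; ++t) {
    bool ok;
    if (kind == "vertex_move") ok = eng.attempt_vertex_move();
    else if (kind == "bond_flip") ok = eng.attempt_bond_flip();
    else if (kind == "protein_hop") ok = eng.attempt_protein_hop();
    else stop("unknown move kind");
    if (ok) ++accepted;
  }
  List out = mesh_to_r(eng.m);
  LogicalVector pr(eng.m.nv());
  for (int i = 0; i < eng.m.nv(); ++i) pr[i] = eng.prot[i] != 0;
  out["protein"] = pr;
  out["accepted"] = accepted;
  out["energy"] = List::create(_["W_A"] = eng.E.WA, _["W_b"] = eng.E.Wb,
                               _["W_d"] = eng.E.Wd, _["W_F"] = eng.E.WF,
                               _["W"] = eng.E.total());
  return out;
}

// Bernoulli sampling of the bare Metropolis rule at fixed dE
// [[Rcpp::export]]
int cpp_metropolis_trials(double dE, double kT, int n) {
  int acc = 0;
  for (int t = 0; t < n; ++t) {
    if (dE <= 0 || unif_rand() < std::exp(-dE / kT)) ++acc;
  }
  return acc;
}

// minimum distance over non-bonded vertex pairs (brute force; for validation)
// [[Rcpp::export]]
double cpp_min_nonbonded_dist(NumericMatrix pos, IntegerMatrix faces) {
  Mesh m = mesh_from_r(pos, faces);
  double best = R_PosInf;
  for (int i = 0; i < m.nv(); ++i)
    for (int j = i + 1; j < m.nv(); ++j) {
      if (m.bonded(i, j)) continue;
      best = std::min(best, vnorm(vsub(m.x[i], m.x[j])));
    }
  return best;
}
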