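// Incremental 3-D Delaunay triangulation (Bowyer-Watson) returning the
// edge (adjacency) set, which is all downstream code needs: two sites are
// Delaunay-adjacent exactly when their Voronoi cells share a facet.
//
// A far super-tetrahedron (side ~1e4 x the bounding radius) hosts the
// incremental construction; tetrahedra touching its vertices are dropped at
// the end.  The result is the exact Delaunay triangulation of the input
// points restricted to witness spheres smaller than the super-tetrahedron
// distance, which is always the case once the caller bounds the point set
// (the package surrounds structures with a pseudo-solvent shell).
//
// Predicates are plain double arithmetic; callers joggle degenerate
// (cospherical/coplanar) inputs, see delaunay_edges() on the R side.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <set>
#include <utility>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tet {
  int v[4];   // vertex indices; >= n_real are super vertices
  int nb[4];  // neighbour tetra opposite v[k], -1 = outside world
  bool alive;
};

inline double orient3d(const double *a, const double *b, const double *c,
                       const double *d) {
  const double bx = b[0] - a[0], by = b[1] - a[1], bz = b[2] - a[2];
  const double cx = c[0] - a[0], cy = c[1] - a[1], cz = c[2] - a[2];
  const double dx = d[0] - a[0], dy = d[1] - a[1], dz = d[2] - a[2];
  return bx * (cy * dz - cz * dy) - by * (cx * dz - cz * dx) +
         bz * (cx * dy - cy * dx);
}

// > 0 iff e lies strictly inside the circumsphere of (a,b,c,d), which must
// be positively oriented (orient3d(a,b,c,d) > 0).
inline double insphere(const double *a, const double *b, const double *c,
                       const double *d, const double *e) {
  double m[4][4];
  const double *p[4] = {a, b, c, d};
  for (int i = 0; i < 4; ++i) {
    const double x = p[i][0] - e[0], y = p[i][1] - e[1], z = p[i][2] - e[2];
    m[i][0] = x; m[i][1] = y; m[i][2] = z; m[i][3] = x * x + y * y + z * z;
  }
  // 4x4 determinant by cofactor expansion along the last column
  double det = 0.0;
  for (int i = 0; i < 4; ++i) {
    double sub[3][3];
    int r = 0;
    for (int j = 0; j < 4; ++j) {
      if (j == i) continue;
      sub[r][0] = m[j][0]; sub[r][1] = m[j][1]; sub[r][2] = m[j][2];
      ++r;
    }
    const double d3 = sub[0][0] * (sub[1][1] * sub[2][2] - sub[1][2] * sub[2][1]) -
                      sub[0][1] * (sub[1][0] * sub[2][2] - sub[1][2] * sub[2][0]) +
                      sub[0][2] * (sub[1][0] * sub[2][1] - sub[1][1] * sub[2][0]);
    det += ((i + 3) % 2 == 0 ? 1.0 : -1.0) * m[i][3] * d3;
  }
  // sign fixed so that, for a positively oriented tetra, inside => positive
  return -det;
}

class Triangulation {
public:
  std::vector<Tet> tets;
  const std::vector<double> &pts;  // flat xyz
  explicit Triangulation(const std::vector<double> &p) : pts(p) {}
  const double *P(int i) const { return &pts[3 * i]; }

  bool conflict(const Tet &t, const double *p) const {
    return insphere(P(t.v[0]), P(t.v[1]), P(t.v[2]), P(t.v[3]), p) > 0.0;
  }

  int add_tet(int a, int b, int c, int d) {
    Tet t;
    t.v[0] = a; t.v[1] = b; t.v[2] = c; t.v[3] = d;
    t.nb[0] = t.nb[1] = t.nb[2] = t.nb[3] = -1;
    t.alive = true;
    tets.push_back(t);
    return (int)tets.size() - 1;
  }

  void insert(const double *p, int pidx) {
    // find any tetra whose circumsphere contains p (the conflict region is
    // connected, so any seed works)
    int seed = -1;
    for (int i = (int)tets.size() - 1; i >= 0; --i) {
      if (tets[i].alive && conflict(tets[i], p)) { seed = i; break; }
    }
    if (seed < 0) stop("point location failed (degenerate input?)");

    // grow the cavity by BFS over conflicting neighbours
    std::vector<int> cavity;
    std::vector<char> in_cavity(tets.size(), 0);
    std::vector<int> stack;
    stack.push_back(seed);
    in_cavity[seed] = 1;
    while (!stack.empty()) {
      int t = stack.back(); stack.pop_back();
      cavity.push_back(t);
      for (int k = 0; k < 4; ++k) {
        int u = tets[t].nb[k];
        if (u >= 0 && !in_cavity[u] && conflict(tets[u], p)) {
          in_cavity[u] = 1;
          stack.push_back(u);
        }
      }
    }

    // collect boundary facets (facet, outside tetra)
    struct BFacet { int f[3]; int outside; };
    std::vector<BFacet> bnd;
    for (int idx : cavity) {
      const Tet &t = tets[idx];
      for (int k = 0; k < 4; ++k) {
        int u = t.nb[k];
        if (u < 0 || !in_cavity[u]) {
          BFacet bf;
          int r = 0;
          for (int j = 0; j < 4; ++j) if (j != k) bf.f[r++] = t.v[j];
          bf.outside = u;
          bnd.push_back(bf);
        }
      }
    }
    for (int idx : cavity) tets[idx].alive = false;

    // retriangulate: one new tetra per boundary facet, linked to siblings
    std::map<std::pair<int, int>, std::pair<int, int> > edge_map;
    std::vector<int> created;
    for (const BFacet &bf : bnd) {
      int f0 = bf.f[0], f1 = bf.f[1], f2 = bf.f[2];
      if (orient3d(P(f0), P(f1), P(f2), p) < 0.0) std::swap(f1, f2);
      int nt = add_tet(f0, f1, f2, pidx);
      created.push_back(nt);
      tets[nt].nb[3] = bf.outside;
      if (bf.outside >= 0) {
        Tet &u = tets[bf.outside];
        for (int k = 0; k < 4; ++k) {
          int vv = u.v[k];
          if (vv != f0 && vv != f1 && vv != f2) { u.nb[k] = nt; break; }
        }
      }
      // internal facets each contain pidx; key them by the opposite edge
      const int vs[3] = {f0, f1, f2};
      for (int k = 0; k < 3; ++k) {  // facet opposite vs[k]
        int e1 = vs[(k + 1) % 3], e2 = vs[(k + 2) % 3];
        std::pair<int, int> key(std::min(e1, e2), std::max(e1, e2));
        std::map<std::pair<int, int>, std::pair<int, int> >::iterator it =
            edge_map.find(key);
        if (it == edge_map.end()) {
          edge_map[key] = std::make_pair(nt, k);
        } else {
          tets[nt].nb[k] = it->second.first;
          tets[it->second.first].nb[it->second.second] = nt;
          edge_map.erase(it);
        }
      }
    }
    if (!edge_map.empty()) stop("cavity retriangulation failed (degenerate input?)");
  }
};

}  // namespace

// [[Rcpp::export(name = ".delaunay_edges_cpp")]]
IntegerMatrix delaunay_edges_cpp(NumericMatrix coords) {
  const int n = coords.nrow();
  if (n < 2) return IntegerMatrix(0, 2);

  // centre and find scale
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < n; ++i) { cx += coords(i, 0); cy += coords(i, 1); cz += coords(i, 2); }
  cx /= n; cy /= n; cz /= n;
  std::vector<double> pts(3 * (n + 4));
  double rmax = 1.0;
  for (int i = 0; i < n; ++i) {
    const double x = coords(i, 0) - cx, y = coords(i, 1) - cy, z = coords(i, 2) - cz;
    pts[3 * i] = x; pts[3 * i + 1] = y; pts[3 * i + 2] = z;
    const double r = std::sqrt(x * x + y * y + z * z);
    if (r > rmax) rmax = r;
  }
  const double D = 1e4 * rmax;
  const double sv[4][3] = {{D, D, D}, {D, -D, -D}, {-D, D, -D}, {-D, -D, D}};
  for (int k = 0; k < 4; ++k)
    for (int j = 0; j < 3; ++j) pts[3 * (n + k) + j] = sv[k][j];

  Triangulation tri(pts);
  // super-tetra must be positively oriented
  if (orient3d(&pts[3 * n], &pts[3 * (n + 1)], &pts[3 * (n + 2)], &pts[3 * (n + 3)]) > 0)
    tri.add_tet(n, n + 1, n + 2, n + 3);
  else
    tri.add_tet(n, n + 2, n + 1, n + 3);

  for (int i = 0; i < n; ++i) tri.insert(tri.P(i), i);

  std::set<std::pair<int, int> > edges;
  for (const Tet &t : tri.tets) {
    if (!t.alive) continue;
    for (int a = 0; a < 4; ++a)
      for (int b = a + 1; b < 4; ++b) {
        const int i = t.v[a], j = t.v[b];
        if (i < n && j < n)
          edges.insert(std::make_pair(std::min(i, j), std::max(i, j)));
      }
  }
  IntegerMatrix out((int)edges.size(), 2);
  int r = 0;
  for (std::set<std::pair<int, int> >::const_iterator it = edges.begin();
       it != edges.end(); ++it, ++r) {
    out(r, 0) = it->first + 1;  // 1-based for R
    out(r, 1) = it->second + 1;
  }
  return out;
}
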