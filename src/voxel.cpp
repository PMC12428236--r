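// Low-level 3D voxel primitives: connected-component labeling, anisotropic
// Euclidean distance transform, topology-preserving thinning, convex hull
// volume. Arrays are passed as flat vectors in R's column-major order with
// dim = (nz, ny, nx), i.e. linear index = z + nz*(y + ny*x), all 0-based here.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <array>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Dims {
  int nz, ny, nx;
  R_xlen_t n() const { return (R_xlen_t)nz * ny * nx; }
  inline R_xlen_t idx(int z, int y, int x) const {
    return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
  }
};

Dims get_dims(const IntegerVector& dim) {
  if (dim.size() != 3) stop("dim must have length 3 (nz, ny, nx)");
  Dims d{dim[0], dim[1], dim[2]};
  if (d.nz < 1 || d.ny < 1 || d.nx < 1) stop("all dimensions must be >= 1");
  return d;
}

// neighbor offsets for a given connectivity (6, 18 or 26)
std::vector<std::array<int,3>> neighbor_offsets(int connectivity) {
  std::vector<std::array<int,3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dz, dy, dx});
      }
  return off;
}

} // namespace

// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  Dims d = get_dims(dim);
  if (mask.size() != d.n()) stop("mask length does not match dim");
  auto off = neighbor_offsets(connectivity);

  IntegerVector labels(mask.size(), 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        R_xlen_t i = d.idx(z, y, x);
        if (!mask[i] || labels[i] != 0) continue;
        ++next;
        labels[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t cur = stack.back(); stack.pop_back();
          int cz = (int)(cur % d.nz);
          R_xlen_t rest = cur / d.nz;
          int cy = (int)(rest % d.ny);
          int cx = (int)(rest / d.ny);
          for (auto& o : off) {
            int z2 = cz + o[0], y2 = cy + o[1], x2 = cx + o[2];
            if (z2 < 0 || z2 >= d.nz || y2 < 0 || y2 >= d.ny || x2 < 0 || x2 >= d.nx)
              continue;
            R_xlen_t j = d.idx(z2, y2, x2);
            if (mask[j] && labels[j] == 0) {
              labels[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
  labels.attr("n") = next;
  return labels;
}

namespace {

// Felzenszwalb & Huttenlocher 1D squared distance transform with physical
// sample spacing s; f is overwritten with the transform.
void dt1d(std::vector<double>& f, double s) {
  int n = (int)f.size();
  if (n == 1) return;
  std::vector<int> v(n);
  std::vector<double> zb(n + 1), out(n);
  int k = 0;
  v[0] = 0;
  zb[0] = -HUGE_VAL;
  zb[1] = HUGE_VAL;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    while (true) {
      double xv = v[k] * s;
      double sden = 2.0 * (xq - xv);
      double scut = (f[q] + xq * xq - f[v[k]] - xv * xv) / sden;
      if (scut <= zb[k]) { --k; }
      else {
        ++k;
        v[k] = q;
        zb[k] = scut;
        zb[k + 1] = HUGE_VAL;
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (zb[k + 1] < xq) ++k;
    double xv = v[k] * s;
    out[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
  f = out;
}

} // namespace

// Euclidean distance (physical units) from each foreground voxel to the
// nearest background voxel. Background voxels get 0. `spacing` = (dz, dy, dx).
// [[Rcpp::export(name = ".edt_3d")]]
NumericVector edt_3d(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  Dims d = get_dims(dim);
  if (mask.size() != d.n()) stop("mask length does not match dim");
  if (spacing.size() != 3) stop("spacing must have length 3");
  const double INF = 1e300;
  NumericVector g(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) g[i] = mask[i] ? INF : 0.0;

  // pass along z (fastest axis)
  {
    std::vector<double> line(d.nz);
    for (int x = 0; x < d.nx; ++x)
      for (int y = 0; y < d.ny; ++y) {
        for (int z = 0; z < d.nz; ++z) line[z] = g[d.idx(z, y, x)];
        dt1d(line, spacing[0]);
        for (int z = 0; z < d.nz; ++z) g[d.idx(z, y, x)] = line[z];
      }
  }
  // pass along y
  {
    std::vector<double> line(d.ny);
    for (int x = 0; x < d.nx; ++x)
      for (int z = 0; z < d.nz; ++z) {
        for (int y = 0; y < d.ny; ++y) line[y] = g[d.idx(z, y, x)];
        dt1d(line, spacing[1]);
        for (int y = 0; y < d.ny; ++y) g[d.idx(z, y, x)] = line[y];
      }
  }
  // pass along x
  {
    std::vector<double> line(d.nx);
    for (int z = 0; z < d.nz; ++z)
      for (int y = 0; y < d.ny; ++y) {
        for (int x = 0; x < d.nx; ++x) line[x] = g[d.idx(z, y, x)];
        dt1d(line, spacing[2]);
        for (int x = 0; x < d.nx; ++x) g[d.idx(z, y, x)] = line[x];
      }
  }
  for (R_xlen_t i = 0; i < g.size(); ++i) g[i] = std::sqrt(g[i]);
  return g;
}

namespace {

// ---- simple-point machinery for thinning --------------------------------
// Works on the 3x3x3 neighborhood packed as nb[27], index = (dz+1) +
// 3*((dy+1) + 3*(dx+1)); center = 13.

inline int pack(int dz, int dy, int dx) { return (dz + 1) + 3 * ((dy + 1) + 3 * (dx + 1)); }

// count 26-connected components of foreground among the 26 neighbors
int fg_components26(const bool nb[27]) {
  int comp = 0;
  bool seen[27] = {false};
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comp;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int c = stack[--top];
      int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int z2 = cz + dz, y2 = cy + dy, x2 = cx + dx;
            if (z2 < 0 || z2 > 2 || y2 < 0 || y2 > 2 || x2 < 0 || x2 > 2) continue;
            int t = z2 + 3 * (y2 + 3 * x2);
            if (t == 13 || t == c || !nb[t] || seen[t]) continue;
            seen[t] = true;
            stack[top++] = t;
          }
    }
  }
  return comp;
}

// count 6-connected components of background restricted to the
// 18-neighborhood that contain at least one 6-neighbor of the center
int bg_components6_in18(const bool nb[27]) {
  // 18-neighborhood: |dz|+|dy|+|dx| in {1,2}
  bool in18[27] = {false};
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (m >= 1 && m <= 2) in18[pack(dz, dy, dx)] = true;
      }
  bool seen[27] = {false};
  int comp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (!in18[s] || nb[s] || seen[s]) continue;
    // grow a 6-connected background component within the 18-neighborhood
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    bool touches_face = false;
    while (top) {
      int c = stack[--top];
      int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      int m = std::abs(cz - 1) + std::abs(cy - 1) + std::abs(cx - 1);
      if (m == 1) touches_face = true;
      static const int face[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int f = 0; f < 6; ++f) {
        int z2 = cz + face[f][0], y2 = cy + face[f][1], x2 = cx + face[f][2];
        if (z2 < 0 || z2 > 2 || y2 < 0 || y2 > 2 || x2 < 0 || x2 > 2) continue;
        int t = z2 + 3 * (y2 + 3 * x2);
        if (t == 13 || !in18[t] || nb[t] || seen[t]) continue;
        seen[t] = true;
        stack[top++] = t;
      }
    }
    if (touches_face) ++comp;
  }
  return comp;
}

// a voxel is simple iff deleting it preserves local topology
inline bool is_simple(const bool nb[27]) {
  return fg_components26(nb) == 1 && bg_components6_in18(nb) == 1;
}

} // namespace

// Topology-preserving curve thinning, layer-synchronous: each iteration
// freezes the current border set (foreground voxels with a background face
// neighbor), orders it by increasing `priority` (the Euclidean distance
// transform, which keeps the skeleton medially centered; ties by index),
// and removes its members sequentially, re-checking simplicity at removal
// time. Curve endpoints (exactly one foreground 26-neighbor) are preserved.
// Freezing the border per iteration peels the object layer by layer, so a
// tube collapses to a protected one-voxel chain before erosion can run down
// its axis; sequential simple-point removal cannot change topology.
// [[Rcpp::export(name = ".thin_3d")]]
LogicalVector thin_3d(LogicalVector mask, IntegerVector dim, NumericVector priority) {
  Dims d = get_dims(dim);
  if (mask.size() != d.n()) stop("mask length does not match dim");
  if (priority.size() != mask.size()) stop("priority length does not match mask");

  std::vector<uint8_t> fg(mask.size());
  std::vector<R_xlen_t> fglist;
  for (R_xlen_t i = 0; i < mask.size(); ++i) {
    fg[i] = mask[i] ? 1 : 0;
    if (fg[i]) fglist.push_back(i);
  }

  auto neighbors27 = [&](R_xlen_t i, bool nb[27], int& fgcount) {
    int cz = (int)(i % d.nz);
    R_xlen_t rest = i / d.nz;
    int cy = (int)(rest % d.ny);
    int cx = (int)(rest / d.ny);
    fgcount = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int p = pack(dz, dy, dx);
          int z2 = cz + dz, y2 = cy + dy, x2 = cx + dx;
          bool v = false;
          if (z2 >= 0 && z2 < d.nz && y2 >= 0 && y2 < d.ny && x2 >= 0 && x2 < d.nx)
            v = fg[d.idx(z2, y2, x2)] != 0;
          nb[p] = v;
          if (p != 13 && v) ++fgcount;
        }
  };

  // a voxel exposed (background face neighbor) in the given direction;
  // faces outside the stack do not count as exposure
  static const int face6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  auto exposed = [&](R_xlen_t i, int f) {
    int cz = (int)(i % d.nz);
    R_xlen_t rest = i / d.nz;
    int cy = (int)(rest % d.ny);
    int cx = (int)(rest / d.ny);
    int z2 = cz + face6[f][0], y2 = cy + face6[f][1], x2 = cx + face6[f][2];
    if (z2 < 0 || z2 >= d.nz || y2 < 0 || y2 >= d.ny || x2 < 0 || x2 >= d.nx)
      return false;
    return !fg[d.idx(z2, y2, x2)];
  };

  bool nb[27];
  int fgcount;
  std::vector<std::pair<double, R_xlen_t>> cand;
  while (true) {
    R_xlen_t removed_cycle = 0;
    // six directional subiterations per cycle: the candidate set of each
    // pass is frozen before the pass, so removal in a growth direction is
    // bounded to one voxel layer per cycle and thin branches are never
    // consumed end-to-end
    for (int f = 0; f < 6; ++f) {
      cand.clear();
      for (R_xlen_t i : fglist)
        if (fg[i] && exposed(i, f)) cand.push_back({priority[i], i});
      std::sort(cand.begin(), cand.end());
      R_xlen_t removed = 0;
      for (auto& pr : cand) {
        R_xlen_t i = pr.second;
        if (!fg[i]) continue;
        neighbors27(i, nb, fgcount);
        // curve endpoint: one foreground neighbor, or two that are mutually
        // 26-adjacent (a digital line end can carry a chord adjacency)
        if (fgcount == 1) continue;
        if (fgcount == 2) {
          int a = -1, b = -1;
          for (int s = 0; s < 27; ++s)
            if (s != 13 && nb[s]) { if (a < 0) a = s; else b = s; }
          int az = a % 3, ay = (a / 3) % 3, ax = a / 9;
          int bz = b % 3, by = (b / 3) % 3, bx = b / 9;
          if (std::abs(az - bz) <= 1 && std::abs(ay - by) <= 1 &&
              std::abs(ax - bx) <= 1)
            continue;
        }
        if (!is_simple(nb)) continue;  // would change topology
        fg[i] = 0;
        ++removed;
      }
      removed_cycle += removed;
      if (removed > 0) {
        std::vector<R_xlen_t> nxt;
        nxt.reserve(fglist.size() - removed);
        for (R_xlen_t i : fglist) if (fg[i]) nxt.push_back(i);
        fglist.swap(nxt);
      }
    }
    if (removed_cycle == 0) break;
  }

  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < (R_xlen_t)fg.size(); ++i) out[i] = fg[i] != 0;
  return out;
}

// ---- 3D convex hull volume (incremental / beneath-beyond) -----------------

namespace {

struct Vec3 {
  double x, y, z;
  Vec3 operator-(const Vec3& o) const { return {x - o.x, y - o.y, z - o.z}; }
  Vec3 cross(const Vec3& o) const {
    return {y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x};
  }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  double norm() const { return std::sqrt(dot(*this)); }
};

struct Facet {
  int a, b, c;
  Vec3 n;      // unit outward normal
  double off;  // n . p for p on plane
  bool alive;
};

void facet_plane(Facet& f, const std::vector<Vec3>& P) {
  Vec3 n = (P[f.b] - P[f.a]).cross(P[f.c] - P[f.a]);
  double nn = n.norm();
  if (nn > 0) { n.x /= nn; n.y /= nn; n.z /= nn; }
  f.n = n;
  f.off = n.dot(P[f.a]);
}

} // namespace

// Volume of the convex hull of an n x 3 matrix of points (rows = points,
// columns in any fixed order). Returns volume 0 with degenerate = TRUE for
// fewer than 4 points or (near-)coplanar input.
// [[Rcpp::export(name = ".hull3_volume")]]
List hull3_volume(NumericMatrix pts) {
  int n = pts.nrow();
  if (pts.ncol() != 3) stop("points must be an n x 3 matrix");
  std::vector<Vec3> P(n);
  double scale = 0;
  for (int i = 0; i < n; ++i) {
    P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    scale = std::max({scale, std::abs(P[i].x), std::abs(P[i].y), std::abs(P[i].z)});
  }
  if (scale == 0) scale = 1;
  const double eps = 1e-9 * scale;

  if (n < 4) return List::create(_["volume"] = 0.0, _["degenerate"] = true);

  // initial tetrahedron: spread points
  int i0 = 0;
  for (int i = 1; i < n; ++i)
    if (P[i].x < P[i0].x || (P[i].x == P[i0].x && (P[i].y < P[i0].y ||
        (P[i].y == P[i0].y && P[i].z < P[i0].z)))) i0 = i;
  int i1 = -1; double best = -1;
  for (int i = 0; i < n; ++i) {
    double dd = (P[i] - P[i0]).norm();
    if (dd > best) { best = dd; i1 = i; }
  }
  if (best <= eps) return List::create(_["volume"] = 0.0, _["degenerate"] = true);
  int i2 = -1; best = -1;
  for (int i = 0; i < n; ++i) {
    double dd = (P[i1] - P[i0]).cross(P[i] - P[i0]).norm();
    if (dd > best) { best = dd; i2 = i; }
  }
  if (best <= eps * (P[i1] - P[i0]).norm())
    return List::create(_["volume"] = 0.0, _["degenerate"] = true);
  Vec3 nrm = (P[i1] - P[i0]).cross(P[i2] - P[i0]);
  double nn = nrm.norm();
  nrm.x /= nn; nrm.y /= nn; nrm.z /= nn;
  int i3 = -1; best = -1;
  for (int i = 0; i < n; ++i) {
    double dd = std::abs(nrm.dot(P[i] - P[i0]));
    if (dd > best) { best = dd; i3 = i; }
  }
  if (best <= eps) return List::create(_["volume"] = 0.0, _["degenerate"] = true);

  std::vector<Facet> F;
  auto add_facet = [&](int a, int b, int c, const Vec3& inside) {
    Facet f{a, b, c, {0,0,0}, 0, true};
    facet_plane(f, P);
    if (f.n.dot(inside) - f.off > 0) { std::swap(f.b, f.c); facet_plane(f, P); }
    F.push_back(f);
  };
  Vec3 centroid{(P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4,
                (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4,
                (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4};
  add_facet(i0, i1, i2, centroid);
  add_facet(i0, i1, i3, centroid);
  add_facet(i0, i2, i3, centroid);
  add_facet(i1, i2, i3, centroid);

  // deterministic shuffled insertion order
  std::vector<int> order;
  order.reserve(n);
  for (int i = 0; i < n; ++i)
    if (i != i0 && i != i1 && i != i2 && i != i3) order.push_back(i);
  uint64_t rng = 88172645463325252ull;
  for (int i = (int)order.size() - 1; i > 0; --i) {
    rng ^= rng << 13; rng ^= rng >> 7; rng ^= rng << 17;
    std::swap(order[i], order[rng % (uint64_t)(i + 1)]);
  }

  for (int p : order) {
    // find visible facets
    std::vector<int> vis;
    for (int fi = 0; fi < (int)F.size(); ++fi) {
      if (!F[fi].alive) continue;
      if (F[fi].n.dot(P[p]) - F[fi].off > eps) vis.push_back(fi);
    }
    if (vis.empty()) continue;
    // horizon: directed edges of visible facets whose reverse is not visible
    std::vector<std::pair<int,int>> edges;
    for (int fi : vis) {
      edges.push_back({F[fi].a, F[fi].b});
      edges.push_back({F[fi].b, F[fi].c});
      edges.push_back({F[fi].c, F[fi].a});
    }
    std::vector<std::pair<int,int>> horizon;
    for (auto& e : edges) {
      bool rev = false;
      for (auto& e2 : edges)
        if (e2.first == e.second && e2.second == e.first) { rev = true; break; }
      if (!rev) horizon.push_back(e);
    }
    for (int fi : vis) F[fi].alive = false;
    for (auto& e : horizon) {
      Facet f{e.first, e.second, p, {0,0,0}, 0, true};
      facet_plane(f, P);
      F.push_back(f);
    }
  }

  // signed volume relative to the initial centroid
  double vol = 0;
  for (auto& f : F) {
    if (!f.alive) continue;
    Vec3 a = P[f.a] - centroid, b = P[f.b] - centroid, c = P[f.c] - centroid;
    vol += a.dot(b.cross(c)) / 6.0;
  }
  return List::create(_["volume"] = std::abs(vol), _["degenerate"] = false);
}
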