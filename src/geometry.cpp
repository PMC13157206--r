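#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable with anisotropic spacing.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, double h, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s;
    for (;;) {
      if (f[v[k]] == INF) { // previous parabola at infinity: replace
        if (k == 0) { v[0] = q; z[0] = -INF; z[1] = INF; s = -INF; break; }
        --k;
        continue;
      }
      double xq = q * h, xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else break;
    }
    if (s != -INF) {
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = INF;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * h;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// squared distance from every voxel to the nearest TRUE voxel
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector vol, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g((size_t)nx * ny * nz);
  for (size_t i = 0; i < g.size(); ++i) g[i] = vol[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = (size_t)k * nx * ny + (size_t)j * nx;
      f.resize(nx); d.resize(nx);
      bool any = false;
      for (int i = 0; i < nx; ++i) { f[i] = g[base + i]; if (f[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f, spacing[0], d, v, z);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)k * nx * ny + i;
      f.resize(ny); d.resize(ny);
      bool any = false;
      for (int j = 0; j < ny; ++j) { f[j] = g[base + (size_t)j * nx]; if (f[j] < INF) any = true; }
      if (!any) continue;
      dt1d(f, spacing[1], d, v, z);
      for (int j = 0; j < ny; ++j) g[base + (size_t)j * nx] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)j * nx + i;
      f.resize(nz); d.resize(nz);
      bool any = false;
      for (int k = 0; k < nz; ++k) { f[k] = g[base + (size_t)k * nx * ny]; if (f[k] < INF) any = true; }
      if (!any) continue;
      dt1d(f, spacing[2], d, v, z);
      for (int k = 0; k < nz; ++k) g[base + (size_t)k * nx * ny] = d[k];
    }

  NumericVector out((size_t)nx * ny * nz);
  for (size_t i = 0; i < g.size(); ++i) out[i] = g[i];
  return out;
}

// ---------------------------------------------------------------------------
// Point-to-triangle-mesh distances with a uniform-grid acceleration
// structure (closest point on triangle via barycentric clamping; Ericson,
// Real-Time Collision Detection).
// ---------------------------------------------------------------------------

struct Vec3 { double x, y, z; };
static inline Vec3 sub(const Vec3& a, const Vec3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }

static double pointTriangleSqDist(const Vec3& p, const Vec3& a, const Vec3& b,
                                  const Vec3& c) {
  Vec3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { Vec3 r = sub(p, a); return dot(r, r); }
  Vec3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { Vec3 r = sub(p, b); return dot(r, r); }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double t = d1 / (d1 - d3);
    Vec3 q = {a.x + t * ab.x, a.y + t * ab.y, a.z + t * ab.z};
    Vec3 r = sub(p, q); return dot(r, r);
  }
  Vec3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { Vec3 r = sub(p, c); return dot(r, r); }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double t = d2 / (d2 - d6);
    Vec3 q = {a.x + t * ac.x, a.y + t * ac.y, a.z + t * ac.z};
    Vec3 r = sub(p, q); return dot(r, r);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    Vec3 q = {b.x + t * (c.x - b.x), b.y + t * (c.y - b.y), b.z + t * (c.z - b.z)};
    Vec3 r = sub(p, q); return dot(r, r);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  Vec3 q = {a.x + ab.x * v + ac.x * w, a.y + ab.y * v + ac.y * w,
            a.z + ab.z * v + ac.z * w};
  Vec3 r = sub(p, q);
  return dot(r, r);
}

// minimum distance from each query point to any triangle of the mesh
// [[Rcpp::export]]
NumericVector cpp_mesh_point_distances(NumericMatrix pts, NumericMatrix V,
                                       IntegerMatrix F) {
  const int np = pts.nrow(), nt = F.nrow();
  NumericVector out(np);
  if (nt == 0) { std::fill(out.begin(), out.end(), R_PosInf); return out; }

  std::vector<Vec3> verts(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) verts[i] = {V(i, 0), V(i, 1), V(i, 2)};

  // mesh bounding box
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (size_t i = 0; i < verts.size(); ++i) {
    const double c[3] = {verts[i].x, verts[i].y, verts[i].z};
    for (int a = 0; a < 3; ++a) {
      lo[a] = std::min(lo[a], c[a]);
      hi[a] = std::max(hi[a], c[a]);
    }
  }
  double ext[3], cell[3];
  int nc[3];
  for (int a = 0; a < 3; ++a) {
    ext[a] = std::max(hi[a] - lo[a], 1e-9);
  }
  // target ~ nt cells total, clamped per-axis to [1, 96]
  double target = std::cbrt((double)std::max(nt, 1));
  for (int a = 0; a < 3; ++a) {
    nc[a] = std::max(1, std::min(96, (int)target));
    cell[a] = ext[a] / nc[a];
  }
  auto cellIndex = [&](double x, int a) {
    int i = (int)std::floor((x - lo[a]) / cell[a]);
    return std::max(0, std::min(nc[a] - 1, i));
  };
  // bin triangles by bbox overlap
  std::vector<std::vector<int>> bins((size_t)nc[0] * nc[1] * nc[2]);
  for (int t = 0; t < nt; ++t) {
    const Vec3& a = verts[F(t, 0) - 1];
    const Vec3& b = verts[F(t, 1) - 1];
    const Vec3& c = verts[F(t, 2) - 1];
    double tlo[3] = {std::min({a.x, b.x, c.x}), std::min({a.y, b.y, c.y}),
                     std::min({a.z, b.z, c.z})};
    double thi[3] = {std::max({a.x, b.x, c.x}), std::max({a.y, b.y, c.y}),
                     std::max({a.z, b.z, c.z})};
    int i0 = cellIndex(tlo[0], 0), i1 = cellIndex(thi[0], 0);
    int j0 = cellIndex(tlo[1], 1), j1 = cellIndex(thi[1], 1);
    int k0 = cellIndex(tlo[2], 2), k1 = cellIndex(thi[2], 2);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          bins[(size_t)k * nc[0] * nc[1] + (size_t)j * nc[0] + i].push_back(t);
  }

  auto cellBoxSqDist = [&](const Vec3& p, int i, int j, int k) {
    double d2 = 0;
    const double pc[3] = {p.x, p.y, p.z};
    const int idx[3] = {i, j, k};
    for (int a = 0; a < 3; ++a) {
      double clo = lo[a] + idx[a] * cell[a];
      double chi = clo + cell[a];
      if (pc[a] < clo) d2 += (clo - pc[a]) * (clo - pc[a]);
      else if (pc[a] > chi) d2 += (pc[a] - chi) * (pc[a] - chi);
    }
    return d2;
  };

  const int kmax = std::max({nc[0], nc[1], nc[2]});
  for (int q = 0; q < np; ++q) {
    Vec3 p = {pts(q, 0), pts(q, 1), pts(q, 2)};
    int ci = cellIndex(p.x, 0), cj = cellIndex(p.y, 1), ck = cellIndex(p.z, 2);
    double best = R_PosInf;
    for (int ring = 0; ring <= kmax; ++ring) {
      double ringMin = R_PosInf;
      bool anyCell = false;
      int i0 = ci - ring, i1 = ci + ring;
      int j0 = cj - ring, j1 = cj + ring;
      int k0 = ck - ring, k1 = ck + ring;
      for (int k = k0; k <= k1; ++k) {
        if (k < 0 || k >= nc[2]) continue;
        for (int j = j0; j <= j1; ++j) {
          if (j < 0 || j >= nc[1]) continue;
          for (int i = i0; i <= i1; ++i) {
            if (i < 0 || i >= nc[0]) continue;
            // shell only: skip interior cells already visited
            if (ring > 0 && i != i0 && i != i1 && j != j0 && j != j1 &&
                k != k0 && k != k1) continue;
            anyCell = true;
            double boxd = cellBoxSqDist(p, i, j, k);
            ringMin = std::min(ringMin, boxd);
            if (boxd >= best) continue;
            const std::vector<int>& tri =
              bins[(size_t)k * nc[0] * nc[1] + (size_t)j * nc[0] + i];
            for (size_t m = 0; m < tri.size(); ++m) {
              int t = tri[m];
              double d2 = pointTriangleSqDist(p, verts[F(t, 0) - 1],
                                              verts[F(t, 1) - 1],
                                              verts[F(t, 2) - 1]);
              if (d2 < best) best = d2;
            }
          }
        }
      }
      if (!anyCell && ring > kmax) break;
      if (best < R_PosInf && ring > 0 && ringMin >= best) break;
    }
    out[q] = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// 2D kernels: point-to-segment-set minimum distance and even-odd
// point-in-polygon (crossing number, half-open rule y1 <= y < y2).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_points_to_segments(NumericMatrix pts, NumericMatrix E) {
  const int np = pts.nrow(), ne = E.nrow();
  NumericVector out(np);
  if (ne == 0) { std::fill(out.begin(), out.end(), R_PosInf); return out; }
  std::vector<double> x1(ne), y1(ne), ex(ne), ey(ne), len2(ne);
  for (int e = 0; e < ne; ++e) {
    x1[e] = E(e, 0); y1[e] = E(e, 1);
    ex[e] = E(e, 2) - x1[e]; ey[e] = E(e, 3) - y1[e];
    len2[e] = ex[e] * ex[e] + ey[e] * ey[e];
    if (len2[e] == 0) len2[e] = 1e-300;
  }
  for (int p = 0; p < np; ++p) {
    const double px = pts(p, 0), py = pts(p, 1);
    double best = R_PosInf;
    for (int e = 0; e < ne; ++e) {
      double tx = px - x1[e], ty = py - y1[e];
      double t = (tx * ex[e] + ty * ey[e]) / len2[e];
      if (t < 0) t = 0; else if (t > 1) t = 1;
      double dx = tx - t * ex[e], dy = ty - t * ey[e];
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_polygons(NumericMatrix pts, NumericMatrix E) {
  const int np = pts.nrow(), ne = E.nrow();
  LogicalVector out(np);
  for (int p = 0; p < np; ++p) {
    const double px = pts(p, 0), py = pts(p, 1);
    int crossings = 0;
    for (int e = 0; e < ne; ++e) {
      const double ya = E(e, 1), yb = E(e, 3);
      if (ya == yb) continue;
      const double ylo = ya < yb ? ya : yb, yhi = ya < yb ? yb : ya;
      if (py < ylo || py >= yhi) continue;
      const double xc = E(e, 0) + (py - ya) * (E(e, 2) - E(e, 0)) / (yb - ya);
      if (px < xc) ++crossings;
    }
    out[p] = (crossings % 2) == 1;
  }
  return out;
}
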