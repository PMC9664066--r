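// Compiled geometry kernels: exact anisotropic Euclidean distance transform,
// separable Gaussian smoothing, iso-surface extraction by marching
// tetrahedra on the Freudenthal (Kuhn) lattice decomposition, and a
// uniform-grid spatial index for nearest-neighbour and ball queries.
//
// Coordinate conventions: volumes are passed as flat vectors in R's
// column-major order with dims (n0, n1, n2); lattice point (i, j, k)
// (0-based) maps to linear index i + n0*(j + n1*k). All distances are in
// world millimetres; callers convert voxel indices to world coordinates.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// one 1-D lower-envelope pass per axis, axis weight = spacing^2.
// Input: logical mask; output: squared distance (mm^2) to the nearest
// TRUE voxel centroid. Voxels in the mask get 0.

static void dt1d(std::vector<double>& f, int n, double s2) {
  if (n == 1) return;
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    if (f[q] == std::numeric_limits<double>::infinity()) continue;
    double s;
    while (true) {
      int p = v[k];
      if (f[p] == std::numeric_limits<double>::infinity()) {
        // previous parabola is at +inf: it never wins
        if (k == 0) { v[0] = q; z[0] = -std::numeric_limits<double>::infinity();
                      z[1] = std::numeric_limits<double>::infinity(); s = z[0]; break; }
        k--;
        continue;
      }
      s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (s <= z[k]) { k--; if (k < 0) { k = 0; v[0] = q; z[0] = -std::numeric_limits<double>::infinity(); z[1] = std::numeric_limits<double>::infinity(); break; } }
      else { k++; v[k] = q; z[k] = s; z[k + 1] = std::numeric_limits<double>::infinity(); break; }
    }
  }
  // handle the case where f[v[0]] itself is infinite (empty line)
  if (f[v[0]] == std::numeric_limits<double>::infinity() && k == 0) {
    return; // all infinite, leave f untouched
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < (double)q) k++;
    int p = v[k];
    double dq = (double)(q - p);
    d[q] = s2 * dq * dq + f[p];
  }
  for (int q = 0; q < n; q++) f[q] = d[q];
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  const R_xlen_t ntot = (R_xlen_t)n0 * n1 * n2;
  NumericVector out(ntot);
  const double INF = std::numeric_limits<double>::infinity();
  for (R_xlen_t i = 0; i < ntot; i++) out[i] = mask[i] ? 0.0 : INF;

  std::vector<double> line;
  // axis 0
  line.resize(n0);
  for (int k = 0; k < n2; k++)
    for (int j = 0; j < n1; j++) {
      R_xlen_t base = (R_xlen_t)n0 * (j + (R_xlen_t)n1 * k);
      for (int i = 0; i < n0; i++) line[i] = out[base + i];
      dt1d(line, n0, spacing[0] * spacing[0]);
      for (int i = 0; i < n0; i++) out[base + i] = line[i];
    }
  // axis 1
  line.resize(n1);
  for (int k = 0; k < n2; k++)
    for (int i = 0; i < n0; i++) {
      R_xlen_t base = i + (R_xlen_t)n0 * n1 * k;
      for (int j = 0; j < n1; j++) line[j] = out[base + (R_xlen_t)n0 * j];
      dt1d(line, n1, spacing[1] * spacing[1]);
      for (int j = 0; j < n1; j++) out[base + (R_xlen_t)n0 * j] = line[j];
    }
  // axis 2
  line.resize(n2);
  const R_xlen_t plane = (R_xlen_t)n0 * n1;
  for (int j = 0; j < n1; j++)
    for (int i = 0; i < n0; i++) {
      R_xlen_t base = i + (R_xlen_t)n0 * j;
      for (int k = 0; k < n2; k++) line[k] = out[base + plane * k];
      dt1d(line, n2, spacing[2] * spacing[2]);
      for (int k = 0; k < n2; k++) out[base + plane * k] = line[k];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing with zero-padding (occupancy convention:
// outside the grid is background). sigma in voxel units, truncated at 3 sigma.

// [[Rcpp::export]]
NumericVector cpp_smooth3(NumericVector field, IntegerVector dims,
                          double sigma) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  const R_xlen_t ntot = (R_xlen_t)n0 * n1 * n2;
  if (sigma <= 0) return clone(field);
  int rad = (int)std::ceil(3.0 * sigma);
  if (rad < 1) rad = 1;
  std::vector<double> w(2 * rad + 1);
  double wsum = 0.0;
  for (int t = -rad; t <= rad; t++) {
    w[t + rad] = std::exp(-0.5 * (double)t * t / (sigma * sigma));
    wsum += w[t + rad];
  }
  for (auto& x : w) x /= wsum;

  std::vector<double> a(field.begin(), field.end()), b(ntot);
  const int ns[3] = {n0, n1, n2};
  const R_xlen_t strides[3] = {1, (R_xlen_t)n0, (R_xlen_t)n0 * n1};
  for (int ax = 0; ax < 3; ax++) {
    const int n = ns[ax];
    const R_xlen_t st = strides[ax];
    for (R_xlen_t idx = 0; idx < ntot; idx++) {
      // coordinate along axis
      int c = (int)((idx / st) % n);
      double acc = 0.0;
      int lo = std::max(-rad, -c), hi = std::min(rad, n - 1 - c);
      for (int t = lo; t <= hi; t++) acc += w[t + rad] * a[idx + st * t];
      b[idx] = acc;
    }
    std::swap(a, b);
  }
  NumericVector out(ntot);
  std::copy(a.begin(), a.end(), out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on the Freudenthal decomposition: each lattice cell is
// split into 6 tetrahedra sharing the main diagonal; the decomposition is
// consistent across neighbouring cells, so the extracted surface of an
// interior blob is closed. Vertices are linearly interpolated edge
// crossings of the level set, in continuous 0-based lattice coordinates.

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
};

static int edge_point(MTState& S, const NumericVector& f,
                      uint64_t ga, uint64_t gb,
                      double ax, double ay, double az,
                      double bx, double by, double bz, double level) {
  if (ga > gb) {
    std::swap(ga, gb);
    std::swap(ax, bx); std::swap(ay, by); std::swap(az, bz);
  }
  uint64_t key = ga * 0x100000001ULL ^ (gb << 1);
  // use exact pair key instead: pack assuming < 2^32 lattice points
  key = (ga << 32) | gb;
  auto it = S.edge_vertex.find(key);
  if (it != S.edge_vertex.end()) return it->second;
  double va = f[(R_xlen_t)ga], vb = f[(R_xlen_t)gb];
  double t = (level - va) / (vb - va);
  if (t < 1e-6) t = 1e-6;
  if (t > 1.0 - 1e-6) t = 1.0 - 1e-6;
  int id = (int)S.vx.size();
  S.vx.push_back(ax + t * (bx - ax));
  S.vy.push_back(ay + t * (by - ay));
  S.vz.push_back(az + t * (bz - az));
  S.edge_vertex.emplace(key, id);
  return id;
}

static void emit_tri(MTState& S, int a, int b, int c,
                     double rx, double ry, double rz) {
  // orient so the normal points from the inside (> level) region outward;
  // (rx,ry,rz) is a reference vector from inside centroid to outside centroid
  double ux = S.vx[b] - S.vx[a], uy = S.vy[b] - S.vy[a], uz = S.vz[b] - S.vz[a];
  double wx = S.vx[c] - S.vx[a], wy = S.vy[c] - S.vy[a], wz = S.vz[c] - S.vz[a];
  double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz, nz = ux * wy - uy * wx;
  if (nx * rx + ny * ry + nz * rz < 0) std::swap(b, c);
  S.tri.push_back(a); S.tri.push_back(b); S.tri.push_back(c);
}

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dims, double level) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  MTState S;
  // the 6 axis permutations defining the Kuhn tetrahedra
  static const int perms[6][3] = {
    {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
  const R_xlen_t str[3] = {1, (R_xlen_t)n0, (R_xlen_t)n0 * n1};

  for (int k = 0; k + 1 < n2; k++)
    for (int j = 0; j + 1 < n1; j++)
      for (int i = 0; i + 1 < n0; i++) {
        R_xlen_t c000 = i + str[1] * j + str[2] * k;
        // quick reject: all 8 corners on one side
        bool any_in = false, any_out = false;
        for (int dz = 0; dz < 2; dz++)
          for (int dy = 0; dy < 2; dy++)
            for (int dx = 0; dx < 2; dx++) {
              double v = field[c000 + dx * str[0] + dy * str[1] + dz * str[2]];
              if (v > level) any_in = true; else any_out = true;
            }
        if (!any_in || !any_out) continue;

        for (int p = 0; p < 6; p++) {
          // tetra lattice offsets: 0, e_a, e_a + e_b, (1,1,1)
          int off[4][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}, {1, 1, 1}};
          off[1][perms[p][0]] = 1;
          off[2][perms[p][0]] = 1;
          off[2][perms[p][1]] = 1;
          uint64_t gid[4];
          double px[4], py[4], pz[4], val[4];
          bool inside[4];
          int nin = 0;
          for (int v = 0; v < 4; v++) {
            int xi = i + off[v][0], yj = j + off[v][1], zk = k + off[v][2];
            R_xlen_t g = xi + str[1] * yj + str[2] * zk;
            gid[v] = (uint64_t)g;
            px[v] = xi; py[v] = yj; pz[v] = zk;
            val[v] = field[g];
            inside[v] = val[v] > level;
            if (inside[v]) nin++;
          }
          if (nin == 0 || nin == 4) continue;
          // reference direction: inside centroid -> outside centroid
          double cix = 0, ciy = 0, ciz = 0, cox = 0, coy = 0, coz = 0;
          for (int v = 0; v < 4; v++) {
            if (inside[v]) { cix += px[v]; ciy += py[v]; ciz += pz[v]; }
            else { cox += px[v]; coy += py[v]; coz += pz[v]; }
          }
          double rx = cox / (4 - nin) - cix / nin;
          double ry = coy / (4 - nin) - ciy / nin;
          double rz = coz / (4 - nin) - ciz / nin;

          int ins[4], outs[4], ni = 0, no = 0;
          for (int v = 0; v < 4; v++) (inside[v] ? ins[ni++] : outs[no++]) = v;

          auto EP = [&](int a, int b) {
            return edge_point(S, field, gid[a], gid[b], px[a], py[a], pz[a],
                              px[b], py[b], pz[b], level);
          };
          if (nin == 1) {
            int A = ins[0];
            emit_tri(S, EP(A, outs[0]), EP(A, outs[1]), EP(A, outs[2]),
                     rx, ry, rz);
          } else if (nin == 3) {
            int D = outs[0];
            emit_tri(S, EP(D, ins[0]), EP(D, ins[1]), EP(D, ins[2]),
                     rx, ry, rz);
          } else { // nin == 2: quad on edges AC, AD, BD, BC (cyclic)
            int A = ins[0], B = ins[1], C = outs[0], D = outs[1];
            int v1 = EP(A, C), v2 = EP(A, D), v3 = EP(B, D), v4 = EP(B, C);
            emit_tri(S, v1, v2, v3, rx, ry, rz);
            emit_tri(S, v1, v3, v4, rx, ry, rz);
          }
        }
      }

  int nv = (int)S.vx.size(), nt = (int)S.tri.size() / 3;
  NumericMatrix verts(nv, 3);
  for (int v = 0; v < nv; v++) {
    verts(v, 0) = S.vx[v]; verts(v, 1) = S.vy[v]; verts(v, 2) = S.vz[v];
  }
  IntegerMatrix tris(nt, 3);
  for (int t = 0; t < nt; t++) {
    tris(t, 0) = S.tri[3 * t] + 1;     // 1-based for R
    tris(t, 1) = S.tri[3 * t + 1] + 1;
    tris(t, 2) = S.tri[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["triangles"] = tris);
}

// ---------------------------------------------------------------------------
// Uniform-grid spatial index for point sets.

struct PointGrid {
  double ox, oy, oz, h;
  int gx, gy, gz;
  std::vector<int> cell_start;  // CSR layout
  std::vector<int> order;
};

static PointGrid build_grid(const NumericMatrix& pts, double cell) {
  PointGrid G;
  const int K = pts.nrow();
  double xmin = R_PosInf, ymin = R_PosInf, zmin = R_PosInf;
  double xmax = R_NegInf, ymax = R_NegInf, zmax = R_NegInf;
  for (int i = 0; i < K; i++) {
    xmin = std::min(xmin, pts(i, 0)); xmax = std::max(xmax, pts(i, 0));
    ymin = std::min(ymin, pts(i, 1)); ymax = std::max(ymax, pts(i, 1));
    zmin = std::min(zmin, pts(i, 2)); zmax = std::max(zmax, pts(i, 2));
  }
  // enlarge the cell if needed so no axis exceeds 512 cells and every
  // point lies inside its assigned cell's box
  double ext = std::max(xmax - xmin, std::max(ymax - ymin, zmax - zmin));
  G.h = std::max(cell, ext / 512.0 * (1.0 + 1e-12));
  G.ox = xmin; G.oy = ymin; G.oz = zmin;
  auto ncell = [&](double lo, double hi) {
    return std::max(1, (int)std::floor((hi - lo) / G.h) + 1);
  };
  G.gx = ncell(xmin, xmax); G.gy = ncell(ymin, ymax); G.gz = ncell(zmin, zmax);
  std::vector<int> cnt((size_t)G.gx * G.gy * G.gz + 1, 0);
  std::vector<int> ci(K);
  for (int i = 0; i < K; i++) {
    int cx = std::min(G.gx - 1, std::max(0, (int)((pts(i, 0) - G.ox) / G.h)));
    int cy = std::min(G.gy - 1, std::max(0, (int)((pts(i, 1) - G.oy) / G.h)));
    int cz = std::min(G.gz - 1, std::max(0, (int)((pts(i, 2) - G.oz) / G.h)));
    ci[i] = cx + G.gx * (cy + G.gy * cz);
    cnt[ci[i] + 1]++;
  }
  for (size_t c = 1; c < cnt.size(); c++) cnt[c] += cnt[c - 1];
  G.cell_start = cnt;
  G.order.resize(K);
  std::vector<int> fill(cnt.begin(), cnt.end() - 1);
  for (int i = 0; i < K; i++) G.order[fill[ci[i]]++] = i;
  return G;
}

static inline double box_dist_sq(const PointGrid& G, int cx, int cy, int cz,
                                 double qx, double qy, double qz) {
  double x0 = G.ox + cx * G.h, x1 = x0 + G.h;
  double y0 = G.oy + cy * G.h, y1 = y0 + G.h;
  double z0 = G.oz + cz * G.h, z1 = z0 + G.h;
  double dx = (qx < x0) ? x0 - qx : (qx > x1 ? qx - x1 : 0.0);
  double dy = (qy < y0) ? y0 - qy : (qy > y1 ? qy - y1 : 0.0);
  double dz = (qz < z0) ? z0 - qz : (qz > z1 ? qz - z1 : 0.0);
  return dx * dx + dy * dy + dz * dz;
}

// Nearest neighbour: returns squared distance and 1-based index of the
// nearest point for every query; ties broken by lowest point index
// (identical rule to the brute-force scan).

// [[Rcpp::export]]
List cpp_grid_nn(NumericMatrix pts, NumericMatrix query) {
  const int K = pts.nrow(), N = query.nrow();
  NumericVector d2out(N);
  IntegerVector idxout(N);
  if (K == 0) stop("empty point set");
  // target ~1 point per cell, clamped
  double vol = 1.0;
  {
    double lo[3], hi[3];
    for (int a = 0; a < 3; a++) {
      lo[a] = R_PosInf; hi[a] = R_NegInf;
      for (int i = 0; i < K; i++) {
        lo[a] = std::min(lo[a], pts(i, a)); hi[a] = std::max(hi[a], pts(i, a));
      }
      vol *= std::max(hi[a] - lo[a], 1e-6);
    }
  }
  double cell = std::cbrt(vol / std::max(1, K));
  if (cell <= 1e-9) cell = 1e-9;
  PointGrid G = build_grid(pts, cell);
  const int maxg = std::max(G.gx, std::max(G.gy, G.gz));

  for (int q = 0; q < N; q++) {
    double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    int cx = std::min(G.gx - 1, std::max(0, (int)((qx - G.ox) / G.h)));
    int cy = std::min(G.gy - 1, std::max(0, (int)((qy - G.oy) / G.h)));
    int cz = std::min(G.gz - 1, std::max(0, (int)((qz - G.oz) / G.h)));
    double best = R_PosInf;
    int bestidx = -1;
    for (int r = 0; r <= maxg; r++) {
      if (bestidx >= 0) {
        double ring_lb = (double)(r - 1) * G.h;
        if (ring_lb > 0 && ring_lb * ring_lb > best) break;
      }
      int x0 = std::max(0, cx - r), x1 = std::min(G.gx - 1, cx + r);
      int y0 = std::max(0, cy - r), y1 = std::min(G.gy - 1, cy + r);
      int z0 = std::max(0, cz - r), z1 = std::min(G.gz - 1, cz + r);
      bool any_cell = false;
      for (int zz = z0; zz <= z1; zz++)
        for (int yy = y0; yy <= y1; yy++)
          for (int xx = x0; xx <= x1; xx++) {
            // Chebyshev shell only
            int ch = std::max(std::abs(xx - cx),
                              std::max(std::abs(yy - cy), std::abs(zz - cz)));
            if (ch != r) continue;
            any_cell = true;
            if (box_dist_sq(G, xx, yy, zz, qx, qy, qz) > best) continue;
            int c = xx + G.gx * (yy + G.gy * zz);
            for (int s = G.cell_start[c]; s < G.cell_start[c + 1]; s++) {
              int i = G.order[s];
              double dx = qx - pts(i, 0), dy = qy - pts(i, 1),
                     dz = qz - pts(i, 2);
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best || (d2 == best && i < bestidx)) {
                best = d2; bestidx = i;
              }
            }
          }
      if (!any_cell && bestidx >= 0) break;
    }
    d2out[q] = best;
    idxout[q] = bestidx + 1;
  }
  return List::create(_["d2"] = d2out, _["index"] = idxout);
}

// Closed-ball query: for every query point, sum of weights of points with
// distance <= radius (accumulated in ascending point order, extended
// precision) and the count of such points.

// [[Rcpp::export]]
List cpp_grid_ball(NumericMatrix pts, NumericVector w, NumericMatrix query,
                   double radius) {
  const int K = pts.nrow(), N = query.nrow();
  NumericVector sums(N);
  IntegerVector counts(N);
  if (K == 0) {
    return List::create(_["sum"] = sums, _["count"] = counts);
  }
  double cell = std::max(radius, 1e-9);
  PointGrid G = build_grid(pts, cell);
  const double r2 = radius * radius;
  std::vector<int> hits;
  for (int q = 0; q < N; q++) {
    double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    int x0 = std::max(0, (int)std::floor((qx - radius - G.ox) / G.h));
    int x1 = std::min(G.gx - 1, (int)std::floor((qx + radius - G.ox) / G.h));
    int y0 = std::max(0, (int)std::floor((qy - radius - G.oy) / G.h));
    int y1 = std::min(G.gy - 1, (int)std::floor((qy + radius - G.oy) / G.h));
    int z0 = std::max(0, (int)std::floor((qz - radius - G.oz) / G.h));
    int z1 = std::min(G.gz - 1, (int)std::floor((qz + radius - G.oz) / G.h));
    hits.clear();
    for (int zz = z0; zz <= z1; zz++)
      for (int yy = y0; yy <= y1; yy++)
        for (int xx = x0; xx <= x1; xx++) {
          if (box_dist_sq(G, xx, yy, zz, qx, qy, qz) > r2) continue;
          int c = xx + G.gx * (yy + G.gy * zz);
          for (int s = G.cell_start[c]; s < G.cell_start[c + 1]; s++) {
            int i = G.order[s];
            double dx = qx - pts(i, 0), dy = qy - pts(i, 1), dz = qz - pts(i, 2);
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 <= r2) hits.push_back(i);
          }
        }
    std::sort(hits.begin(), hits.end());
    long double acc = 0.0L;
    for (int i : hits) acc += (long double)w[i];
    sums[q] = (double)acc;
    counts[q] = (int)hits.size();
  }
  return List::create(_["sum"] = sums, _["count"] = counts);
}
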