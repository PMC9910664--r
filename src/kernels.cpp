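// Voxel-level kernels for binary 3D image analysis.
//
// Volumes are stored as R arrays with dim = c(nz, ny, nx): slice index z is
// the fastest-varying dimension, so voxel (z, y, x) lives at linear offset
// z + nz * (y + ny * x) (all 0-based here).

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <queue>

using namespace Rcpp;

static const double EDT_INF = 1e30;

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// one 1D lower-envelope pass per axis.
// ---------------------------------------------------------------------------

static void edt1d(const std::vector<double>& f, std::vector<double>& d,
                  std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -EDT_INF;
  z[1] = EDT_INF;
  for (int q = 1; q < n; ++q) {
    double s = 0.0;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = EDT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Apply the 1D transform along one axis of the (nz, ny, nx) grid.
// axis: 0 = z, 1 = y, 2 = x.
static void edt_pass(std::vector<double>& d, int nz, int ny, int nx, int axis) {
  int n = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  std::vector<double> f(n), out(n), z(n + 1);
  std::vector<int> v(n);
  if (axis == 0) {
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        size_t base = (size_t)nz * (y + (size_t)ny * x);
        for (int i = 0; i < n; ++i) f[i] = d[base + i];
        edt1d(f, out, v, z, n);
        for (int i = 0; i < n; ++i) d[base + i] = out[i];
      }
  } else if (axis == 1) {
    for (int x = 0; x < nx; ++x)
      for (int zz = 0; zz < nz; ++zz) {
        size_t base = zz + (size_t)nz * (size_t)ny * x;
        for (int i = 0; i < n; ++i) f[i] = d[base + (size_t)nz * i];
        edt1d(f, out, v, z, n);
        for (int i = 0; i < n; ++i) d[base + (size_t)nz * i] = out[i];
      }
  } else {
    for (int y = 0; y < ny; ++y)
      for (int zz = 0; zz < nz; ++zz) {
        size_t base = zz + (size_t)nz * y;
        size_t stride = (size_t)nz * ny;
        for (int i = 0; i < n; ++i) f[i] = d[base + stride * i];
        edt1d(f, out, v, z, n);
        for (int i = 0; i < n; ++i) d[base + stride * i] = out[i];
      }
  }
}

// Squared Euclidean distance to the nearest TRUE voxel. per_slice = TRUE
// restricts the transform to within each z-slice (2D distances).
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector seed, int nz, int ny, int nx,
                         bool per_slice) {
  size_t n = (size_t)nz * ny * nx;
  std::vector<double> d(n);
  for (size_t i = 0; i < n; ++i) d[i] = seed[i] ? 0.0 : EDT_INF;
  if (!per_slice) edt_pass(d, nz, ny, nx, 0);
  edt_pass(d, nz, ny, nx, 1);
  edt_pass(d, nz, ny, nx, 2);
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = d[i];
  return out;
}

// ---------------------------------------------------------------------------
// Binary morphology.
//
// Round elements are Euclidean discs/balls of pixel centers at distance
// <= radius; realised exactly through the distance transform. Border
// contract: beyond-border padding is background for dilation and foreground
// for erosion (distances are only measured to in-image voxels, which yields
// exactly that contract).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".morph_round_cpp")]]
LogicalVector morph_round_cpp(LogicalVector mask, int nz, int ny, int nx,
                              int radius, bool per_slice, bool erode) {
  size_t n = (size_t)nz * ny * nx;
  if (radius == 0) return clone(mask);
  LogicalVector seed(n);
  if (erode) {
    for (size_t i = 0; i < n; ++i) seed[i] = !mask[i];
  } else {
    seed = mask;
  }
  NumericVector d = edt_sq_cpp(seed, nz, ny, nx, per_slice);
  double r2 = (double)radius * radius + 1e-9;
  LogicalVector out(n);
  if (erode) {
    for (size_t i = 0; i < n; ++i) out[i] = mask[i] && d[i] > r2;
  } else {
    for (size_t i = 0; i < n; ++i) out[i] = d[i] <= r2;
  }
  return out;
}

// Sliding min/max along one axis, window [-r, r]; pad = value assumed
// outside the image.
static void minmax_pass(std::vector<uint8_t>& a, int nz, int ny, int nx,
                        int axis, int r, bool take_max, uint8_t pad) {
  int n = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  size_t stride = (axis == 0) ? 1 : (axis == 1) ? (size_t)nz
                                                : (size_t)nz * ny;
  std::vector<uint8_t> line(n), out(n);
  int o1 = (axis == 0) ? ny : nz;
  int o2 = (axis == 2) ? ny : nx;
  for (int j = 0; j < o2; ++j)
    for (int i = 0; i < o1; ++i) {
      size_t base;
      if (axis == 0) base = (size_t)nz * (i + (size_t)ny * j);
      else if (axis == 1) base = i + (size_t)nz * ny * (size_t)j;
      else base = i + (size_t)nz * j;
      for (int q = 0; q < n; ++q) line[q] = a[base + stride * q];
      for (int q = 0; q < n; ++q) {
        uint8_t acc = take_max ? 0 : 1;
        for (int w = q - r; w <= q + r; ++w) {
          uint8_t v = (w < 0 || w >= n) ? pad : line[w];
          if (take_max) { if (v > acc) acc = v; }
          else { if (v < acc) acc = v; }
        }
        out[q] = acc;
      }
      for (int q = 0; q < n; ++q) a[base + stride * q] = out[q];
    }
}

// Square (Chebyshev) structuring element of the given radius.
// [[Rcpp::export(name = ".morph_square_cpp")]]
LogicalVector morph_square_cpp(LogicalVector mask, int nz, int ny, int nx,
                               int radius, bool per_slice, bool erode) {
  size_t n = (size_t)nz * ny * nx;
  std::vector<uint8_t> a(n);
  for (size_t i = 0; i < n; ++i) a[i] = mask[i] ? 1 : 0;
  uint8_t pad = erode ? 1 : 0;
  if (!per_slice) minmax_pass(a, nz, ny, nx, 0, radius, !erode, pad);
  minmax_pass(a, nz, ny, nx, 1, radius, !erode, pad);
  minmax_pass(a, nz, ny, nx, 2, radius, !erode, pad);
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = a[i] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Connected components. conn is one of 26 / 6 (3D) or 8 / 4 (per-slice 2D:
// no cross-slice links, so every component lives in a single slice).
// Returns labels (1-based, 0 = background), component voxel counts, and the
// lexicographically smallest (z, y, x) voxel of each component (1-based).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".label_components_cpp")]]
List label_components_cpp(LogicalVector mask, int nz, int ny, int nx,
                          int conn) {
  size_t n = (size_t)nz * ny * nx;
  std::vector<int> labels(n, 0);
  std::vector<int> dz, dy, dx;
  bool in_slice = (conn == 8 || conn == 4);
  for (int az = -1; az <= 1; ++az)
    for (int ay = -1; ay <= 1; ++ay)
      for (int ax = -1; ax <= 1; ++ax) {
        if (az == 0 && ay == 0 && ax == 0) continue;
        int manh = std::abs(az) + std::abs(ay) + std::abs(ax);
        if (in_slice && az != 0) continue;
        if ((conn == 6 || conn == 4) && manh != 1) continue;
        dz.push_back(az); dy.push_back(ay); dx.push_back(ax);
      }
  int ndirs = (int)dz.size();
  std::vector<double> sizes;
  std::vector<int> minz, miny, minx;
  std::vector<size_t> stack;
  int cur = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s]) continue;
    ++cur;
    double sz = 0;
    int mz = nz, my = ny, mx = nx;
    stack.clear();
    stack.push_back(s);
    labels[s] = cur;
    while (!stack.empty()) {
      size_t i = stack.back();
      stack.pop_back();
      ++sz;
      int z = (int)(i % nz);
      int y = (int)((i / nz) % ny);
      int x = (int)(i / ((size_t)nz * ny));
      if (z < mz || (z == mz && (y < my || (y == my && x < mx)))) {
        mz = z; my = y; mx = x;
      }
      for (int k = 0; k < ndirs; ++k) {
        int z2 = z + dz[k], y2 = y + dy[k], x2 = x + dx[k];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
          continue;
        size_t j = z2 + (size_t)nz * (y2 + (size_t)ny * x2);
        if (mask[j] && !labels[j]) {
          labels[j] = cur;
          stack.push_back(j);
        }
      }
    }
    sizes.push_back(sz);
    minz.push_back(mz + 1);
    miny.push_back(my + 1);
    minx.push_back(mx + 1);
  }
  IntegerVector lab(n);
  for (size_t i = 0; i < n; ++i) lab[i] = labels[i];
  return List::create(_["labels"] = lab,
                      _["sizes"] = wrap(sizes),
                      _["min_z"] = wrap(minz),
                      _["min_y"] = wrap(miny),
                      _["min_x"] = wrap(minx));
}

// Per-slice hole fill: background 4-connected components not reachable from
// the slice border become foreground.
// [[Rcpp::export(name = ".fill_holes_slices_cpp")]]
LogicalVector fill_holes_slices_cpp(LogicalVector mask, int nz, int ny,
                                    int nx) {
  size_t n = (size_t)nz * ny * nx;
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = true;  // start filled
  std::vector<uint8_t> visited((size_t)ny * nx);
  std::vector<int> stack;
  for (int z = 0; z < nz; ++z) {
    std::fill(visited.begin(), visited.end(), 0);
    stack.clear();
    // seed from border background pixels of this slice
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (y != 0 && y != ny - 1 && x != 0 && x != nx - 1) continue;
        size_t i3 = z + (size_t)nz * (y + (size_t)ny * x);
        if (!mask[i3] && !visited[y + (size_t)ny * x]) {
          visited[y + (size_t)ny * x] = 1;
          stack.push_back(y + ny * x);
        }
      }
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      int y = p % ny, x = p / ny;
      const int oy[4] = {1, -1, 0, 0};
      const int ox[4] = {0, 0, 1, -1};
      for (int k = 0; k < 4; ++k) {
        int y2 = y + oy[k], x2 = x + ox[k];
        if (y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx) continue;
        size_t p2 = y2 + (size_t)ny * x2;
        size_t i3 = z + (size_t)nz * p2;
        if (!mask[i3] && !visited[p2]) {
          visited[p2] = 1;
          stack.push_back((int)(y2 + ny * x2));
        }
      }
    }
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x)
        if (visited[y + (size_t)ny * x])
          out[z + (size_t)nz * (y + (size_t)ny * x)] = false;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Local thickness (largest inscribed sphere). For each foreground voxel,
// thickness = 2 * r - 1 voxels, where r is the Euclidean distance to the
// nearest in-image background voxel center of the largest sphere covering
// the voxel. Voxels whose maximal sphere is contained in a neighbor's
// sphere are skipped as paint sources (distance-ridge reduction; exact, as
// sphere containment is transitive and strictly increases r).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".local_thickness_cpp")]]
NumericVector local_thickness_cpp(LogicalVector mask, int nz, int ny,
                                  int nx) {
  size_t n = (size_t)nz * ny * nx;
  LogicalVector bg(n);
  bool any_bg = false;
  for (size_t i = 0; i < n; ++i) {
    bg[i] = !mask[i];
    if (bg[i]) any_bg = true;
  }
  if (!any_bg) stop("mask fills the whole volume: thickness is unbounded");
  NumericVector dsq = edt_sq_cpp(bg, nz, ny, nx, false);
  NumericVector th(n);
  // ridge selection + sphere painting, largest radii first
  std::vector<size_t> fg;
  fg.reserve(n / 4);
  for (size_t i = 0; i < n; ++i)
    if (mask[i]) fg.push_back(i);
  const double sq2 = std::sqrt(2.0), sq3 = std::sqrt(3.0);
  for (size_t t = 0; t < fg.size(); ++t) {
    size_t i = fg[t];
    double r = std::sqrt(dsq[i]);
    int z = (int)(i % nz);
    int y = (int)((i / nz) % ny);
    int x = (int)(i / ((size_t)nz * ny));
    bool contained = false;
    for (int az = -1; az <= 1 && !contained; ++az)
      for (int ay = -1; ay <= 1 && !contained; ++ay)
        for (int ax = -1; ax <= 1 && !contained; ++ax) {
          if (az == 0 && ay == 0 && ax == 0) continue;
          int z2 = z + az, y2 = y + ay, x2 = x + ax;
          if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
            continue;
          size_t j = z2 + (size_t)nz * (y2 + (size_t)ny * x2);
          if (!mask[j]) continue;
          int manh = std::abs(az) + std::abs(ay) + std::abs(ax);
          double dist = (manh == 1) ? 1.0 : (manh == 2 ? sq2 : sq3);
          if (std::sqrt(dsq[j]) >= r + dist - 1e-9) contained = true;
        }
    if (contained) continue;
    double val = 2.0 * r - 1.0;
    double s = r - 0.5;          // sphere surface radius from voxel centers
    double s2 = s * s + 1e-9;
    int rr = (int)std::floor(s + 1e-9);
    for (int az = -rr; az <= rr; ++az)
      for (int ay = -rr; ay <= rr; ++ay) {
        double part = (double)az * az + (double)ay * ay;
        if (part > s2) continue;
        for (int ax = -rr; ax <= rr; ++ax) {
          if (part + (double)ax * ax > s2) continue;
          int z2 = z + az, y2 = y + ay, x2 = x + ax;
          if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
            continue;
          size_t j = z2 + (size_t)nz * (y2 + (size_t)ny * x2);
          if (mask[j] && th[j] < val) th[j] = val;
        }
      }
  }
  return th;
}

// ---------------------------------------------------------------------------
// Directed-secant run counting. For each principal axis, walk every
// axis-parallel voxel row; a run is a maximal consecutive stretch of
// foreground-inside-VOI voxels. Lines with no run are excluded; the rest
// contribute their run count and their VOI extent (in voxels) to the
// totals. Returns per-axis (runs, length).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".secant_runs_cpp")]]
List secant_runs_cpp(LogicalVector mask, LogicalVector roi, int nz, int ny,
                     int nx) {
  double runs[3] = {0, 0, 0};
  double len[3] = {0, 0, 0};
  for (int axis = 0; axis < 3; ++axis) {
    int n = (axis == 0) ? nz : (axis == 1) ? ny : nx;
    size_t stride = (axis == 0) ? 1 : (axis == 1) ? (size_t)nz
                                                  : (size_t)nz * ny;
    int o1 = (axis == 0) ? ny : nz;
    int o2 = (axis == 2) ? ny : nx;
    for (int j = 0; j < o2; ++j)
      for (int i = 0; i < o1; ++i) {
        size_t base;
        if (axis == 0) base = (size_t)nz * (i + (size_t)ny * j);
        else if (axis == 1) base = i + (size_t)nz * ny * (size_t)j;
        else base = i + (size_t)nz * j;
        int line_runs = 0;
        double line_len = 0;
        bool in_run = false;
        for (int q = 0; q < n; ++q) {
          size_t p = base + stride * q;
          bool in_roi = roi[p];
          bool hit = in_roi && mask[p];
          if (in_roi) line_len += 1;
          if (hit && !in_run) ++line_runs;
          in_run = hit;
        }
        if (line_runs > 0) {
          runs[axis] += line_runs;
          len[axis] += line_len;
        }
      }
  }
  return List::create(_["runs"] = NumericVector::create(runs[0], runs[1],
                                                        runs[2]),
                      _["length_vox"] = NumericVector::create(len[0], len[1],
                                                              len[2]));
}

// ---------------------------------------------------------------------------
// Closed-surface extraction from a binary mask: marching over the Kuhn
// 6-tetrahedra decomposition of each lattice cell, iso-level 0.5, vertices
// at crossing-edge midpoints. The Kuhn decomposition tiles space with
// matching face diagonals between neighboring cells, so the extracted
// surface is closed and manifold. The volume is padded with one background
// layer so masks touching the border still yield closed surfaces.
// Vertices come back in voxel-center coordinates (0-based (z, y, x) order
// columns z, y, x); faces are 1-based triples with outward orientation.
// ---------------------------------------------------------------------------

struct MeshAcc {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vz, vy, vx;
  std::vector<int> f1, f2, f3;
};

static int edge_point(MeshAcc& acc, uint64_t ga, uint64_t gb,
                      const double* pa, const double* pb) {
  uint64_t a = ga < gb ? ga : gb;
  uint64_t b = ga < gb ? gb : ga;
  uint64_t key = (a << 32) | b;
  auto it = acc.edge_vertex.find(key);
  if (it != acc.edge_vertex.end()) return it->second;
  int id = (int)acc.vz.size();
  acc.vz.push_back(0.5 * (pa[0] + pb[0]));
  acc.vy.push_back(0.5 * (pa[1] + pb[1]));
  acc.vx.push_back(0.5 * (pa[2] + pb[2]));
  acc.edge_vertex.emplace(key, id);
  return id;
}

static void add_tri(MeshAcc& acc, int a, int b, int c,
                    const double* cin, const double* cout) {
  // orient so the normal points from inside (foreground) to outside
  double u[3], v[3], nrm[3], w[3];
  u[0] = acc.vz[b] - acc.vz[a]; u[1] = acc.vy[b] - acc.vy[a];
  u[2] = acc.vx[b] - acc.vx[a];
  v[0] = acc.vz[c] - acc.vz[a]; v[1] = acc.vy[c] - acc.vy[a];
  v[2] = acc.vx[c] - acc.vx[a];
  nrm[0] = u[1] * v[2] - u[2] * v[1];
  nrm[1] = u[2] * v[0] - u[0] * v[2];
  nrm[2] = u[0] * v[1] - u[1] * v[0];
  w[0] = cout[0] - cin[0]; w[1] = cout[1] - cin[1]; w[2] = cout[2] - cin[2];
  double dot = nrm[0] * w[0] + nrm[1] * w[1] + nrm[2] * w[2];
  if (dot < 0) std::swap(b, c);
  acc.f1.push_back(a + 1);
  acc.f2.push_back(b + 1);
  acc.f3.push_back(c + 1);
}

// [[Rcpp::export(name = ".surface_mesh_cpp")]]
List surface_mesh_cpp(LogicalVector mask, int nz, int ny, int nx) {
  // Kuhn tetrahedra: all contain the main diagonal 0 -> 7 (corner bits
  // encode (dz, dy, dx) as bit0 = z, bit1 = y, bit2 = x).
  static const int tets[6][4] = {
      {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
      {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  MeshAcc acc;
  size_t gz = nz + 2, gy = ny + 2;  // padded grid ids
  auto grid_id = [&](int z, int y, int x) -> uint64_t {
    return (uint64_t)(z + 1) + gz * ((uint64_t)(y + 1) + gy * (uint64_t)(x + 1));
  };
  auto value_at = [&](int z, int y, int x) -> int {
    if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) return 0;
    return mask[z + (size_t)nz * (y + (size_t)ny * x)] ? 1 : 0;
  };
  double corner[8][3];
  uint64_t gid[8];
  int val[8];
  for (int x = -1; x < nx; ++x)
    for (int y = -1; y < ny; ++y)
      for (int z = -1; z < nz; ++z) {
        int any = 0, all = 1;
        for (int c = 0; c < 8; ++c) {
          int cz = z + (c & 1), cy = y + ((c >> 1) & 1), cx = x + ((c >> 2) & 1);
          val[c] = value_at(cz, cy, cx);
          any |= val[c];
          all &= val[c];
          corner[c][0] = cz; corner[c][1] = cy; corner[c][2] = cx;
          gid[c] = grid_id(cz, cy, cx);
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          int in[4], nin = 0, out[4], nout = 0;
          for (int c = 0; c < 4; ++c) {
            int ci = tets[t][c];
            if (val[ci]) in[nin++] = ci; else out[nout++] = ci;
          }
          if (nin == 0 || nin == 4) continue;
          double cin[3] = {0, 0, 0}, cout[3] = {0, 0, 0};
          for (int c = 0; c < nin; ++c)
            for (int k = 0; k < 3; ++k) cin[k] += corner[in[c]][k] / nin;
          for (int c = 0; c < nout; ++c)
            for (int k = 0; k < 3; ++k) cout[k] += corner[out[c]][k] / nout;
          if (nin == 1) {
            int a = edge_point(acc, gid[in[0]], gid[out[0]], corner[in[0]], corner[out[0]]);
            int b = edge_point(acc, gid[in[0]], gid[out[1]], corner[in[0]], corner[out[1]]);
            int c = edge_point(acc, gid[in[0]], gid[out[2]], corner[in[0]], corner[out[2]]);
            add_tri(acc, a, b, c, cin, cout);
          } else if (nin == 3) {
            int a = edge_point(acc, gid[out[0]], gid[in[0]], corner[out[0]], corner[in[0]]);
            int b = edge_point(acc, gid[out[0]], gid[in[1]], corner[out[0]], corner[in[1]]);
            int c = edge_point(acc, gid[out[0]], gid[in[2]], corner[out[0]], corner[in[2]]);
            add_tri(acc, a, b, c, cin, cout);
          } else {  // 2 in, 2 out: quad split into two triangles
            int p00 = edge_point(acc, gid[in[0]], gid[out[0]], corner[in[0]], corner[out[0]]);
            int p01 = edge_point(acc, gid[in[0]], gid[out[1]], corner[in[0]], corner[out[1]]);
            int p10 = edge_point(acc, gid[in[1]], gid[out[0]], corner[in[1]], corner[out[0]]);
            int p11 = edge_point(acc, gid[in[1]], gid[out[1]], corner[in[1]], corner[out[1]]);
            add_tri(acc, p00, p01, p11, cin, cout);
            add_tri(acc, p00, p11, p10, cin, cout);
          }
        }
      }
  int nv = (int)acc.vz.size();
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; ++i) {
    verts(i, 0) = acc.vz[i];
    verts(i, 1) = acc.vy[i];
    verts(i, 2) = acc.vx[i];
  }
  int nf = (int)acc.f1.size();
  IntegerMatrix faces(nf, 3);
  for (int i = 0; i < nf; ++i) {
    faces(i, 0) = acc.f1[i];
    faces(i, 1) = acc.f2[i];
    faces(i, 2) = acc.f3[i];
  }
  return List::create(_["vertices_zyx"] = verts, _["faces"] = faces);
}
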