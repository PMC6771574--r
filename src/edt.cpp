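#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// 1-D squared-distance transform (lower envelope of parabolas,
// Felzenszwalb & Huttenlocher 2012), sample positions i * w.
// f: input squared distances; d: output; v/z: scratch (size n, n+1).
static void dt1d(const double* f, double* d, int n, double w,
                 int* v, double* z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[k]] == INF) { v[k] = q; continue; }
    double s;
    while (true) {
      double xq = q * w, xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double x = q * w;
    while (z[k + 1] < x) ++k;
    double dx = x - v[k] * w;
    d[q] = dx * dx + f[v[k]];
  }
}

// Exact Euclidean distance transform of a logical 3-D array, in world
// millimetres, honouring per-axis voxel spacing. Returns distances to the
// nearest TRUE voxel centre (0 on source voxels, Inf if mask is empty).
// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t ntot = nxy * nz;
  NumericVector out(ntot);
  double* p = REAL(out);
  const int* m = LOGICAL(mask);
  for (R_xlen_t i = 0; i < ntot; ++i)
    p[i] = (m[i] == TRUE) ? 0.0 : INF;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (contiguous)
  for (int zz = 0; zz < nz; ++zz)
    for (int y = 0; y < ny; ++y) {
      double* row = p + zz * nxy + (R_xlen_t)y * nx;
      dt1d(row, d.data(), nx, spacing[0], v.data(), z.data());
      std::copy(d.begin(), d.begin() + nx, row);
    }
  // pass along y (stride nx)
  for (int zz = 0; zz < nz; ++zz)
    for (int x = 0; x < nx; ++x) {
      double* base = p + zz * nxy + x;
      for (int y = 0; y < ny; ++y) f[y] = base[(R_xlen_t)y * nx];
      dt1d(f.data(), d.data(), ny, spacing[1], v.data(), z.data());
      for (int y = 0; y < ny; ++y) base[(R_xlen_t)y * nx] = d[y];
    }
  // pass along z (stride nx*ny)
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      double* base = p + (R_xlen_t)y * nx + x;
      for (int zz = 0; zz < nz; ++zz) f[zz] = base[zz * nxy];
      dt1d(f.data(), d.data(), nz, spacing[2], v.data(), z.data());
      for (int zz = 0; zz < nz; ++zz) base[zz * nxy] = d[zz];
    }
  for (R_xlen_t i = 0; i < ntot; ++i)
    p[i] = std::sqrt(p[i]);
  out.attr("dim") = dims;
  return out;
}

// Exact segment/voxel-grid traversal (Amanatides & Woo DDA): does the
// segment p0 -> p1, given in continuous voxel coordinates where cell i
// spans [i, i+1), pass through any TRUE cell? Catches arbitrarily short
// corner grazes that sampled tests can miss.
// [[Rcpp::export]]
bool segment_hits_mask_cpp(LogicalVector mask, IntegerVector dims,
                           NumericVector p0, NumericVector p1) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int* m = LOGICAL(mask);
  const double INF = std::numeric_limits<double>::infinity();
  double d[3];
  int cell[3], stp[3];
  double tMax[3], tDelta[3];
  for (int a = 0; a < 3; ++a) {
    d[a] = p1[a] - p0[a];
    cell[a] = (int)std::floor(p0[a]);
    if (d[a] > 0) {
      stp[a] = 1;
      tMax[a] = ((cell[a] + 1) - p0[a]) / d[a];
      tDelta[a] = 1.0 / d[a];
    } else if (d[a] < 0) {
      stp[a] = -1;
      tMax[a] = (cell[a] - p0[a]) / d[a];
      tDelta[a] = -1.0 / d[a];
    } else {
      stp[a] = 0;
      tMax[a] = INF;
      tDelta[a] = INF;
    }
  }
  while (true) {
    if (cell[0] >= 0 && cell[0] < nx && cell[1] >= 0 && cell[1] < ny &&
        cell[2] >= 0 && cell[2] < nz) {
      if (m[cell[0] + (R_xlen_t)nx * (cell[1] + (R_xlen_t)ny * cell[2])])
        return true;
    }
    int a = (tMax[0] <= tMax[1] && tMax[0] <= tMax[2]) ? 0
            : ((tMax[1] <= tMax[2]) ? 1 : 2);
    if (tMax[a] > 1.0) break;
    cell[a] += stp[a];
    tMax[a] += tDelta[a];
  }
  return false;
}

// Fill interior cavities of a logical 3-D mask: BFS the complement from the
// grid border (6-connectivity); anything not reached is interior.
// [[Rcpp::export]]
LogicalVector fill_holes_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t ntot = nxy * nz;
  const int* m = LOGICAL(mask);
  std::vector<char> outside(ntot, 0);
  std::vector<R_xlen_t> queue;
  queue.reserve(ntot / 8);
  auto idx = [&](int x, int y, int z) {
    return (R_xlen_t)z * nxy + (R_xlen_t)y * nx + x;
  };
  auto push = [&](int x, int y, int z) {
    R_xlen_t i = idx(x, y, z);
    if (!outside[i] && m[i] == FALSE) { outside[i] = 1; queue.push_back(i); }
  };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) { push(0, y, z); push(nx - 1, y, z); }
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) { push(x, 0, z); push(x, ny - 1, z); }
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) { push(x, y, 0); push(x, y, nz - 1); }
  for (size_t head = 0; head < queue.size(); ++head) {
    R_xlen_t i = queue[head];
    int z = (int)(i / nxy);
    int rem = (int)(i - (R_xlen_t)z * nxy);
    int y = rem / nx, x = rem % nx;
    if (x > 0) push(x - 1, y, z);
    if (x < nx - 1) push(x + 1, y, z);
    if (y > 0) push(x, y - 1, z);
    if (y < ny - 1) push(x, y + 1, z);
    if (z > 0) push(x, y, z - 1);
    if (z < nz - 1) push(x, y, z + 1);
  }
  LogicalVector out(ntot);
  int* o = LOGICAL(out);
  for (R_xlen_t i = 0; i < ntot; ++i) o[i] = !outside[i];
  out.attr("dim") = dims;
  return out;
}
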