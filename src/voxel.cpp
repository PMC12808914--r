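#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 3D connected-component labeling of the nonzero phase.
// conn = 26 or 6. Returns integer labels (0 = background), labeled in
// scan order so output is deterministic.
// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector mask, IntegerVector dims, int conn) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> offx, offy, offz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (conn == 6 && manh != 1) continue;
        offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
      }
  const int nb = (int)offx.size();
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int x = (int)(p % nx);
      int y = (int)((p / nx) % ny);
      int z = (int)(p / ((R_xlen_t)nx * ny));
      for (int m = 0; m < nb; ++m) {
        int xx = x + offx[m], yy = y + offy[m], zz = z + offz[m];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t q = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher), f in/out.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance transform of the phase (mask true) to the
// nearest background voxel center, in voxel units. Outside the grid counts
// as background (distance to the boundary).
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d2(n);
  const double INF = 1e18;
  // initialize along x: squared distance to the nearest in-grid background
  // voxel within the row (INF when the row has none)
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      double last_bg = -INF;
      for (int x = 0; x < nx; ++x) {
        if (!mask[base + x]) { last_bg = x; d2[base + x] = 0.0; }
        else {
          double dd = x - last_bg;
          d2[base + x] = (dd >= 1e9) ? INF : dd * dd;
        }
      }
      double next_bg = INF;
      for (int x = nx - 1; x >= 0; --x) {
        if (!mask[base + x]) next_bg = x;
        else {
          double dd = next_bg - x;
          double v = (dd >= 1e9) ? INF : dd * dd;
          if (v < d2[base + x]) d2[base + x] = v;
        }
      }
    }
  // propagate along y then z with the parabola transform
  int nmax = std::max(ny, nz);
  std::vector<double> f(nmax), dcol(nmax), zz(nmax + 1);
  std::vector<int> vv(nmax);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y)
        f[y] = d2[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x];
      dt1d(f, dcol, vv, zz, ny);
      for (int y = 0; y < ny; ++y)
        d2[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x] = dcol[y];
    }
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z)
        f[z] = d2[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x];
      dt1d(f, dcol, vv, zz, nz);
      for (int z = 0; z < nz; ++z)
        d2[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x] = dcol[z];
    }
  // the grid boundary counts as background: the nearest virtual outside
  // voxel lies straight along one axis
  for (R_xlen_t p = 0; p < n; ++p) {
    if (!mask[p]) continue;
    int x = (int)(p % nx);
    int y = (int)((p / nx) % ny);
    int z = (int)(p / ((R_xlen_t)nx * ny));
    double bd = std::min({x + 1, nx - x, y + 1, ny - y, z + 1, nz - z});
    if (bd * bd < d2[p]) d2[p] = bd * bd;
  }
  d2.attr("dim") = dims;
  return d2;
}

// Local thickness by inscribed-sphere propagation. For every phase voxel p
// the sphere radius is r(p) = sqrt(edt2(p)) - 0.5 (distance from the voxel
// center to the near face of the nearest background voxel); the sphere
// covers voxels q with |q - p| <= r(p), and thickness(q) is the diameter of
// the largest covering sphere. Every sphere is painted (no domination
// pruning: a larger sphere covering a center does not cover that center's
// whole sphere), so the result is exact for this definition.
// [[Rcpp::export(name = ".localThickness3d")]]
NumericVector localThickness3d(LogicalVector mask, NumericVector edt2,
                               IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector th(n, 0.0);
  std::vector<R_xlen_t> centers;
  centers.reserve(n / 2);
  for (R_xlen_t p = 0; p < n; ++p) if (mask[p]) centers.push_back(p);
  std::sort(centers.begin(), centers.end(),
            [&](R_xlen_t a, R_xlen_t b) { return edt2[a] > edt2[b]; });
  for (R_xlen_t ci = 0; ci < (R_xlen_t)centers.size(); ++ci) {
    R_xlen_t p = centers[ci];
    double r = std::sqrt(edt2[p]) - 0.5;
    if (r < 0) r = 0;
    double dia = 2.0 * r;
    int x = (int)(p % nx);
    int y = (int)((p / nx) % ny);
    int z = (int)(p / ((R_xlen_t)nx * ny));
    int ri = (int)std::floor(r + 1e-9);
    double r2 = r * r + 1e-9;
    for (int dz = -ri; dz <= ri; ++dz) {
      int zzq = z + dz;
      if (zzq < 0 || zzq >= nz) continue;
      for (int dy = -ri; dy <= ri; ++dy) {
        int yyq = y + dy;
        if (yyq < 0 || yyq >= ny) continue;
        double dd2 = (double)dz * dz + (double)dy * dy;
        if (dd2 > r2) continue;
        int rx = (int)std::floor(std::sqrt(r2 - dd2));
        int x0 = std::max(0, x - rx), x1 = std::min(nx - 1, x + rx);
        R_xlen_t base = (R_xlen_t)zzq * nx * ny + (R_xlen_t)yyq * nx;
        for (int xx = x0; xx <= x1; ++xx)
          if (th[base + xx] < dia) th[base + xx] = dia;
      }
    }
  }
  th.attr("dim") = dims;
  return th;
}
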