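#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher exact 1D squared-distance transform.
// Uses a large finite constant instead of Inf so parabola intersections
// stay well defined on all-empty rows.
static const double DT_INF = 1e18;

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance (in voxel units) from every voxel to the
// nearest seed voxel (seed = TRUE). Distances are between voxel centres.
// [[Rcpp::export]]
NumericVector edt_squared_cpp(LogicalVector seed, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = seed[i] ? 0.0 : DT_INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int zz = 0; zz < nz; zz++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; x++) f[x] = out[base + x];
      dt1d(f, d, v, z, nx);
      for (int x = 0; x < nx; x++) out[base + x] = d[x];
    }
  // y pass
  for (int zz = 0; zz < nz; zz++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + x;
      for (int y = 0; y < ny; y++) f[y] = out[base + (R_xlen_t)y * nx];
      dt1d(f, d, v, z, ny);
      for (int y = 0; y < ny; y++) out[base + (R_xlen_t)y * nx] = d[y];
    }
  // z pass
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int zz = 0; zz < nz; zz++) f[zz] = out[base + (R_xlen_t)zz * nx * ny];
      dt1d(f, d, v, z, nz);
      for (int zz = 0; zz < nz; zz++) out[base + (R_xlen_t)zz * nx * ny] = d[zz];
    }
  return out;
}

struct CentreRec {
  double r2;
  int x, y, z;
};

// Local thickness by maximal inscribed spheres.
//
// Convention: the sphere centred at phase voxel c has radius r(c) equal to
// the Euclidean distance from c to the nearest opposite-phase voxel centre;
// the (open) sphere covers voxels i with d(i, c) < r(c); the thickness of a
// voxel is 2 * max(r) over all spheres covering it. Squared distances between
// voxel centres are integers, so the strict inequality is evaluated exactly.
// Returns the squared covering radius per voxel (0 outside the phase).
// [[Rcpp::export]]
NumericVector local_thickness_cpp(LogicalVector phase, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;

  LogicalVector seed(n);
  for (R_xlen_t i = 0; i < n; i++) seed[i] = !phase[i];
  NumericVector r2 = edt_squared_cpp(seed, dim);

  NumericVector th2(n);
  std::vector<CentreRec> centres;
  centres.reserve(n / 4);
  for (int zz = 0; zz < nz; zz++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t i = (R_xlen_t)zz * nx * ny + (R_xlen_t)y * nx + x;
        if (phase[i]) {
          CentreRec c;
          c.r2 = r2[i];
          c.x = x; c.y = y; c.z = zz;
          centres.push_back(c);
        }
      }
  std::sort(centres.begin(), centres.end(),
            [](const CentreRec &a, const CentreRec &b) { return a.r2 > b.r2; });

  for (size_t ci = 0; ci < centres.size(); ci++) {
    const CentreRec &c = centres[ci];
    double r = std::sqrt(c.r2);

    // Skip spheres provably contained in a neighbour's sphere:
    // r_j >= r_c + d(c, j) for one of the 26 neighbours j. Squared
    // distances are integers, so the test is exact after squaring:
    // (r2j - r2c - d2) >= 0 and (r2j - r2c - d2)^2 >= 4 * r2c * d2.
    bool redundant = false;
    for (int dz = -1; dz <= 1 && !redundant; dz++)
      for (int dy = -1; dy <= 1 && !redundant; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int xj = c.x + dx, yj = c.y + dy, zj = c.z + dz;
          if (xj < 0 || xj >= nx || yj < 0 || yj >= ny || zj < 0 || zj >= nz)
            continue;
          R_xlen_t j = (R_xlen_t)zj * nx * ny + (R_xlen_t)yj * nx + xj;
          if (!phase[j]) continue;
          double d2 = (double)(dx * dx + dy * dy + dz * dz);
          double lhs = r2[j] - c.r2 - d2;
          if (lhs >= 0.0 && lhs * lhs >= 4.0 * c.r2 * d2) {
            redundant = true;
            break;
          }
        }
    if (redundant) continue;

    int R = (int)std::ceil(r);
    for (int dz = -R; dz <= R; dz++) {
      int zj = c.z + dz;
      if (zj < 0 || zj >= nz) continue;
      for (int dy = -R; dy <= R; dy++) {
        int yj = c.y + dy;
        if (yj < 0 || yj >= ny) continue;
        R_xlen_t base = (R_xlen_t)zj * nx * ny + (R_xlen_t)yj * nx;
        for (int dx = -R; dx <= R; dx++) {
          int xj = c.x + dx;
          if (xj < 0 || xj >= nx) continue;
          double d2 = (double)dx * dx + (double)dy * dy + (double)dz * dz;
          if (d2 < c.r2 - 0.5) {  // integer squared distances: strict <
            R_xlen_t j = base + xj;
            if (phase[j] && th2[j] < c.r2) th2[j] = c.r2;
          }
        }
      }
    }
  }
  return th2;
}
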