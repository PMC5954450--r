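#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian smoothing with per-axis sigma (voxels). Values outside
// the grid are taken as zero; callers pad the volume so this is the
// background phase.
// [[Rcpp::export]]
NumericVector smooth3d_cpp(NumericVector field, IntegerVector dim,
                           NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector cur = clone(field);

  const int dims[3] = {nx, ny, nz};
  const R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};

  for (int axis = 0; axis < 3; axis++) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int rad = (int)std::ceil(3.5 * s);
    std::vector<double> k(2 * rad + 1);
    double ksum = 0;
    for (int i = -rad; i <= rad; i++) {
      k[i + rad] = std::exp(-0.5 * i * i / (s * s));
      ksum += k[i + rad];
    }
    for (size_t i = 0; i < k.size(); i++) k[i] /= ksum;

    NumericVector nxt(n);
    int len = dims[axis];
    R_xlen_t stride = strides[axis];
    // iterate over all lines along `axis`
    int d1 = (axis + 1) % 3, d2 = (axis + 2) % 3;
    for (int j2 = 0; j2 < dims[d2]; j2++)
      for (int j1 = 0; j1 < dims[d1]; j1++) {
        R_xlen_t base = (R_xlen_t)j1 * strides[d1] + (R_xlen_t)j2 * strides[d2];
        for (int p = 0; p < len; p++) {
          double acc = 0;
          int lo = std::max(0, p - rad), hi = std::min(len - 1, p + rad);
          for (int q = lo; q <= hi; q++)
            acc += k[q - p + rad] * cur[base + (R_xlen_t)q * stride];
          nxt[base + (R_xlen_t)p * stride] = acc;
        }
      }
    cur = nxt;
  }
  return cur;
}

static inline void interp_pt(const double *pa, const double *pb, double va,
                             double vb, double iso, double *out) {
  double t = (iso - va) / (vb - va);
  for (int i = 0; i < 3; i++) out[i] = pa[i] + t * (pb[i] - pa[i]);
}

static inline double tri_area(const double *a, const double *b,
                              const double *c) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double w[3] = {u[1] * v[2] - u[2] * v[1], u[2] * v[0] - u[0] * v[2],
                 u[0] * v[1] - u[1] * v[0]};
  return 0.5 * std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
}

// Area contributed by one tetrahedron of the iso-surface at `iso`.
static double tet_area(const double pts[4][3], const double vals[4],
                       double iso) {
  int inside[4], nin = 0;
  for (int i = 0; i < 4; i++) {
    inside[i] = vals[i] >= iso;
    nin += inside[i];
  }
  if (nin == 0 || nin == 4) return 0.0;

  if (nin == 1 || nin == 3) {
    int lone = -1;
    for (int i = 0; i < 4; i++)
      if ((nin == 1 && inside[i]) || (nin == 3 && !inside[i])) lone = i;
    double tri[3][3];
    int k = 0;
    for (int i = 0; i < 4; i++) {
      if (i == lone) continue;
      interp_pt(pts[lone], pts[i], vals[lone], vals[i], iso, tri[k++]);
    }
    return tri_area(tri[0], tri[1], tri[2]);
  }

  // nin == 2: quad between the two inside and two outside vertices
  int in_i[2], out_i[2], a = 0, bq = 0;
  for (int i = 0; i < 4; i++) {
    if (inside[i]) in_i[a++] = i; else out_i[bq++] = i;
  }
  double q[4][3];
  // cycle: (in0,out0) (in1,out0) (in1,out1) (in0,out1)
  interp_pt(pts[in_i[0]], pts[out_i[0]], vals[in_i[0]], vals[out_i[0]], iso, q[0]);
  interp_pt(pts[in_i[1]], pts[out_i[0]], vals[in_i[1]], vals[out_i[0]], iso, q[1]);
  interp_pt(pts[in_i[1]], pts[out_i[1]], vals[in_i[1]], vals[out_i[1]], iso, q[2]);
  interp_pt(pts[in_i[0]], pts[out_i[1]], vals[in_i[0]], vals[out_i[1]], iso, q[3]);
  return tri_area(q[0], q[1], q[2]) + tri_area(q[0], q[2], q[3]);
}

// Total iso-surface area (in voxel^2 units) of a scalar field sampled at
// voxel centres, by marching tetrahedra: each 2x2x2 cell is split into six
// tetrahedra around the main diagonal, and each tetrahedron is triangulated
// directly (no case table needed).
// [[Rcpp::export]]
double mesh_area_cpp(NumericVector field, IntegerVector dim, double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;

  // six-tet decomposition of the cube, vertices bit-coded x + 2y + 4z,
  // every tet containing the 0-7 diagonal
  static const int tets[6][4] = {{0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
                                 {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  double area = 0.0;

  for (int z = 0; z + 1 < nz; z++)
    for (int y = 0; y + 1 < ny; y++)
      for (int x = 0; x + 1 < nx; x++) {
        double v[8];
        double p[8][3];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; c++) {
          int cxi = x + (c & 1), cyi = y + ((c >> 1) & 1), czi = z + ((c >> 2) & 1);
          v[c] = field[(R_xlen_t)czi * sz + (R_xlen_t)cyi * sy + cxi];
          p[c][0] = cxi; p[c][1] = cyi; p[c][2] = czi;
          if (v[c] >= iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; t++) {
          double tp[4][3], tv[4];
          for (int i = 0; i < 4; i++) {
            int c = tets[t][i];
            tp[i][0] = p[c][0]; tp[i][1] = p[c][1]; tp[i][2] = p[c][2];
            tv[i] = v[c];
          }
          area += tet_area(tp, tv, iso);
        }
      }
  return area;
}
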