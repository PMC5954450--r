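#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a 3D mask, 6- or 26-connectivity.
// Labels are 1..k in discovery order; 0 for background (mask == FALSE).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  std::vector<int> off_x, off_y, off_z;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m != 1) continue;
        off_x.push_back(dx);
        off_y.push_back(dy);
        off_z.push_back(dz);
      }
  const int noff = (int)off_x.size();

  IntegerVector labels(n);
  int next = 0;
  std::vector<R_xlen_t> stack;

  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || labels[s] != 0) continue;
    next++;
    labels[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t i = stack.back();
      stack.pop_back();
      int x = (int)(i % nx);
      int y = (int)((i / nx) % ny);
      int z = (int)(i / ((R_xlen_t)nx * ny));
      for (int k = 0; k < noff; k++) {
        int xj = x + off_x[k], yj = y + off_y[k], zj = z + off_z[k];
        if (xj < 0 || xj >= nx || yj < 0 || yj >= ny || zj < 0 || zj >= nz)
          continue;
        R_xlen_t j = (R_xlen_t)zj * nx * ny + (R_xlen_t)yj * nx + xj;
        if (mask[j] && labels[j] == 0) {
          labels[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return labels;
}
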