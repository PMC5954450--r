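#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Mean intercept length by ray casting.
//
// For each direction a parallel bundle of rays (spacing `spacing` voxels in
// a plane orthogonal to the direction) is marched through the volume with
// step `step` voxels. Along each ray the sampled phase (nearest voxel) is
// tracked; every foreground/background transition between consecutive
// in-grid samples counts as one phase crossing. MIL(direction) = total
// in-grid ray length / number of crossings.
//
// Returns per-direction total length, crossing count and MIL (NaN when the
// direction has no crossings).
// [[Rcpp::export]]
List mil_cpp(LogicalVector mask, IntegerVector dim, NumericMatrix dirs,
             double spacing, double step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nd = dirs.nrow();
  NumericVector total_len(nd), mil(nd);
  IntegerVector crossings(nd);

  const double cx = nx / 2.0, cy = ny / 2.0, cz = nz / 2.0;

  for (int id = 0; id < nd; id++) {
    double dx = dirs(id, 0), dy = dirs(id, 1), dz = dirs(id, 2);
    double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
    dx /= nrm; dy /= nrm; dz /= nrm;

    // orthonormal frame (u, v, d)
    double ax = std::fabs(dx), ay = std::fabs(dy), az = std::fabs(dz);
    double ux, uy, uz;
    if (ax <= ay && ax <= az) { ux = 0; uy = -dz; uz = dy; }
    else if (ay <= az)        { ux = -dz; uy = 0; uz = dx; }
    else                      { ux = -dy; uy = dx; uz = 0; }
    double un = std::sqrt(ux * ux + uy * uy + uz * uz);
    ux /= un; uy /= un; uz /= un;
    double vx = dy * uz - dz * uy;
    double vy = dz * ux - dx * uz;
    double vz = dx * uy - dy * ux;

    // extent of the box corners in the (u, v) plane (relative to centre)
    double amin = 0, amax = 0, bmin = 0, bmax = 0;
    for (int corner = 0; corner < 8; corner++) {
      double px = ((corner & 1) ? nx : 0) - cx;
      double py = ((corner & 2) ? ny : 0) - cy;
      double pz = ((corner & 4) ? nz : 0) - cz;
      double a = px * ux + py * uy + pz * uz;
      double b = px * vx + py * vy + pz * vz;
      amin = std::min(amin, a); amax = std::max(amax, a);
      bmin = std::min(bmin, b); bmax = std::max(bmax, b);
    }

    double len = 0;
    int cross = 0;

    for (double a = amin; a <= amax; a += spacing) {
      for (double b = bmin; b <= bmax; b += spacing) {
        double ox = cx + a * ux + b * vx;
        double oy = cy + a * uy + b * vy;
        double oz = cz + a * uz + b * vz;

        // clip the ray o + t*d against the box [0,nx]x[0,ny]x[0,nz]
        double t0 = -1e30, t1 = 1e30;
        bool miss = false;
        double o[3] = {ox, oy, oz};
        double dd[3] = {dx, dy, dz};
        double hi[3] = {(double)nx, (double)ny, (double)nz};
        for (int axi = 0; axi < 3; axi++) {
          if (std::fabs(dd[axi]) < 1e-12) {
            if (o[axi] < 0 || o[axi] > hi[axi]) { miss = true; break; }
          } else {
            double ta = (0 - o[axi]) / dd[axi];
            double tb = (hi[axi] - o[axi]) / dd[axi];
            if (ta > tb) std::swap(ta, tb);
            t0 = std::max(t0, ta);
            t1 = std::min(t1, tb);
          }
        }
        if (miss || t1 <= t0) continue;

        int prev = -1;  // -1 = no previous in-grid sample
        int nin = 0;
        for (double t = t0; t <= t1; t += step) {
          int ix = (int)std::floor(ox + t * dx);
          int iy = (int)std::floor(oy + t * dy);
          int iz = (int)std::floor(oz + t * dz);
          if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
            prev = -1;
            continue;
          }
          int fg = mask[(R_xlen_t)iz * nx * ny + (R_xlen_t)iy * nx + ix] ? 1 : 0;
          nin++;
          if (prev >= 0 && fg != prev) cross++;
          prev = fg;
        }
        len += nin * step;
      }
    }
    total_len[id] = len;
    crossings[id] = cross;
    mil[id] = cross > 0 ? len / cross : NA_REAL;
  }
  return List::create(_["mil"] = mil, _["total_length"] = total_len,
                      _["crossings"] = crossings);
}
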