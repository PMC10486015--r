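// Rasterization helper for the phantom generator: stamp balls (tube
// centerline samples with per-point radii) into a voxel mask.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// points: m x 3 matrix of physical coordinates (um), radii: length m (um);
// voxel centres sit at (index - 1) * voxel (1-based R indexing convention).
// [[Rcpp::export]]
LogicalVector stamp_balls_cpp(IntegerVector dim, double voxel,
                              NumericMatrix points, NumericVector radii) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector mask(n);
  for (int p = 0; p < points.nrow(); ++p) {
    double cx = points(p, 0), cy = points(p, 1), cz = points(p, 2);
    double r = radii[p];
    if (r <= 0) continue;
    double r2 = r * r;
    int i0 = (int)std::floor((cx - r) / voxel), i1 = (int)std::ceil((cx + r) / voxel);
    int j0 = (int)std::floor((cy - r) / voxel), j1 = (int)std::ceil((cy + r) / voxel);
    int k0 = (int)std::floor((cz - r) / voxel), k1 = (int)std::ceil((cz + r) / voxel);
    if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0; if (k0 < 0) k0 = 0;
    if (i1 > nx - 1) i1 = nx - 1;
    if (j1 > ny - 1) j1 = ny - 1;
    if (k1 > nz - 1) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      double dz = k * voxel - cz;
      for (int j = j0; j <= j1; ++j) {
        double dy = j * voxel - cy;
        double dyz = dy * dy + dz * dz;
        if (dyz > r2) continue;
        for (int i = i0; i <= i1; ++i) {
          double dx = i * voxel - cx;
          if (dx * dx + dyz <= r2)
            mask[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
        }
      }
    }
  }
  return mask;
}
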