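// Exact Euclidean distance transform, 3D, separable lower-envelope algorithm.
// Distances are in voxel units (squared); callers scale by voxel size.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double BIG = 1e20;

// 1D squared distance transform of sampled function f (length n) into d.
static void dt1d(const double* f, double* d, int n, int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (voxels^2) from every voxel to the nearest TRUE
// voxel of `feature`. All-FALSE input returns BIG everywhere.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector feature, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  double* g = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = feature[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double* row = g + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      dt1d(row, d.data(), nx, v.data(), z.data());
      for (int i = 0; i < nx; ++i) row[i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      double* base = g + i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = base[(R_xlen_t)nx * j];
      dt1d(f.data(), d.data(), ny, v.data(), z.data());
      for (int j = 0; j < ny; ++j) base[(R_xlen_t)nx * j] = d[j];
    }
  // pass along z
  const R_xlen_t stz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double* base = g + i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = base[stz * k];
      dt1d(f.data(), d.data(), nz, v.data(), z.data());
      for (int k = 0; k < nz; ++k) base[stz * k] = d[k];
    }
  return out;
}
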