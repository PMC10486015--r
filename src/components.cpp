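// Connected-component labeling (6- or 26-connectivity), per-label moment
// accumulation, and multi-source BFS label propagation.
#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);  // zero-initialized
  std::vector<R_xlen_t> stack;
  int next = 0;

  // neighbour offsets
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && man != 1) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  const int nn = (int)dxs.size();

  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      int rem = (int)(cur % ((R_xlen_t)nx * ny));
      int j = rem / nx, i = rem % nx;
      for (int t = 0; t < nn; ++t) {
        int ii = i + dxs[t], jj = j + dys[t], kk = k + dzs[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// Per-label voxel count and raw moments of 0-based voxel indices:
// columns: count, sx, sy, sz, sxx, syy, szz, sxy, sxz, syz
// [[Rcpp::export]]
NumericMatrix label_moments_cpp(IntegerVector lab, IntegerVector dim,
                                int n_labels) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix m(n_labels, 10);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        int l = lab[idx];
        if (l <= 0) continue;
        int r = l - 1;
        m(r, 0) += 1.0;
        m(r, 1) += i; m(r, 2) += j; m(r, 3) += k;
        m(r, 4) += (double)i * i;
        m(r, 5) += (double)j * j;
        m(r, 6) += (double)k * k;
        m(r, 7) += (double)i * j;
        m(r, 8) += (double)i * k;
        m(r, 9) += (double)j * k;
      }
  return m;
}

// Propagate seed labels over `mask` by multi-source BFS (26-connectivity);
// used to attribute pore voxels to the nearest skeleton segment.
// [[Rcpp::export]]
IntegerVector propagate_labels_cpp(LogicalVector mask, IntegerVector seeds,
                                   IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s)
    if (seeds[s] > 0) {
      lab[s] = seeds[s];
      q.push(s);
    }
  while (!q.empty()) {
    R_xlen_t cur = q.front();
    q.pop();
    int k = (int)(cur / ((R_xlen_t)nx * ny));
    int rem = (int)(cur % ((R_xlen_t)nx * ny));
    int j = rem / nx, i = rem % nx;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int ii = i + dx, jj = j + dy, kk = k + dz;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          R_xlen_t t = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          if (mask[t] && lab[t] == 0) {
            lab[t] = lab[cur];
            q.push(t);
          }
        }
  }
  return lab;
}
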