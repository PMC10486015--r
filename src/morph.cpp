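// Separable grayscale morphology (running max/min, monotonic deque) and
// separable Gaussian convolution with reflective boundaries.
#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cmath>
using namespace Rcpp;

// sliding-window extremum along one axis; window = 2*half + 1, clipped at ends
static void run_extremum_line(const double* in, double* out, int n,
                              R_xlen_t stride, int half, bool take_max) {
  std::deque<int> q;  // indices, values monotone
  int r = 0;
  for (int i = 0; i < n; ++i) {
    // push elements up to i + half
    while (r <= i + half && r < n) {
      double v = in[(R_xlen_t)r * stride];
      while (!q.empty()) {
        double back = in[(R_xlen_t)q.back() * stride];
        if (take_max ? (back <= v) : (back >= v)) q.pop_back(); else break;
      }
      q.push_back(r);
      ++r;
    }
    while (q.front() < i - half) q.pop_front();
    out[(R_xlen_t)i * stride] = in[(R_xlen_t)q.front() * stride];
  }
}

static void filter_axis(double* g, int nx, int ny, int nz, int axis, int half,
                        bool take_max) {
  std::vector<double> buf;
  if (axis == 0) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        double* row = g + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        buf.assign(row, row + nx);
        run_extremum_line(buf.data(), row, nx, 1, half, take_max);
      }
  } else if (axis == 1) {
    buf.resize(ny);
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        double* base = g + i + (R_xlen_t)nx * ny * k;
        for (int j = 0; j < ny; ++j) buf[j] = base[(R_xlen_t)nx * j];
        std::vector<double> outb(ny);
        run_extremum_line(buf.data(), outb.data(), ny, 1, half, take_max);
        for (int j = 0; j < ny; ++j) base[(R_xlen_t)nx * j] = outb[j];
      }
  } else {
    buf.resize(nz);
    const R_xlen_t stz = (R_xlen_t)nx * ny;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double* base = g + i + (R_xlen_t)nx * j;
        for (int k = 0; k < nz; ++k) buf[k] = base[stz * k];
        std::vector<double> outb(nz);
        run_extremum_line(buf.data(), outb.data(), nz, 1, half, take_max);
        for (int k = 0; k < nz; ++k) base[stz * k] = outb[k];
      }
  }
}

// Grayscale dilation (op = 1) or erosion (op = 0) with a cube structuring
// element of half-width `half` voxels.
// [[Rcpp::export]]
NumericVector cube_filter_cpp(NumericVector vol, IntegerVector dim, int half,
                              int op) {
  NumericVector out = clone(vol);
  double* g = REAL(out);
  bool take_max = (op == 1);
  filter_axis(g, dim[0], dim[1], dim[2], 0, half, take_max);
  filter_axis(g, dim[0], dim[1], dim[2], 1, half, take_max);
  filter_axis(g, dim[0], dim[1], dim[2], 2, half, take_max);
  return out;
}

static void conv_line(const double* in, double* out, int n, R_xlen_t stride,
                      const std::vector<double>& ker) {
  int half = ((int)ker.size() - 1) / 2;
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int t = -half; t <= half; ++t) {
      int idx = i + t;
      if (idx < 0) idx = -idx - 1;          // reflect
      if (idx >= n) idx = 2 * n - idx - 1;  // reflect
      if (idx < 0) idx = 0;
      if (idx >= n) idx = n - 1;
      acc += ker[t + half] * in[(R_xlen_t)idx * stride];
    }
    out[(R_xlen_t)i * stride] = acc;
  }
}

// Separable Gaussian blur, sigma in voxels, reflective boundaries.
// [[Rcpp::export]]
NumericVector gaussian_blur_cpp(NumericVector vol, IntegerVector dim,
                                double sigma) {
  NumericVector out = clone(vol);
  if (sigma <= 0) return out;
  int half = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * half + 1);
  double s = 0;
  for (int t = -half; t <= half; ++t) {
    ker[t + half] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + half];
  }
  for (auto& k : ker) k /= s;

  const int nx = dim[0], ny = dim[1], nz = dim[2];
  double* g = REAL(out);
  std::vector<double> buf;
  // x
  buf.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double* row = g + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      std::copy(row, row + nx, buf.begin());
      conv_line(buf.data(), row, nx, 1, ker);
    }
  // y
  buf.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      double* base = g + i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) buf[j] = base[(R_xlen_t)nx * j];
      std::vector<double> outb(ny);
      conv_line(buf.data(), outb.data(), ny, 1, ker);
      for (int j = 0; j < ny; ++j) base[(R_xlen_t)nx * j] = outb[j];
    }
  // z
  buf.resize(nz);
  const R_xlen_t stz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double* base = g + i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) buf[k] = base[stz * k];
      std::vector<double> outb(nz);
      conv_line(buf.data(), outb.data(), nz, 1, ker);
      for (int k = 0; k < nz; ++k) base[stz * k] = outb[k];
    }
  return out;
}
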