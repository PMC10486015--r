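// Single-relaxation (BGK) D3Q19 lattice-Boltzmann solver for creeping flow in
// a binary pore geometry: body-force driving, Guo forcing term, half-way
// bounce-back at solid voxels, periodic boundaries on all faces.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int CX[19] = {0, 1,-1, 0, 0, 0, 0, 1,-1, 1,-1, 1,-1, 1,-1, 0, 0, 0, 0};
static const int CY[19] = {0, 0, 0, 1,-1, 0, 0, 1,-1,-1, 1, 0, 0, 0, 0, 1,-1, 1,-1};
static const int CZ[19] = {0, 0, 0, 0, 0, 1,-1, 0, 0, 0, 0, 1,-1,-1, 1, 1,-1,-1, 1};
static const double W[19] = {
  1.0/3,
  1.0/18, 1.0/18, 1.0/18, 1.0/18, 1.0/18, 1.0/18,
  1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36,
  1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36};

// [[Rcpp::export]]
List lbm_flow_cpp(LogicalVector pore, IntegerVector dim, NumericVector force,
                  double tau, double tol, double max_iter, int check_every) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double fx = force[0], fy = force[1], fz = force[2];

  int opp[19];
  for (int d = 0; d < 19; ++d)
    for (int e = 0; e < 19; ++e)
      if (CX[e] == -CX[d] && CY[e] == -CY[d] && CZ[e] == -CZ[d]) opp[d] = e;

  std::vector<char> solid(n);
  R_xlen_t nfluid = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    solid[s] = pore[s] ? 0 : 1;
    if (!solid[s]) ++nfluid;
  }
  if (nfluid == 0)
    return List::create(_["mean_u"] = NumericVector::create(0, 0, 0),
                        _["mean_u_pore"] = NumericVector::create(0, 0, 0),
                        _["porosity"] = 0.0, _["iterations"] = 0,
                        _["converged"] = true, _["residual"] = 0.0,
                        _["nu"] = (tau - 0.5) / 3.0);

  std::vector<double> f((size_t)n * 19), f2((size_t)n * 19);
  for (R_xlen_t s = 0; s < n; ++s)
    for (int d = 0; d < 19; ++d) f[(size_t)d * n + s] = W[d];

  const double omega = 1.0 / tau;
  const double fcoef = 1.0 - 0.5 * omega;
  double prev[3] = {0, 0, 0};
  double residual = R_PosInf;
  bool converged = false;
  double iter = 0;

  while (iter < max_iter) {
    // collision (fluid nodes only)
    for (R_xlen_t s = 0; s < n; ++s) {
      if (solid[s]) continue;
      double rho = 0, ux = 0, uy = 0, uz = 0;
      double fi[19];
      for (int d = 0; d < 19; ++d) {
        fi[d] = f[(size_t)d * n + s];
        rho += fi[d];
        ux += fi[d] * CX[d];
        uy += fi[d] * CY[d];
        uz += fi[d] * CZ[d];
      }
      ux = (ux + 0.5 * fx) / rho;
      uy = (uy + 0.5 * fy) / rho;
      uz = (uz + 0.5 * fz) / rho;
      double usq = ux * ux + uy * uy + uz * uz;
      for (int d = 0; d < 19; ++d) {
        double cu = CX[d] * ux + CY[d] * uy + CZ[d] * uz;
        double feq = W[d] * rho * (1.0 + 3.0 * cu + 4.5 * cu * cu - 1.5 * usq);
        double cf = CX[d] * fx + CY[d] * fy + CZ[d] * fz;
        double uf = ux * fx + uy * fy + uz * fz;
        double Fd = fcoef * W[d] * (3.0 * (cf - uf) + 9.0 * cu * cf);
        f[(size_t)d * n + s] = fi[d] - omega * (fi[d] - feq) + Fd;
      }
    }
    // streaming with bounce-back, pull scheme
    for (int d = 0; d < 19; ++d) {
      const double* fs = f.data() + (size_t)d * n;
      const double* fo = f.data() + (size_t)opp[d] * n;
      double* ft = f2.data() + (size_t)d * n;
      R_xlen_t s = 0;
      for (int k = 0; k < nz; ++k) {
        int ks = k - CZ[d]; if (ks < 0) ks += nz; if (ks >= nz) ks -= nz;
        for (int j = 0; j < ny; ++j) {
          int js = j - CY[d]; if (js < 0) js += ny; if (js >= ny) js -= ny;
          for (int i = 0; i < nx; ++i, ++s) {
            if (solid[s]) continue;
            int is = i - CX[d]; if (is < 0) is += nx; if (is >= nx) is -= nx;
            R_xlen_t src = is + (R_xlen_t)nx * (js + (R_xlen_t)ny * ks);
            ft[s] = solid[src] ? fo[s] : fs[src];
          }
        }
      }
    }
    f.swap(f2);
    iter += 1;

    if (((long long)iter) % check_every == 0) {
      double m[3] = {0, 0, 0};
      for (R_xlen_t s = 0; s < n; ++s) {
        if (solid[s]) continue;
        double rho = 0, ux = 0, uy = 0, uz = 0;
        for (int d = 0; d < 19; ++d) {
          double v = f[(size_t)d * n + s];
          rho += v; ux += v * CX[d]; uy += v * CY[d]; uz += v * CZ[d];
        }
        m[0] += (ux + 0.5 * fx) / rho;
        m[1] += (uy + 0.5 * fy) / rho;
        m[2] += (uz + 0.5 * fz) / rho;
      }
      double num = 0, den = 0;
      for (int c = 0; c < 3; ++c) {
        num += (m[c] - prev[c]) * (m[c] - prev[c]);
        den += m[c] * m[c];
        prev[c] = m[c];
      }
      residual = den > 0 ? std::sqrt(num / den) : R_PosInf;
      if (residual < tol) { converged = true; break; }
    }
  }

  // final macroscopic velocity sums
  double msum[3] = {0, 0, 0};
  for (R_xlen_t s = 0; s < n; ++s) {
    if (solid[s]) continue;
    double rho = 0, ux = 0, uy = 0, uz = 0;
    for (int d = 0; d < 19; ++d) {
      double v = f[(size_t)d * n + s];
      rho += v; ux += v * CX[d]; uy += v * CY[d]; uz += v * CZ[d];
    }
    msum[0] += (ux + 0.5 * fx) / rho;
    msum[1] += (uy + 0.5 * fy) / rho;
    msum[2] += (uz + 0.5 * fz) / rho;
  }
  NumericVector mean_u = NumericVector::create(
      msum[0] / n, msum[1] / n, msum[2] / n);
  NumericVector mean_up = NumericVector::create(
      msum[0] / nfluid, msum[1] / nfluid, msum[2] / nfluid);
  return List::create(_["mean_u"] = mean_u, _["mean_u_pore"] = mean_up,
                      _["porosity"] = (double)nfluid / (double)n,
                      _["iterations"] = iter, _["converged"] = converged,
                      _["residual"] = residual,
                      _["nu"] = (tau - 0.5) / 3.0);
}
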