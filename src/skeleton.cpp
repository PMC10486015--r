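// Curve skeletonization by distance-ordered homotopic thinning: simple points
// (whose deletion preserves topology) are removed in order of increasing
// distance-transform value; curve endpoints are preserved.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// local 3x3x3 neighbourhood, index = (dx+1) + 3*(dy+1) + 9*(dz+1), centre 13
static inline int loc(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

// condition A: foreground of N26 forms exactly one 26-connected component
static bool one_fg_component(const bool* nb) {
  int first = -1, nfg = 0;
  for (int t = 0; t < 27; ++t) {
    if (t == 13) continue;
    if (nb[t]) { ++nfg; if (first < 0) first = t; }
  }
  if (nfg == 0) return false;
  bool vis[27] = {false};
  int stack[27], sp = 0;
  stack[sp++] = first;
  vis[first] = true;
  int seen = 1;
  while (sp) {
    int cur = stack[--sp];
    int cx = cur % 3 - 1, cy = (cur / 3) % 3 - 1, cz = cur / 9 - 1;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int nx2 = cx + dx, ny2 = cy + dy, nz2 = cz + dz;
          if (nx2 < -1 || nx2 > 1 || ny2 < -1 || ny2 > 1 || nz2 < -1 || nz2 > 1)
            continue;
          int t = loc(nx2, ny2, nz2);
          if (t == 13 || vis[t] || !nb[t]) continue;
          vis[t] = true;
          stack[sp++] = t;
          ++seen;
        }
  }
  return seen == nfg;
}

// condition B: background 6-neighbours of the centre all belong to one
// 6-connected background component within the 18-neighbourhood
static bool one_bg_component(const bool* nb) {
  static const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  int seeds[6], ns = 0;
  for (int s = 0; s < 6; ++s) {
    int t = loc(d6[s][0], d6[s][1], d6[s][2]);
    if (!nb[t]) seeds[ns++] = t;
  }
  if (ns == 0) return false;  // interior voxel, not deletable
  bool vis[27] = {false};
  int stack[27], sp = 0;
  stack[sp++] = seeds[0];
  vis[seeds[0]] = true;
  while (sp) {
    int cur = stack[--sp];
    int cx = cur % 3 - 1, cy = (cur / 3) % 3 - 1, cz = cur / 9 - 1;
    for (int s = 0; s < 6; ++s) {
      int nx2 = cx + d6[s][0], ny2 = cy + d6[s][1], nz2 = cz + d6[s][2];
      if (nx2 < -1 || nx2 > 1 || ny2 < -1 || ny2 > 1 || nz2 < -1 || nz2 > 1)
        continue;
      // restrict to the 18-neighbourhood
      if (std::abs(nx2) + std::abs(ny2) + std::abs(nz2) > 2) continue;
      int t = loc(nx2, ny2, nz2);
      if (t == 13 || vis[t] || nb[t]) continue;
      vis[t] = true;
      stack[sp++] = t;
    }
  }
  for (int s = 1; s < ns; ++s)
    if (!vis[seeds[s]]) return false;
  return true;
}

// [[Rcpp::export]]
LogicalVector thin_skeleton_cpp(LogicalVector mask, IntegerVector dim,
                                NumericVector priority) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> fg(n);
  for (R_xlen_t s = 0; s < n; ++s) fg[s] = mask[s] ? 1 : 0;

  auto at = [&](int i, int j, int k) -> bool {
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return false;
    return fg[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] != 0;
  };
  auto fill_nb = [&](int i, int j, int k, bool* nb) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          nb[loc(dx, dy, dz)] = at(i + dx, j + dy, k + dz);
  };
  auto n26 = [&](int i, int j, int k) -> int {
    int c = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          if (at(i + dx, j + dy, k + dz)) ++c;
        }
    return c;
  };

  std::vector<R_xlen_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    cand.clear();
    R_xlen_t idx = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++idx) {
          if (!fg[idx]) continue;
          // border: has a 6-neighbour background (incl. out-of-volume? no:
          // out-of-volume treated as background only for topology, but we do
          // not erode from volume faces to avoid clipping through-structures)
          bool border = false;
          if (i > 0 && !at(i - 1, j, k)) border = true;
          else if (i < nx - 1 && !at(i + 1, j, k)) border = true;
          else if (j > 0 && !at(i, j - 1, k)) border = true;
          else if (j < ny - 1 && !at(i, j + 1, k)) border = true;
          else if (k > 0 && !at(i, j, k - 1)) border = true;
          else if (k < nz - 1 && !at(i, j, k + 1)) border = true;
          if (border) cand.push_back(idx);
        }
    std::stable_sort(cand.begin(), cand.end(),
                     [&](R_xlen_t a, R_xlen_t b) {
                       return priority[a] < priority[b];
                     });
    for (R_xlen_t c = 0; c < (R_xlen_t)cand.size(); ++c) {
      R_xlen_t s = cand[c];
      if (!fg[s]) continue;
      int k = (int)(s / ((R_xlen_t)nx * ny));
      int rem = (int)(s % ((R_xlen_t)nx * ny));
      int j = rem / nx, i = rem % nx;
      if (n26(i, j, k) <= 1) continue;  // endpoint or isolated
      bool nb[27];
      fill_nb(i, j, k, nb);
      if (one_fg_component(nb) && one_bg_component(nb)) {
        fg[s] = 0;
        changed = true;
      }
    }
  }

  LogicalVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = fg[s] != 0;
  return out;
}
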