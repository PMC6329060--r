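#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected flood fill from a seed voxel (0-based linear index).
// Returns the connected component containing the seed as a logical vector
// of the same length as the mask.

// [[Rcpp::export(name = ".flood_fill26")]]
LogicalVector flood_fill26(LogicalVector mask, IntegerVector dims, double seed_lin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  R_xlen_t seed = (R_xlen_t)seed_lin;
  if (seed < 0 || seed >= n) stop("seed out of range");
  const int *m = LOGICAL(mask);
  if (m[seed] != TRUE) stop("seed voxel is not set in the mask");

  std::vector<char> out(n, 0);
  std::vector<R_xlen_t> stack;
  stack.reserve(4096);
  out[seed] = 1;
  stack.push_back(seed);

  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  while (!stack.empty()) {
    R_xlen_t cur = stack.back();
    stack.pop_back();
    int k = (int)(cur / sz);
    R_xlen_t rem = cur - (R_xlen_t)k * sz;
    int j = (int)(rem / sy);
    int i = (int)(rem - (R_xlen_t)j * sy);
    for (int dk = -1; dk <= 1; ++dk) {
      int kk = k + dk;
      if (kk < 0 || kk >= nz) continue;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= ny) continue;
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          int ii = i + di;
          if (ii < 0 || ii >= nx) continue;
          R_xlen_t nb = ii * sx + jj * sy + (R_xlen_t)kk * sz;
          if (m[nb] == TRUE && !out[nb]) {
            out[nb] = 1;
            stack.push_back(nb);
          }
        }
      }
    }
  }

  LogicalVector res(n);
  int *r = LOGICAL(res);
  for (R_xlen_t p = 0; p < n; ++p) r[p] = out[p] ? TRUE : FALSE;
  return res;
}
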