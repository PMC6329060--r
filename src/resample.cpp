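#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double tri_sample(const double *v, int nx, int ny, int nz,
                                double x, double y, double z, double outside) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return outside;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == nx - 1) --i0;
  if (j0 == ny - 1) --j0;
  if (k0 == nz - 1) --k0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  R_xlen_t b = i0 + (R_xlen_t)j0 * sy + (R_xlen_t)k0 * sz;
  double c000 = v[b],           c100 = v[b + 1];
  double c010 = v[b + sy],      c110 = v[b + sy + 1];
  double c001 = v[b + sz],      c101 = v[b + sz + 1];
  double c011 = v[b + sy + sz], c111 = v[b + sy + sz + 1];
  double c00 = c000 + fx * (c100 - c000);
  double c10 = c010 + fx * (c110 - c010);
  double c01 = c001 + fx * (c101 - c001);
  double c11 = c011 + fx * (c111 - c011);
  double c0 = c00 + fy * (c10 - c00);
  double c1 = c01 + fy * (c11 - c01);
  return c0 + fz * (c1 - c0);
}

// Trilinear interpolation of a 3-d grid at continuous 0-based index
// coordinates.  Points outside the grid return `outside`.

// [[Rcpp::export(name = ".trilinear_sample")]]
NumericVector trilinear_sample(NumericVector vol, IntegerVector dims,
                               NumericMatrix pts, double outside) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *v = REAL(vol);
  R_xlen_t m = pts.nrow();
  NumericVector out(m);
  for (R_xlen_t p = 0; p < m; ++p)
    out[p] = tri_sample(v, nx, ny, nz, pts(p, 0), pts(p, 1), pts(p, 2), outside);
  return out;
}

// Resample a grid through an affine map: for every output voxel (i,j,k)
// the source index coordinate is A %*% (i,j,k) + b, sampled trilinearly.

// [[Rcpp::export(name = ".resample_affine")]]
NumericVector resample_affine(NumericVector vol, IntegerVector dims,
                              IntegerVector out_dims, NumericMatrix A,
                              NumericVector b, double outside) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = out_dims[0], oy = out_dims[1], oz = out_dims[2];
  const double *v = REAL(vol);
  NumericVector out((R_xlen_t)ox * oy * oz);
  double *o = REAL(out);
  R_xlen_t p = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      double bx = A(0, 1) * j + A(0, 2) * k + b[0];
      double by = A(1, 1) * j + A(1, 2) * k + b[1];
      double bz = A(2, 1) * j + A(2, 2) * k + b[2];
      for (int i = 0; i < ox; ++i, ++p) {
        double x = A(0, 0) * i + bx;
        double y = A(1, 0) * i + by;
        double z = A(2, 0) * i + bz;
        o[p] = tri_sample(v, nx, ny, nz, x, y, z, outside);
      }
    }
  }
  return out;
}
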