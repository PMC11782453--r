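#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Exact Euclidean distance transform on an anisotropic grid, by separable
// lower-envelope-of-parabolas passes (Felzenszwalb & Huttenlocher, 2012).
// Sites are the TRUE voxels; the result holds, at every voxel, the squared
// Euclidean distance (mm^2) between voxel centers, using the physical
// spacing of each axis. Voxels with no site anywhere get +Inf.

// Finite stand-in for "no site": far above any realistic squared mm
// distance, far below overflow when offsets are added.
static const double HUGE_SQ = 1e20;

// One 1-D lower-envelope pass along n samples at pitch h (mm); f holds
// squared distances on input and is overwritten in place.
static void edt1d(std::vector<double>& f, std::vector<double>& d,
                  std::vector<int>& v, std::vector<double>& z,
                  int n, double h) {
  int k = 0;
  v[0] = 0;
  z[0] = -HUGE_SQ;
  z[1] = HUGE_SQ;
  for (int q = 1; q < n; ++q) {
    double xq = q * h;
    double s;
    while (true) {
      double xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    if (s <= z[k]) { // k == 0 and still dominated: replace the root
      v[0] = q;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
    }
    z[k + 1] = HUGE_SQ;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * h;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dim,
                     NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (mask[i] == TRUE) ? 0.0 : HUGE_SQ;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying index)
  for (int kz = 0; kz < nz; ++kz)
    for (int ky = 0; ky < ny; ++ky) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      edt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = f[i];
    }
  // pass along y
  for (int kz = 0; kz < nz; ++kz)
    for (int kx = 0; kx < nx; ++kx) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + kx;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      edt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = f[j];
    }
  // pass along z
  for (int ky = 0; ky < ny; ++ky)
    for (int kx = 0; kx < nx; ++kx) {
      R_xlen_t base = (R_xlen_t)ky * nx + kx;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nx * ny];
      edt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nx * ny] = f[k];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] >= 1e19) out[i] = R_PosInf;
  return out;
}
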