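#include <Rcpp.h>
using namespace Rcpp;

// Trilinear sampling of a 3D array at continuous 0-based voxel coordinates.
// Coordinates outside [0, dim-1] on any axis return `fill`.
// [[Rcpp::export]]
NumericVector trilinear_sample_cpp(const NumericVector& grid,
                                   const IntegerVector& dims,
                                   const NumericMatrix& idx,
                                   double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = idx.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    const double x = idx(p, 0), y = idx(p, 1), z = idx(p, 2);
    if (!(x >= 0.0) || !(y >= 0.0) || !(z >= 0.0) ||
        x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) {
      out[p] = fill;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
    if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
    if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
    // degenerate single-slab axes: clamp weight instead
    const double fx = (nx == 1) ? 0.0 : x - x0;
    const double fy = (ny == 1) ? 0.0 : y - y0;
    const double fz = (nz == 1) ? 0.0 : z - z0;
    const int x1 = (nx == 1) ? x0 : x0 + 1;
    const int y1 = (ny == 1) ? y0 : y0 + 1;
    const int z1 = (nz == 1) ? z0 : z0 + 1;
    const R_xlen_t sxy = (R_xlen_t)nx * ny;
    #define G(i, j, k) grid[(i) + (R_xlen_t)nx * (j) + sxy * (k)]
    const double c00 = G(x0, y0, z0) * (1 - fx) + G(x1, y0, z0) * fx;
    const double c10 = G(x0, y1, z0) * (1 - fx) + G(x1, y1, z0) * fx;
    const double c01 = G(x0, y0, z1) * (1 - fx) + G(x1, y0, z1) * fx;
    const double c11 = G(x0, y1, z1) * (1 - fx) + G(x1, y1, z1) * fx;
    #undef G
    const double c0 = c00 * (1 - fy) + c10 * fy;
    const double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Bilinear sampling of a matrix at continuous 0-based coordinates (rows, cols).
// [[Rcpp::export]]
NumericVector bilinear_sample_cpp(const NumericMatrix& m,
                                  const NumericVector& ri,
                                  const NumericVector& ci,
                                  double fill) {
  const int nr = m.nrow(), nc = m.ncol();
  const int n = ri.size();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    const double r = ri[p], c = ci[p];
    if (!(r >= 0.0) || !(c >= 0.0) || r > nr - 1.0 || c > nc - 1.0) {
      out[p] = fill;
      continue;
    }
    int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    if (r0 > nr - 2) r0 = nr - 2; if (r0 < 0) r0 = 0;
    if (c0 > nc - 2) c0 = nc - 2; if (c0 < 0) c0 = 0;
    const double fr = (nr == 1) ? 0.0 : r - r0;
    const double fc = (nc == 1) ? 0.0 : c - c0;
    const int r1 = (nr == 1) ? r0 : r0 + 1;
    const int c1 = (nc == 1) ? c0 : c0 + 1;
    out[p] = m(r0, c0) * (1 - fr) * (1 - fc) + m(r1, c0) * fr * (1 - fc) +
             m(r0, c1) * (1 - fr) * fc + m(r1, c1) * fr * fc;
  }
  return out;
}
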