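#include <Rcpp.h>
using namespace Rcpp;

// Zero-boundary (zero-padded) 1D convolutions along each axis of a 3D array
// stored column-major with dim = (ny, nx, nz).  `flip = true` applies the
// adjoint (correlation); for symmetric kernels the two coincide.

static inline int off_of(int j, int c, bool flip) {
  int off = j - c;
  return flip ? -off : off;
}

// [[Rcpp::export]]
NumericVector conv_axis3(NumericVector arr, IntegerVector dims, NumericVector k,
                         int axis, bool flip) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  int m = k.size(), c = (m - 1) / 2;
  NumericVector out(arr.size());
  const double* pin = &arr[0];
  double* pout = &out[0];
  const double* pk = &k[0];
  size_t sy = 1, sx = (size_t)ny, sz = (size_t)ny * nx;

  if (axis == 1) {                    // along y (contiguous)
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        const double* pi = pin + z * sz + x * sx;
        double* po = pout + z * sz + x * sx;
        for (int y = 0; y < ny; ++y) {
          double s = 0.0;
          for (int j = 0; j < m; ++j) {
            int ys = y - off_of(j, c, flip);
            if (ys >= 0 && ys < ny) s += pk[j] * pi[ys];
          }
          po[y] = s;
        }
      }
  } else if (axis == 2) {             // along x: daxpy over contiguous y-columns
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        double* po = pout + z * sz + x * sx;
        for (int j = 0; j < m; ++j) {
          int xs = x - off_of(j, c, flip);
          if (xs < 0 || xs >= nx) continue;
          const double* pi = pin + z * sz + xs * sx;
          double w = pk[j];
          for (int y = 0; y < ny; ++y) po[y] += w * pi[y];
        }
      }
  } else {                            // along z
    for (int z = 0; z < nz; ++z) {
      double* po = pout + z * sz;
      for (int j = 0; j < m; ++j) {
        int zs = z - off_of(j, c, flip);
        if (zs < 0 || zs >= nz) continue;
        const double* pi = pin + zs * sz;
        double w = pk[j];
        for (size_t i = 0; i < sz; ++i) po[i] += w * pi[i];
      }
    }
  }
  return out;
}

// Direct zero-boundary 2D convolution with an arbitrary kernel (oracle path
// and non-separable psi support).
// [[Rcpp::export]]
NumericMatrix conv2_full(NumericMatrix img, NumericMatrix ker, bool flip) {
  int ny = img.nrow(), nx = img.ncol();
  int my = ker.nrow(), mx = ker.ncol();
  int cy = (my - 1) / 2, cx = (mx - 1) / 2;
  NumericMatrix out(ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double s = 0.0;
      for (int jx = 0; jx < mx; ++jx) {
        int xs = x - off_of(jx, cx, flip);
        if (xs < 0 || xs >= nx) continue;
        for (int jy = 0; jy < my; ++jy) {
          int ys = y - off_of(jy, cy, flip);
          if (ys < 0 || ys >= ny) continue;
          s += ker(jy, jx) * img(ys, xs);
        }
      }
      out(y, x) = s;
    }
  return out;
}

// 26-neighbourhood local maxima of a 3D array above `threshold`.
// Returns 1-based linear indices.
// [[Rcpp::export]]
IntegerVector local_maxima3(NumericVector arr, IntegerVector dims, double threshold) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  size_t sx = (size_t)ny, sz = (size_t)ny * nx;
  const double* p = &arr[0];
  std::vector<int> hits;
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        size_t i = y + x * sx + z * sz;
        double v = p[i];
        if (v <= threshold) continue;
        bool is_max = true;
        for (int dz = -1; dz <= 1 && is_max; ++dz) {
          int zz = z + dz; if (zz < 0 || zz >= nz) continue;
          for (int dx = -1; dx <= 1 && is_max; ++dx) {
            int xx = x + dx; if (xx < 0 || xx >= nx) continue;
            for (int dy = -1; dy <= 1; ++dy) {
              int yy = y + dy; if (yy < 0 || yy >= ny) continue;
              if (dy == 0 && dx == 0 && dz == 0) continue;
              if (p[yy + xx * sx + zz * sz] > v) { is_max = false; break; }
            }
          }
        }
        if (is_max) hits.push_back((int)i + 1);
      }
  return wrap(hits);
}
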