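#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rayleigh-Sommerfeld surface integral of a discretized radiator:
//   S(x) = sum_j area_j * exp(-(a + i k) R_j) / R_j ,  R_j = |x - e_j|
// The physical prefactor i*rho*c*k*u0/(2*pi) is applied on the R side.
// a (Np/m) is the amplitude attenuation folded into a complex wavenumber.
// [[Rcpp::export]]
ComplexVector rs_field_cpp(NumericMatrix elem, NumericVector area,
                           NumericMatrix pts, double k, double a) {
  const int n = elem.nrow(), m = pts.nrow();
  ComplexVector out(m);
  const double *ex = &elem(0, 0), *ey = &elem(0, 1), *ez = &elem(0, 2);
  const double *ar = &area[0];
  for (int i = 0; i < m; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double re = 0.0, im = 0.0;
    for (int j = 0; j < n; ++j) {
      const double dx = px - ex[j], dy = py - ey[j], dz = pz - ez[j];
      const double R = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double amp = ar[j] * std::exp(-a * R) / R;
      const double ph = -k * R;
      re += amp * std::cos(ph);
      im += amp * std::sin(ph);
    }
    out[i].r = re;
    out[i].i = im;
  }
  return out;
}

static void blur_axis(const double *src, double *dst,
                      int n0, int n1, int n2,
                      int s0, int s1, int s2,
                      const double *ker, int hw) {
  // convolve along axis 0 (stride s0) for every (i1, i2); zero outside domain
  for (int i2 = 0; i2 < n2; ++i2) {
    for (int i1 = 0; i1 < n1; ++i1) {
      const double *col = src + (size_t)i1 * s1 + (size_t)i2 * s2;
      double *out = dst + (size_t)i1 * s1 + (size_t)i2 * s2;
      for (int i0 = 0; i0 < n0; ++i0) {
        double acc = 0.0;
        const int lo = std::max(0, i0 - hw), hi = std::min(n0 - 1, i0 + hw);
        for (int j = lo; j <= hi; ++j)
          acc += ker[j - i0 + hw] * col[(size_t)j * s0];
        out[(size_t)i0 * s0] = acc;
      }
    }
  }
}

// Separable 3-D Gaussian convolution with a shared 1-D kernel (odd length),
// zero (absorbing) boundary condition. Returns a new array.
// [[Rcpp::export]]
NumericVector gauss_blur3_cpp(NumericVector arr, IntegerVector dim,
                              NumericVector kernel) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int hw = (kernel.size() - 1) / 2;
  NumericVector tmp(arr.size()), out(arr.size());
  const double *ker = &kernel[0];
  // x-pass: axis 0 stride 1, loops over (y, z)
  blur_axis(&arr[0], &out[0], nx, ny, nz, 1, nx, (size_t)nx * ny, ker, hw);
  // y-pass
  blur_axis(&out[0], &tmp[0], ny, nx, nz, nx, 1, (size_t)nx * ny, ker, hw);
  // z-pass
  blur_axis(&tmp[0], &out[0], nz, nx * ny, 1, (size_t)nx * ny, 1, 1, ker, hw);
  out.attr("dim") = dim;
  return out;
}
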