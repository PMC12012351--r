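#include <Rcpp.h>
using namespace Rcpp;

// Backproject filtered parallel-beam projections onto a square pixel grid.
// filt: n_det x n_views filtered projections; pixel (r, c) maps to
// x = (c - (n-1)/2) * dx, y = ((n-1)/2 - r) * dx (row index runs downward),
// detector coordinate s = -x sin(theta) + y cos(theta), linear interpolation
// between detector samples, zero outside the array. Along a row, s changes
// by a constant -dx sin(theta) per column, so the fractional detector index
// is advanced incrementally and the in-bounds column range solved up front.
// [[Rcpp::export]]
NumericMatrix backproject_cpp(NumericMatrix filt, NumericVector theta,
                              int n_pix, double pixel_mm, double pitch_mm) {
  const int n_det = filt.nrow(), n_views = filt.ncol();
  const double c0 = (n_pix - 1) / 2.0;
  const double det_c = (n_det + 1) / 2.0;  // 1-based centre index
  NumericMatrix img(n_pix, n_pix);
  double *im = img.begin();
  for (int v = 0; v < n_views; ++v) {
    const double st = std::sin(theta[v]), ct = std::cos(theta[v]);
    const double du = -pixel_mm * st / pitch_mm;     // index step per column
    const double *col = &filt(0, v);
    for (int r = 0; r < n_pix; ++r) {
      const double y = (c0 - r) * pixel_mm;
      // u at column 0
      double u0 = (y * ct + c0 * pixel_mm * st) / pitch_mm + det_c;
      // columns with 1 <= u < n_det
      int clo = 0, chi = n_pix - 1;
      if (du > 1e-12) {
        clo = (int)std::ceil((1.0 - u0) / du);
        chi = (int)std::floor((n_det - 1e-9 - u0) / du);
      } else if (du < -1e-12) {
        clo = (int)std::ceil((n_det - 1e-9 - u0) / du);
        chi = (int)std::floor((1.0 - u0) / du);
      } else if (u0 < 1.0 || u0 >= n_det) {
        continue;
      }
      if (clo < 0) clo = 0;
      if (chi > n_pix - 1) chi = n_pix - 1;
      if (clo > chi) continue;
      double u = u0 + clo * du;
      double *row = im + r;  // column-major: element (r, c) = im[r + c*n_pix]
      for (int c = clo; c <= chi; ++c, u += du) {
        const int i0 = (int)u;
        const double w = u - i0;
        row[(size_t)c * n_pix] += (1.0 - w) * col[i0 - 1] + w * col[i0];
      }
    }
  }
  const double scale = M_PI / n_views;
  for (size_t k = 0; k < (size_t)n_pix * n_pix; ++k) im[k] *= scale;
  return img;
}

// Pixel-driven (splat) forward projection: adjoint-style accumulation of
// image values into detector bins with linear interpolation weights, scaled
// by pixel area / detector pitch so the result approximates line integrals
// in cm of the image quantity. Adequate for smooth correction terms.
// [[Rcpp::export]]
NumericMatrix forwardproject_cpp(NumericMatrix img, NumericVector theta,
                                 int n_det, double pitch_mm,
                                 double pixel_mm) {
  const int n_pix = img.nrow(), n_views = theta.size();
  const double c0 = (n_pix - 1) / 2.0;
  const double det_c = (n_det + 1) / 2.0;
  const double scale = (pixel_mm / 10.0) * (pixel_mm / 10.0) /
                       (pitch_mm / 10.0);
  NumericMatrix out(n_det, n_views);
  const double *im = img.begin();
  for (int v = 0; v < n_views; ++v) {
    const double st = std::sin(theta[v]), ct = std::cos(theta[v]);
    const double du = -pixel_mm * st / pitch_mm;
    double *col = &out(0, v);
    for (int r = 0; r < n_pix; ++r) {
      const double y = (c0 - r) * pixel_mm;
      double u = (y * ct + c0 * pixel_mm * st) / pitch_mm + det_c;
      const double *row = im + r;
      for (int c = 0; c < n_pix; ++c, u += du) {
        const double val = row[(size_t)c * n_pix];
        if (val == 0.0) continue;
        const int i0 = (int)std::floor(u);
        if (i0 < 1 || i0 >= n_det) continue;
        const double w = u - i0;
        col[i0 - 1] += (1.0 - w) * val;
        col[i0] += w * val;
      }
    }
  }
  for (size_t k = 0; k < (size_t)n_det * n_views; ++k) out.begin()[k] *= scale;
  return out;
}
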