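#include <Rcpp.h>
using namespace Rcpp;

// Bilinear interpolation of a grayscale image at fractional positions.
// Coordinates are 0-based with pixel centres at integer positions:
// x indexes columns, y indexes rows. Positions outside the image are
// clamped to the border (the caller decides whether to flag them).
// [[Rcpp::export]]
NumericVector cpp_bilinear(const NumericMatrix& img, const NumericVector& x,
                           const NumericVector& y) {
  const int nr = img.nrow(), nc = img.ncol();
  const int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i], yi = y[i];
    if (xi < 0) xi = 0;
    if (xi > nc - 1) xi = nc - 1;
    if (yi < 0) yi = 0;
    if (yi > nr - 1) yi = nr - 1;
    int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi);
    if (x0 > nc - 2) x0 = nc - 2;
    if (y0 > nr - 2) y0 = nr - 2;
    if (x0 < 0) x0 = 0;
    if (y0 < 0) y0 = 0;
    double fx = xi - x0, fy = yi - y0;
    double i00 = img(y0, x0), i01 = img(y0, x0 + 1);
    double i10 = img(y0 + 1, x0), i11 = img(y0 + 1, x0 + 1);
    out[i] = i00 * (1 - fx) * (1 - fy) + i01 * fx * (1 - fy) +
             i10 * (1 - fx) * fy + i11 * fx * fy;
  }
  return out;
}

// Accumulate, in place, the squared distance from each pixel centre to the
// nearest of a set of polyline sample points, limited to a square
// neighbourhood of half-width `radius` pixels around each sample.
// d2 must be initialised by the caller (typically to +Inf).
// [[Rcpp::export]]
void cpp_accum_dist2(NumericMatrix d2, const NumericVector& px,
                     const NumericVector& py, const double radius) {
  const int nr = d2.nrow(), nc = d2.ncol();
  const int n = px.size();
  const int r = (int)std::ceil(radius);
  for (int i = 0; i < n; ++i) {
    const double cx = px[i], cy = py[i];
    int x0 = (int)std::floor(cx) - r, x1 = (int)std::ceil(cx) + r;
    int y0 = (int)std::floor(cy) - r, y1 = (int)std::ceil(cy) + r;
    if (x0 < 0) x0 = 0;
    if (y0 < 0) y0 = 0;
    if (x1 > nc - 1) x1 = nc - 1;
    if (y1 > nr - 1) y1 = nr - 1;
    for (int xx = x0; xx <= x1; ++xx) {
      const double dx = xx - cx;
      for (int yy = y0; yy <= y1; ++yy) {
        const double dy = yy - cy;
        const double d = dx * dx + dy * dy;
        if (d < d2(yy, xx)) d2(yy, xx) = d;
      }
    }
  }
}
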