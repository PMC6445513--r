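#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Accumulate gradient-orientation lines into a vote image. For each seed
// pixel (xs, ys) a segment is rasterized from -r_max to +r_max steps of
// (dx, dy), where max(|dx|, |dy|) == 1 so every step lands on a distinct
// pixel. Rounding matches R's round() (half to even) so the R reference
// implementation of the rasterizer agrees exactly.
// [[Rcpp::export]]
NumericMatrix line_accumulate(IntegerVector xs, IntegerVector ys,
                              NumericVector dx, NumericVector dy,
                              int r_max, int nr, int nc) {
  NumericMatrix acc(nr, nc);
  R_xlen_t n = xs.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    double x0 = xs[i], y0 = ys[i], ddx = dx[i], ddy = dy[i];
    for (int t = -r_max; t <= r_max; ++t) {
      int xi = (int) std::nearbyint(x0 + t * ddx);
      int yi = (int) std::nearbyint(y0 + t * ddy);
      if (xi >= 1 && xi <= nc && yi >= 1 && yi <= nr)
        acc(yi - 1, xi - 1) += 1.0;
    }
  }
  return acc;
}

// Bilinear sampling of 'img' at (ox[k] + xs[j], oy[k] + ys[j]) for all
// offsets k and centers j. Out-of-bounds points get value 0 and flag FALSE.
// The interpolation formula mirrors the package's R reference bilinear
// sampler term for term, so both paths agree to the last bit.
// [[Rcpp::export]]
List sample_block(NumericMatrix img, IntegerVector xs, IntegerVector ys,
                  NumericVector ox, NumericVector oy) {
  int nr = img.nrow(), nc = img.ncol();
  R_xlen_t K = ox.size(), C = xs.size();
  NumericMatrix values(K, C);
  LogicalMatrix inbounds(K, C);
  const double *im = img.begin();
  for (R_xlen_t j = 0; j < C; ++j) {
    double xc0 = xs[j], yc0 = ys[j];
    for (R_xlen_t k = 0; k < K; ++k) {
      double x = xc0 + ox[k];
      double y = yc0 + oy[k];
      bool inb = (x >= 1.0 && x <= nc && y >= 1.0 && y <= nr);
      if (!inb) {
        values(k, j) = 0.0;
        inbounds(k, j) = FALSE;
        continue;
      }
      double xcl = x < 1.0 ? 1.0 : (x > nc ? nc : x);
      double ycl = y < 1.0 ? 1.0 : (y > nr ? nr : y);
      double x1 = std::floor(xcl); if (x1 > nc - 1) x1 = nc - 1;
      double y1 = std::floor(ycl); if (y1 > nr - 1) y1 = nr - 1;
      double fx = xcl - x1, fy = ycl - y1;
      R_xlen_t i11 = (R_xlen_t)(x1 - 1) * nr + (R_xlen_t)(y1 - 1);
      double v = (1 - fx) * (1 - fy) * im[i11]
               + fx * (1 - fy) * im[i11 + nr]
               + (1 - fx) * fy * im[i11 + 1]
               + fx * fy * im[i11 + nr + 1];
      values(k, j) = v;
      inbounds(k, j) = TRUE;
    }
  }
  return List::create(_["values"] = values, _["inbounds"] = inbounds);
}
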