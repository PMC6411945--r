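#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Grayscale opening of an image by a non-flat ball structuring element.
// The ball has radius r in the pixel plane and a spherical-cap height
// profile h(u) = sqrt(r^2 - |u|^2) in intensity units (1:1 scaling).
// Offsets falling outside the image are ignored (erosion treats them as
// +Inf, dilation as -Inf), so a constant image opens to itself exactly.
// [[Rcpp::export]]
NumericMatrix ball_opening_cpp(NumericMatrix img, double radius) {
  const int nr = img.nrow(), nc = img.ncol();
  const int r = (int)std::floor(radius);
  std::vector<int> du, dv;
  std::vector<double> h;
  const double r2 = radius * radius;
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b) {
      double d2 = (double)a * a + (double)b * b;
      if (d2 <= r2) {
        du.push_back(a);
        dv.push_back(b);
        h.push_back(std::sqrt(r2 - d2));
      }
    }
  const int K = (int)du.size();
  NumericMatrix ero(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double m = R_PosInf;
      for (int k = 0; k < K; ++k) {
        int ii = i + du[k], jj = j + dv[k];
        if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
        double v = img(ii, jj) - h[k];
        if (v < m) m = v;
      }
      ero(i, j) = m;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        int ii = i + du[k], jj = j + dv[k];
        if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
        double v = ero(ii, jj) + h[k];
        if (v > m) m = v;
      }
      out(i, j) = m;
    }
  return out;
}
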