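#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian convolution with a kernel truncated at 4 sigma and
// renormalised; out-of-image samples are treated as zero (the scene is
// empty outside the padded cell footprint).
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  const int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double ksum = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    ksum += k[i + r];
  }
  for (double &v : k) v /= ksum;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // vertical pass: shifted-column accumulation, contiguous in memory
  for (int j = 0; j < nc; ++j) {
    const double *src = &img(0, j);
    double *dst = &tmp(0, j);
    for (int d = -r; d <= r; ++d) {
      const double w = k[d + r];
      const int i0 = std::max(0, -d), i1 = std::min(nr, nr - d);
      for (int i = i0; i < i1; ++i) dst[i] += w * src[i + d];
    }
  }
  // horizontal pass: accumulate weighted neighbouring columns
  for (int j = 0; j < nc; ++j) {
    double *dst = &out(0, j);
    const int lo = std::max(-r, -j), hi = std::min(r, nc - 1 - j);
    for (int d = lo; d <= hi; ++d) {
      const double w = k[d + r];
      const double *src = &tmp(0, j + d);
      for (int i = 0; i < nr; ++i) dst[i] += w * src[i];
    }
  }
  return out;
}
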