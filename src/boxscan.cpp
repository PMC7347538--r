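#include <Rcpp.h>
using namespace Rcpp;

// Box-scan local-maximum detector.
//
// A pixel p is accepted when the box of side 2*half+1 centred on p lies
// fully inside the image and p is the first pixel, in row-major order
// (row, then column), attaining the maximum of that box. "First" rather
// than "unique" makes plateau maxima deterministic: the top-left pixel of
// an equal-valued plateau represents it. The corner gate then requires
// value(p) - mean(four box corners) > tol.
//
// Returns one row per accepted pixel with 1-based (row, col).
// [[Rcpp::export]]
DataFrame cpp_box_scan(NumericMatrix img, int half, double tol) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> rows, cols;
  std::vector<double> peaks, corners;
  for (int i = half; i < nr - half; ++i) {
    for (int j = half; j < nc - half; ++j) {
      const double v = img(i, j);
      // accepted iff, scanning the window in row-major order, no pixel
      // before p reaches v and no pixel after p exceeds v
      bool ok = true;
      for (int di = -half; di <= half && ok; ++di) {
        for (int dj = -half; dj <= half; ++dj) {
          if (di == 0 && dj == 0) continue;
          const double w = img(i + di, j + dj);
          const bool beforeP = (di < 0) || (di == 0 && dj < 0);
          if (w > v || (beforeP && w == v)) { ok = false; break; }
        }
      }
      if (!ok) continue;
      const double cm = (img(i - half, j - half) + img(i - half, j + half) +
                         img(i + half, j - half) + img(i + half, j + half)) / 4.0;
      if (v - cm > tol) {
        rows.push_back(i + 1);
        cols.push_back(j + 1);
        peaks.push_back(v);
        corners.push_back(cm);
      }
    }
  }
  return DataFrame::create(_["row"] = rows, _["col"] = cols,
                           _["peak"] = peaks, _["corner_mean"] = corners);
}
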