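#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Seeded threshold region growth with nearest-seed splitting.
//
// The cluster of seed s is the 8-connected component, containing s, of
// in-mask pixels with intensity >= thr[s] that lie in s's nearest-seed
// (Voronoi) cell. Restricting every pixel to its nearest seed is the
// nearest-seed contest rule applied uniformly: it splits bright regions
// holding two seeds along their bisector and prevents a weak seed's low
// border threshold from annexing a stronger neighbour's shoulder.
// Distance ties go to the stronger peak, then to the lower seed index.
// Regions of different seeds are disjoint and connected by construction.
//
// Returns an integer label matrix (0 = unassigned, k = seed k, 1-based).
// [[Rcpp::export]]
IntegerMatrix cpp_grow_regions(NumericMatrix img, LogicalMatrix mask,
                               IntegerVector seedRow, IntegerVector seedCol,
                               NumericVector thr, NumericVector peak) {
  const int nr = img.nrow(), nc = img.ncol();
  const int ns = seedRow.size();
  const R_xlen_t npx = (R_xlen_t)nr * nc;
  IntegerMatrix lab(nr, nc);
  std::vector<int> stamp(npx, 0);
  std::vector<R_xlen_t> q;

  // bucket grid over seed positions for nearest-other-seed queries
  const int B = 16;
  const int nby = (nr + B - 1) / B, nbx = (nc + B - 1) / B;
  std::vector<std::vector<int>> buck((size_t)nby * nbx);
  for (int s = 0; s < ns; ++s) {
    const int br = (seedRow[s] - 1) / B, bc = (seedCol[s] - 1) / B;
    buck[(size_t)bc * nby + br].push_back(s);
  }
  // true when some other seed is closer to (qr, qc) than seed s at d2s
  // (or equally close with a stronger peak / lower index)
  auto blocked = [&](int qr, int qc, int s, double d2s) -> bool {
    const int rad = (int)std::ceil(std::sqrt(d2s));
    const int b0r = std::max(0, (qr - rad) / B);
    const int b1r = std::min(nby - 1, (qr + rad) / B);
    const int b0c = std::max(0, (qc - rad) / B);
    const int b1c = std::min(nbx - 1, (qc + rad) / B);
    for (int bc = b0c; bc <= b1c; ++bc)
      for (int br = b0r; br <= b1r; ++br)
        for (int t : buck[(size_t)bc * nby + br]) {
          if (t == s) continue;
          const double dr = qr - (seedRow[t] - 1);
          const double dc = qc - (seedCol[t] - 1);
          const double d2t = dr * dr + dc * dc;
          if (d2t < d2s ||
              (d2t == d2s && (peak[t] > peak[s] ||
                              (peak[t] == peak[s] && t < s))))
            return true;
        }
    return false;
  };

  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int s = 0; s < ns; ++s) {
    const int r0 = seedRow[s] - 1, c0 = seedCol[s] - 1;
    const double t = thr[s];
    const R_xlen_t start = (R_xlen_t)c0 * nr + r0;
    if (!mask[start] || img[start] < t) continue;
    if (blocked(r0, c0, s, 0.0)) continue;  // duplicate seed position
    q.clear();
    stamp[start] = s + 1;
    q.push_back(start);
    lab[start] = s + 1;
    for (size_t h = 0; h < q.size(); ++h) {
      const R_xlen_t p = q[h];
      const int pr = (int)(p % nr), pc = (int)(p / nr);
      for (int k = 0; k < 8; ++k) {
        const int qr = pr + dr8[k], qc = pc + dc8[k];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        const R_xlen_t pq = (R_xlen_t)qc * nr + qr;
        if (stamp[pq] == s + 1) continue;
        stamp[pq] = s + 1;
        if (!mask[pq] || img[pq] < t) continue;
        const double ddr = qr - r0, ddc = qc - c0;
        if (blocked(qr, qc, s, ddr * ddr + ddc * ddc)) continue;
        lab[pq] = s + 1;
        q.push_back(pq);
      }
    }
  }
  return lab;
}
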