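#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <deque>
using namespace Rcpp;

// 2-D median filter with odd square kernel and reflected borders.
// Non-finite values are excluded from each window; a window with no finite
// neighbour yields NA. Pixels that are NA on input stay NA on output (the
// caller re-masks, but we honour it here too so maps keep their undefined set).
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix x, int k) {
  if (k < 1 || k % 2 == 0) stop("kernel size must be a positive odd integer");
  int nr = x.nrow(), nc = x.ncol(), h = k / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)k * k);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!R_finite(x(i, j))) { out(i, j) = NA_REAL; continue; }
      buf.clear();
      for (int dj = -h; dj <= h; ++dj) {
        for (int di = -h; di <= h; ++di) {
          int ii = i + di, jj = j + dj;
          // reflect about the edge (a b c | b a -> indices mirrored)
          if (ii < 0) ii = -ii;
          if (ii >= nr) ii = 2 * nr - 2 - ii;
          if (jj < 0) jj = -jj;
          if (jj >= nc) jj = 2 * nc - 2 - jj;
          double v = x(ii, jj);
          if (R_finite(v)) buf.push_back(v);
        }
      }
      if (buf.empty()) { out(i, j) = NA_REAL; continue; }
      size_t m = buf.size();
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
      double med = buf[m / 2];
      if (m % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + m / 2);
        med = 0.5 * (med + lo);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Connected-component labeling of a logical matrix under 4- or 8-connectivity.
// Returns an integer matrix: 0 for background, 1..K for components.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc); // zero-initialised
  int next = 0;
  const int d4r[] = {-1, 1, 0, 0}, d4c[] = {0, 0, -1, 1};
  const int d8r[] = {-1, 1, 0, 0, -1, -1, 1, 1}, d8c[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = (connectivity == 4) ? d4r : d8r;
  const int *dc = (connectivity == 4) ? d4c : d8c;
  int nd = (connectivity == 4) ? 4 : 8;
  std::deque<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.clear();
      q.push_back(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop_front();
        for (int d = 0; d < nd; ++d) {
          int ii = p.first + dr[d], jj = p.second + dc[d];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push_back(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}
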