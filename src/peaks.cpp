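// Prominence-based peak detection on long magnitude series. Prominence is
// measured by walking outwards from each local maximum to the nearest
// strictly higher sample (optionally capped at wlen samples per side, the
// relevant notion when only short-span events matter) and taking the height
// above the higher of the two en-route minima. A greedy pass keeps the
// highest peaks subject to a minimum separation.
#include <Rcpp.h>
#include <algorithm>
#include <vector>

// [[Rcpp::export(name = ".find_peaks_cpp")]]
Rcpp::IntegerVector find_peaks_cpp(Rcpp::NumericVector x, double prominence,
                                   int min_dist, int wlen) {
  const R_xlen_t n = x.size();
  std::vector<R_xlen_t> cand;
  for (R_xlen_t i = 1; i + 1 < n; ++i)
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) cand.push_back(i);

  std::vector<R_xlen_t> keep;
  for (R_xlen_t p : cand) {
    const double h = x[p];
    const R_xlen_t lo = (wlen > 0) ? std::max<R_xlen_t>(0, p - wlen) : 0;
    const R_xlen_t hi = (wlen > 0) ? std::min<R_xlen_t>(n - 1, p + wlen) : n - 1;
    double lmin = h, rmin = h;
    for (R_xlen_t i = p; i > lo && x[i] <= h;) {
      --i;
      lmin = std::min(lmin, x[i]);
    }
    for (R_xlen_t i = p; i < hi && x[i] <= h;) {
      ++i;
      rmin = std::min(rmin, x[i]);
    }
    if (h - std::max(lmin, rmin) >= prominence) keep.push_back(p);
  }
  if (keep.empty()) return Rcpp::IntegerVector(0);

  // greedy minimum-separation: highest first, ties to the earlier peak
  std::vector<R_xlen_t> order(keep.size());
  for (size_t k = 0; k < keep.size(); ++k) order[k] = k;
  std::stable_sort(order.begin(), order.end(), [&](R_xlen_t a, R_xlen_t b) {
    return x[keep[a]] > x[keep[b]];
  });
  std::vector<char> suppressed(keep.size(), 0);
  std::vector<R_xlen_t> out;
  for (R_xlen_t k : order) {
    if (suppressed[k]) continue;
    out.push_back(keep[k]);
    // keep[] is position-sorted: suppress the contiguous range within min_dist
    auto lo_it = std::lower_bound(keep.begin(), keep.end(),
                                  keep[k] - min_dist + 1);
    auto hi_it = std::upper_bound(keep.begin(), keep.end(),
                                  keep[k] + min_dist - 1);
    for (auto it = lo_it; it != hi_it; ++it)
      suppressed[it - keep.begin()] = 1;
    suppressed[k] = 1;
  }
  std::sort(out.begin(), out.end());
  Rcpp::IntegerVector res(out.size());
  for (size_t k = 0; k < out.size(); ++k) res[k] = int(out[k]) + 1;  // 1-based
  return res;
}
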