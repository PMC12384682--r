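#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Batch pre-survey window features for one modality over a regular sensor grid.
//
// series:     n_ticks x n_rooms fused room series; row r holds grid time
//             (r-1)*period; NA columns = sensorless room
// seg_*:      occupancy segments, sorted by survey then chronologically;
//             seg_col is the 1-based column of the room's series, 0 when the
//             segment contributes no data (off map / sensorless)
// Segments are half-open [start, end): a reading at exactly `start` belongs
// to the segment, one at `end` does not.
// A trailing moving average over (t - span, t] is applied to the concatenated
// series before the descriptive features are computed.
//
// Returns n_surveys x 6: min, max, mean, median, sd (n-1), n_points.
// [[Rcpp::export(name = ".window_features_batch")]]
NumericMatrix window_features_batch(NumericMatrix series,
                                    IntegerVector seg_survey,
                                    IntegerVector seg_col,
                                    NumericVector seg_start,
                                    NumericVector seg_end,
                                    int n_surveys, double period, double span) {
  const int n_ticks = series.nrow();
  const int n_seg = seg_survey.size();
  NumericMatrix out(n_surveys, 6);
  for (int s = 0; s < n_surveys; ++s) {
    for (int j = 0; j < 5; ++j) out(s, j) = NA_REAL;
    out(s, 5) = 0.0;
  }
  std::vector<double> tm, vv, sm;
  int i = 0;
  while (i < n_seg) {
    const int sid = seg_survey[i];
    tm.clear(); vv.clear();
    while (i < n_seg && seg_survey[i] == sid) {
      const int col = seg_col[i];
      if (col > 0) {
        // grid ticks with start <= t < end
        int i0 = (int)std::ceil(seg_start[i] / period - 1e-9);
        int i1 = (int)std::ceil(seg_end[i] / period - 1e-9) - 1;
        if (i0 < 0) i0 = 0;
        if (i1 > n_ticks - 1) i1 = n_ticks - 1;
        for (int t = i0; t <= i1; ++t) {
          double v = series(t, col - 1);
          if (!NumericMatrix::is_na(v)) {
            tm.push_back(t * period);
            vv.push_back(v);
          }
        }
      }
      ++i;
    }
    const int n = (int)vv.size();
    out(sid - 1, 5) = n;
    if (n == 0) continue;
    // trailing moving average over (t - span, t]
    sm.resize(n);
    double run = 0.0;
    int lo = 0;
    for (int k = 0; k < n; ++k) {
      run += vv[k];
      while (tm[lo] <= tm[k] - span) { run -= vv[lo]; ++lo; }
      sm[k] = run / (k - lo + 1);
    }
    double mn = sm[0], mx = sm[0], sum = 0.0;
    for (int k = 0; k < n; ++k) {
      if (sm[k] < mn) mn = sm[k];
      if (sm[k] > mx) mx = sm[k];
      sum += sm[k];
    }
    const double mean = sum / n;
    double ss = 0.0;
    for (int k = 0; k < n; ++k) ss += (sm[k] - mean) * (sm[k] - mean);
    const double sd = (n > 1) ? std::sqrt(ss / (n - 1)) : NA_REAL;
    std::vector<double> srt(sm.begin(), sm.end());
    std::sort(srt.begin(), srt.end());
    const double med = (n % 2 == 1) ? srt[n / 2]
                                    : 0.5 * (srt[n / 2 - 1] + srt[n / 2]);
    out(sid - 1, 0) = mn;
    out(sid - 1, 1) = mx;
    out(sid - 1, 2) = mean;
    out(sid - 1, 3) = med;
    out(sid - 1, 4) = sd;
  }
  return out;
}
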