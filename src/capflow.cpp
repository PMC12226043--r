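#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter, a[0] assumed 1 (normalized upstream).
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int k = 0; k < nz - 1; ++k)
      z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return y;
}

// Group threshold crossings into events. Candidates are local maxima of
// |x| above the per-sample threshold; a candidate joins the current event
// while it lies within `gap` samples of the event's running extremum,
// otherwise it opens a new event. Each event is aligned at its absolute
// extremum (earliest sample wins ties). Returns 1-based indices.
// [[Rcpp::export]]
IntegerVector detect_events_cpp(NumericVector x, NumericVector thr, int gap) {
  int n = x.size();
  std::vector<int> out;
  bool in_ev = false;
  int best = -1;
  double best_val = -1.0;
  for (int i = 0; i < n; ++i) {
    double ax = std::fabs(x[i]);
    if (!(ax > thr[i])) continue;
    double prev = i > 0 ? std::fabs(x[i - 1]) : -1.0;
    double next = i < n - 1 ? std::fabs(x[i + 1]) : -1.0;
    if (!(ax >= prev && ax >= next)) continue;  // not a local peak
    if (in_ev && (i - best) > gap) {
      out.push_back(best + 1);
      in_ev = false;
    }
    if (!in_ev) { in_ev = true; best = i; best_val = ax; }
    else if (ax > best_val) { best = i; best_val = ax; }
  }
  if (in_ev) out.push_back(best + 1);
  return wrap(out);
}

// Per-chunk median of |x| computed separately for mask-true and mask-false
// samples. Returns a K x 2 matrix (col 1: mask true, col 2: false), NA where
// a chunk holds no samples of that regime.
// [[Rcpp::export]]
NumericMatrix chunk_median_abs_cpp(NumericVector x, LogicalVector mask, int chunk_len) {
  int n = x.size();
  int k = (n + chunk_len - 1) / chunk_len;
  NumericMatrix out(k, 2);
  std::vector<double> buf_t, buf_f;
  buf_t.reserve(chunk_len); buf_f.reserve(chunk_len);
  for (int c = 0; c < k; ++c) {
    buf_t.clear(); buf_f.clear();
    int lo = c * chunk_len, hi = std::min(n, lo + chunk_len);
    for (int i = lo; i < hi; ++i) {
      if (mask[i]) buf_t.push_back(std::fabs(x[i]));
      else buf_f.push_back(std::fabs(x[i]));
    }
    for (int s = 0; s < 2; ++s) {
      std::vector<double>& b = s == 0 ? buf_t : buf_f;
      if (b.empty()) { out(c, s) = NA_REAL; continue; }
      size_t m = b.size() / 2;
      std::nth_element(b.begin(), b.begin() + m, b.end());
      double med = b[m];
      if (b.size() % 2 == 0) {
        double lo2 = *std::max_element(b.begin(), b.begin() + m);
        med = 0.5 * (med + lo2);
      }
      out(c, s) = med;
    }
  }
  return out;
}

// Accumulate a template waveform into x at each center (1-based sample of the
// template's alignment point). Safe under overlapping placements.
// [[Rcpp::export]]
NumericVector add_template_cpp(NumericVector x, IntegerVector centers,
                               NumericVector tmpl, int align) {
  int n = x.size(), m = tmpl.size();
  NumericVector y = clone(x);
  for (int e = 0; e < centers.size(); ++e) {
    int start = centers[e] - 1 - (align - 1);
    for (int j = 0; j < m; ++j) {
      int idx = start + j;
      if (idx >= 0 && idx < n) y[idx] += tmpl[j];
    }
  }
  return y;
}
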