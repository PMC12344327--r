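#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Centered running median that skips missing values. The window shrinks at
// the edges of the recording. A missing sample stays missing; a non-missing
// sample is replaced by the median of the non-missing values inside its
// window (which always includes itself).
// [[Rcpp::export]]
NumericVector median_filter_cpp(NumericVector x, int window) {
  if (window < 3 || window % 2 == 0)
    stop("window must be an odd integer >= 3");
  int n = x.size();
  int h = (window - 1) / 2;
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(window);
  for (int i = 0; i < n; ++i) {
    if (NumericVector::is_na(x[i])) {
      out[i] = NA_REAL;
      continue;
    }
    int lo = std::max(0, i - h);
    int hi = std::min(n - 1, i + h);
    buf.clear();
    for (int j = lo; j <= hi; ++j)
      if (!NumericVector::is_na(x[j])) buf.push_back(x[j]);
    size_t m = buf.size();
    size_t mid = m / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double med = buf[mid];
    if (m % 2 == 0) {
      double lower = *std::max_element(buf.begin(), buf.begin() + mid);
      med = (med + lower) / 2.0;
    }
    out[i] = med;
  }
  return out;
}
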