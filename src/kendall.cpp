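// Kendall tau-b by Knight's O(n log n) algorithm:
// sort by (x, y), count exchanges of y with a merge sort, correct for ties.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// counts pairs (i < j) with y[i] > y[j] via bottom-up merge sort
static double count_exchanges(std::vector<double>& y) {
  size_t n = y.size();
  std::vector<double> buf(n);
  double swaps = 0.0;
  for (size_t width = 1; width < n; width *= 2) {
    for (size_t lo = 0; lo < n; lo += 2 * width) {
      size_t mid = std::min(lo + width, n), hi = std::min(lo + 2 * width, n);
      size_t i = lo, j = mid, k = lo;
      while (i < mid && j < hi) {
        if (y[j] < y[i]) {          // strict: equal values are not exchanges
          swaps += (double)(mid - i);
          buf[k++] = y[j++];
        } else {
          buf[k++] = y[i++];
        }
      }
      while (i < mid) buf[k++] = y[i++];
      while (j < hi) buf[k++] = y[j++];
    }
    std::copy(buf.begin(), buf.end(), y.begin());
  }
  return swaps;
}

static double tie_pairs(const std::vector<double>& v) {
  double t = 0.0;
  size_t i = 0, n = v.size();
  while (i < n) {
    size_t j = i;
    while (j < n && v[j] == v[i]) ++j;
    double m = (double)(j - i);
    t += m * (m - 1.0) / 2.0;
    i = j;
  }
  return t;
}

// [[Rcpp::export]]
double kendall_tau_cpp(NumericVector xr, NumericVector yr) {
  R_xlen_t n = xr.size();
  if (yr.size() != n) stop("x and y must have equal length");
  if (n < 2) stop("need at least two observations");

  std::vector<size_t> ord(n);
  for (R_xlen_t i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (xr[a] != xr[b]) return xr[a] < xr[b];
    return yr[a] < yr[b];
  });

  std::vector<double> xs(n), ys(n);
  for (R_xlen_t i = 0; i < n; ++i) { xs[i] = xr[ord[i]]; ys[i] = yr[ord[i]]; }

  // joint ties and x ties on the sorted sequence
  double n3 = 0.0, n1 = 0.0;
  {
    size_t i = 0, N = (size_t)n;
    while (i < N) {
      size_t j = i;
      while (j < N && xs[j] == xs[i]) ++j;
      double m = (double)(j - i);
      n1 += m * (m - 1.0) / 2.0;
      size_t a = i;
      while (a < j) {
        size_t b = a;
        while (b < j && ys[b] == ys[a]) ++b;
        double mm = (double)(b - a);
        n3 += mm * (mm - 1.0) / 2.0;
        a = b;
      }
      i = j;
    }
  }

  double swaps = count_exchanges(ys);  // ys now sorted
  double n2 = tie_pairs(ys);

  double n0 = (double)n * ((double)n - 1.0) / 2.0;
  double num = n0 - n1 - n2 + n3 - 2.0 * swaps;
  double den = std::sqrt((n0 - n1) * (n0 - n2));
  if (den == 0.0) stop("Kendall tau undefined: a variable is constant");
  return num / den;
}
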