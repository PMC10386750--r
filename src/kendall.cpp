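#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sum of t(t-1)/2 over tie groups of a sorted vector.
static double tie_term(const std::vector<double>& v) {
  double s = 0.0;
  size_t i = 0, n = v.size();
  while (i < n) {
    size_t j = i;
    while (j < n && v[j] == v[i]) ++j;
    double t = (double)(j - i);
    s += t * (t - 1.0) / 2.0;
    i = j;
  }
  return s;
}

// Kendall tau-b via Knight's O(n log n) algorithm:
//   tau_b = (n0 - n1 - n2 + n3 - 2 swaps) / sqrt((n0 - n1) (n0 - n2))
// with n0 = n(n-1)/2, n1/n2 the x/y tie terms, n3 the both-tied term, and
// `swaps` the strict inversions of y after sorting by (x, y), counted by
// merge sort.
// [[Rcpp::export]]
double kendall_tau_b_cpp(NumericVector x, NumericVector y) {
  size_t n = (size_t)x.size();
  if (n < 2) return NA_REAL;
  std::vector<size_t> idx(n);
  for (size_t i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](size_t a, size_t b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });
  std::vector<double> ys(n);
  for (size_t i = 0; i < n; ++i) ys[i] = y[idx[i]];

  // x-tie term n1 and both-tied term n3 over x-tie groups (y sorted inside)
  double n1 = 0.0, n3 = 0.0;
  size_t i = 0;
  while (i < n) {
    size_t j = i;
    while (j < n && x[idx[j]] == x[idx[i]]) ++j;
    double t = (double)(j - i);
    n1 += t * (t - 1.0) / 2.0;
    size_t a = i;
    while (a < j) {
      size_t b = a;
      while (b < j && ys[b] == ys[a]) ++b;
      double u = (double)(b - a);
      n3 += u * (u - 1.0) / 2.0;
      a = b;
    }
    i = j;
  }

  // strict inversions of ys by bottom-up merge sort
  std::vector<double> arr(ys), buf(n);
  double swaps = 0.0;
  for (size_t width = 1; width < n; width *= 2) {
    for (size_t lo = 0; lo < n; lo += 2 * width) {
      size_t mid = std::min(lo + width, n), hi = std::min(lo + 2 * width, n);
      size_t a = lo, b = mid, k = lo;
      while (a < mid && b < hi) {
        if (arr[b] < arr[a]) {
          buf[k++] = arr[b++];
          swaps += (double)(mid - a);
        } else {
          buf[k++] = arr[a++];
        }
      }
      while (a < mid) buf[k++] = arr[a++];
      while (b < hi) buf[k++] = arr[b++];
    }
    std::swap(arr, buf);
  }

  std::vector<double> ysort(y.begin(), y.end());
  std::sort(ysort.begin(), ysort.end());
  double n2 = tie_term(ysort);

  double n0 = (double)n * ((double)n - 1.0) / 2.0;
  double den = std::sqrt((n0 - n1) * (n0 - n2));
  if (den == 0.0) return NA_REAL;
  return (n0 - n1 - n2 + n3 - 2.0 * swaps) / den;
}
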