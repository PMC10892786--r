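#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Sample entropy template counts: B = pairs of length-m templates within
// Chebyshev distance r, A = same at length m+1, over the first n-m start
// points, self-matches excluded. Returns c(A, B).
// [[Rcpp::export(name = ".sampenCounts")]]
NumericVector sampenCounts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m; // number of templates (both lengths use these starts)
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      if (i + m < n && j + m < n && std::fabs(x[i + m] - x[j + m]) <= r)
        A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}

// LZ76 complexity (Kaspar-Schuster exhaustive-history parsing) of an
// integer symbol sequence: number of words in the parsing.
// [[Rcpp::export(name = ".lz76Complexity")]]
int lz76Complexity(IntegerVector s) {
  const int n = s.size();
  if (n == 0) return 0;
  if (n == 1) return 1;
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
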