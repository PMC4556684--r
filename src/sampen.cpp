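#include <Rcpp.h>
#include <algorithm>
#include <numeric>

using namespace Rcpp;

// Template match counts for sample entropy.
//
// Templates of length m start at positions 0..N-m-1 (so that every template
// can be extended by one sample). B counts unordered pairs (i, j), i != j,
// whose m-length templates match under the Chebyshev distance with strict
// inequality (< tol); A counts the subset that still match when extended to
// length m + 1. SampEn = -log(A / B).
//
// Counting is box-assisted: template start positions are sorted by their
// first sample value, so only pairs already matching on coordinate 0 are
// inspected (a two-pointer sweep over the sorted order). This prunes the
// O(N^2) pair space by the first-coordinate match probability, which for
// r = 0.15 keeps 24-hour coarse-grained series well inside a second.
//
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double tol) {
  const int n = x.size();
  if (m < 1) stop("pattern length m must be >= 1");
  if (!(tol > 0)) stop("tolerance must be > 0");
  if (n < m + 2) stop("series too short for pattern length m");

  const int nt = n - m;  // number of templates
  std::vector<int> ord(nt);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });

  double A = 0.0, B = 0.0;
  for (int a = 0; a < nt; ++a) {
    const int i = ord[a];
    const double xi = x[i];
    for (int b = a + 1; b < nt; ++b) {
      const int j = ord[b];
      if (x[j] - xi >= tol) break;  // sorted: no later b can match coord 0
      bool match = true;
      for (int k = 1; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) >= tol) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0;
      if (std::abs(x[i + m] - x[j + m]) < tol) A += 1.0;
    }
  }
  return NumericVector::create(_["A"] = A, _["B"] = B);
}
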