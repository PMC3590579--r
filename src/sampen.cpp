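#include <Rcpp.h>
using namespace Rcpp;

// Richman-Moorman template-pair counts for sample entropy.
//
// Counts unordered pairs i < j with i, j <= N - m whose m-length templates
// match within Chebyshev tolerance r (count B), and whose (m+1)-length
// templates also match (count A). Self-matches are excluded by construction.
// S_E = -log(A / B) is computed on the R side so that degenerate counts can
// be flagged rather than silently propagated.
//
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of usable template start points
  double B = 0.0, A = 0.0;
  if (nt < 2) return NumericVector::create(0.0, 0.0);
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0;
      if (std::abs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(B, A);
}
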