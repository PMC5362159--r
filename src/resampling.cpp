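#include <Rcpp.h>
using namespace Rcpp;

// Residual Systematic Resampling.
//
// One-pass recurrence producing integer replication counts from a single
// uniform draw u in [0, 1/P):
//   r_m = floor((w_m - u) * P) + 1,  then  u <- u + r_m / P - w_m.
// Counts sum to P exactly in exact arithmetic and E[r_m] = P * w_m.
// [[Rcpp::export(name = ".rsr_resample_cpp")]]
IntegerVector rsr_resample_cpp(NumericVector weights, double u) {
  const int P = weights.size();
  IntegerVector counts(P);
  double uu = u;
  long total = 0;
  for (int m = 0; m < P; ++m) {
    const double w = weights[m];
    if (w < 0) stop("negative weight at position %d", m + 1);
    long r = (long)std::floor((w - uu) * P) + 1;
    if (r < 0) r = 0;  // guards floating-point underrun; exact math gives r >= 0
    counts[m] = (int)r;
    uu += (double)r / P - w;
    total += r;
  }
  // floating-point slack can leave the tally one off P on adversarial inputs;
  // absorb the difference in the largest-weight particle
  if (total != P) {
    int imax = (int)(std::max_element(weights.begin(), weights.end()) - weights.begin());
    counts[imax] += (int)(P - total);
    if (counts[imax] < 0) stop("resampling counts failed to sum to P");
  }
  return counts;
}
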