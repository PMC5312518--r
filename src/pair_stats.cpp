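#include <Rcpp.h>
using namespace Rcpp;

// Pairwise concordance statistics for Kendall's tau.
// Tied pairs contribute nothing to numerator or denominator.

// [[Rcpp::export(name = ".tau_complete_cpp")]]
double tau_complete_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  double num = 0.0, den = 0.0;
  for (int r = 0; r < n - 1; ++r) {
    for (int s = r + 1; s < n; ++s) {
      double dx = x[r] - x[s], dy = y[r] - y[s];
      if (dx == 0.0 || dy == 0.0) continue;
      num += ((dx > 0) == (dy > 0)) ? 1.0 : -1.0;
      den += 1.0;
    }
  }
  if (den == 0.0) return NA_REAL;
  return num / den;
}

// Renormalized Oakes statistic: `w` holds the per-subject orderability
// weight (1/G(t)^2 for events inside the support of G, 0 otherwise); a pair
// is scored with the weight of its smaller observed time.
// [[Rcpp::export(name = ".tau_censored_cpp")]]
double tau_censored_cpp(NumericVector cost, NumericVector t,
                        NumericVector w) {
  const int n = cost.size();
  double num = 0.0, den = 0.0;
  for (int r = 0; r < n - 1; ++r) {
    for (int s = r + 1; s < n; ++s) {
      double dx = cost[r] - cost[s], dy = t[r] - t[s];
      if (dx == 0.0 || dy == 0.0) continue;
      double wp = (dy < 0) ? w[r] : w[s];
      if (wp <= 0.0) continue;
      num += (((dx > 0) == (dy > 0)) ? 1.0 : -1.0) * wp;
      den += wp;
    }
  }
  if (den == 0.0) return NA_REAL;
  return num / den;
}
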