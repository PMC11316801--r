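#include <Rcpp.h>
#include <Rmath.h>
using namespace Rcpp;

// Two-sided Wilcoxon signed-rank p-values, one per column of the paired
// difference matrix D. Zeros are dropped; exact distribution (psignrank)
// when |d| has no ties, tie-corrected normal approximation otherwise.
// [[Rcpp::export(name = ".signed_rank_p_cols")]]
NumericVector signed_rank_p_cols(NumericMatrix D) {
  const int nb = D.ncol(), nr = D.nrow();
  NumericVector out(nb);
  std::vector<double> d, ad, r;
  d.reserve(nr); ad.reserve(nr); r.reserve(nr);

  for (int j = 0; j < nb; ++j) {
    d.clear(); ad.clear();
    for (int i = 0; i < nr; ++i) {
      double v = D(i, j);
      if (R_finite(v) && v != 0.0) { d.push_back(v); ad.push_back(std::fabs(v)); }
    }
    const int n = (int)d.size();
    if (n < 2) { out[j] = NA_REAL; continue; }

    // average ranks of |d| (O(n^2); n is small)
    r.assign(n, 0.0);
    bool ties = false;
    for (int i = 0; i < n; ++i) {
      int less = 0, eq = 0;
      for (int k = 0; k < n; ++k) {
        if (ad[k] < ad[i]) ++less;
        else if (ad[k] == ad[i]) ++eq;
      }
      if (eq > 1) ties = true;
      r[i] = less + (eq + 1) / 2.0;
    }
    double V = 0.0;
    for (int i = 0; i < n; ++i) if (d[i] > 0) V += r[i];

    double p;
    if (!ties) {
      double p_lo = R::psignrank(V, n, 1, 0);
      double p_hi = R::psignrank(V - 1.0, n, 0, 0);
      p = 2.0 * std::min(p_lo, p_hi);
      if (p > 1.0) p = 1.0;
    } else {
      // tie-corrected variance
      double tie_sum = 0.0;
      for (int i = 0; i < n; ++i) {
        int eq = 0;
        for (int k = 0; k < n; ++k) if (ad[k] == ad[i]) ++eq;
        if (eq > 1) tie_sum += (double)(eq * eq - 1); // counted eq times => eq^3-eq total
      }
      double sig2 = n * (n + 1.0) * (2.0 * n + 1.0) / 24.0 - tie_sum / 48.0;
      if (sig2 <= 0) { out[j] = NA_REAL; continue; }
      double z = (V - n * (n + 1.0) / 4.0) / std::sqrt(sig2);
      p = 2.0 * R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0);
    }
    out[j] = p;
  }
  return out;
}
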