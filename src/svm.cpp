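#include <Rcpp.h>
using namespace Rcpp;

// Linear SVM via dual coordinate descent (Hsieh et al. 2008, liblinear
// algorithm 3), L2-regularized L1 (hinge) loss. The bias is handled by an
// augmented constant feature of value 1, so it is regularized like the
// weights (liblinear with intercept_scaling = 1). Coordinates are visited
// in a fixed cyclic order so the fit is deterministic.
//
// X: n x p matrix, y: +1/-1 labels, C: cost. Returns list(w, b, n_iter).
// [[Rcpp::export(name = ".svm_dcd_fit")]]
List svm_dcd_fit(NumericMatrix X, NumericVector y, double C,
                 int max_epochs = 1000, double tol = 1e-4) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> alpha(n, 0.0), w(p + 1, 0.0), qii(n);

  for (int i = 0; i < n; ++i) {
    double s = 1.0; // augmented bias feature
    for (int j = 0; j < p; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }

  int epoch = 0;
  for (; epoch < max_epochs; ++epoch) {
    double max_pg = 0.0;
    for (int i = 0; i < n; ++i) {
      if (qii[i] <= 0) continue;
      double wx = w[p]; // bias feature contribution
      for (int j = 0; j < p; ++j) wx += w[j] * X(i, j);
      const double g = y[i] * wx - 1.0;
      // projected gradient
      double pg = g;
      if (alpha[i] <= 0.0 && g > 0.0) pg = 0.0;
      else if (alpha[i] >= C && g < 0.0) pg = 0.0;
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (pg != 0.0) {
        const double old = alpha[i];
        double a = old - g / qii[i];
        if (a < 0.0) a = 0.0; else if (a > C) a = C;
        alpha[i] = a;
        const double d = (a - old) * y[i];
        if (d != 0.0) {
          for (int j = 0; j < p; ++j) w[j] += d * X(i, j);
          w[p] += d;
        }
      }
    }
    if (max_pg < tol) { ++epoch; break; }
  }

  NumericVector wout(p);
  for (int j = 0; j < p; ++j) wout[j] = w[j];
  return List::create(_["w"] = wout, _["b"] = w[p], _["n_epochs"] = epoch);
}
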