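#include <Rcpp.h>
using namespace Rcpp;

// L2-regularized L1-loss (hinge) linear SVM, solved in the dual by
// coordinate descent (the liblinear algorithm). The bias is handled by an
// augmented constant feature of value 1, so it is regularized like the
// weights; this leaves the decision-value ordering (all the pipeline
// scores by ROC AUC) unaffected. Deterministic fixed-order sweeps.
//
// X: n x p feature matrix, y: +1/-1 labels, C: cost, tol: stopping
// tolerance on the projected gradient range, max_sweeps: hard cap.
// Returns c(w (p), b).
// [[Rcpp::export(name = ".svm_dualcd")]]
NumericVector svm_dualcd(NumericMatrix X, NumericVector y, double C,
                         double tol = 1e-4, int max_sweeps = 1000) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> alpha(n, 0.0), qii(n);
  std::vector<double> w(p + 1, 0.0);  // last entry = bias weight
  for (int i = 0; i < n; ++i) {
    double s = 1.0;  // augmented bias feature
    for (int j = 0; j < p; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double pg_max = -1e300, pg_min = 1e300;
    for (int i = 0; i < n; ++i) {
      double xw = w[p];
      for (int j = 0; j < p; ++j) xw += X(i, j) * w[j];
      double G = y[i] * xw - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      else if (alpha[i] >= C && G < 0.0) PG = 0.0;
      if (PG > pg_max) pg_max = PG;
      if (PG < pg_min) pg_min = PG;
      if (PG != 0.0) {
        double a_old = alpha[i];
        double a_new = a_old - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        else if (a_new > C) a_new = C;
        alpha[i] = a_new;
        double d = (a_new - a_old) * y[i];
        if (d != 0.0) {
          for (int j = 0; j < p; ++j) w[j] += d * X(i, j);
          w[p] += d;
        }
      }
    }
    if (pg_max - pg_min < tol && pg_max < tol && pg_min > -tol) break;
  }
  NumericVector out(p + 1);
  for (int j = 0; j <= p; ++j) out[j] = w[j];
  return out;
}
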