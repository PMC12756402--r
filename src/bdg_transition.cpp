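#include <Rcpp.h>
using namespace Rcpp;

// Row recurrence of the linear birth-death-immigration transition matrix.
// Row 0 is the immigration component; row i is row i-1 convolved with the
// per-ancestor modified-geometric law g = alpha*delta_0 + (1-alpha)(1-beta)
// * Geometric(beta) shifted to 1. The geometric tail makes the convolution
// a first-order recursion, O(n) per row.
// [[Rcpp::export]]
NumericMatrix bdg_transition_rows(NumericVector imm, double alpha, double beta) {
  int ns = imm.size();
  NumericMatrix P(ns, ns);
  for (int j = 0; j < ns; ++j) P(0, j) = imm[j];
  double c1 = (1.0 - alpha) * (1.0 - beta);
  for (int i = 1; i < ns; ++i) {
    double s = 0.0;
    P(i, 0) = alpha * P(i - 1, 0);
    for (int j = 1; j < ns; ++j) {
      s = P(i - 1, j - 1) + beta * s;
      P(i, j) = alpha * P(i - 1, j) + c1 * s;
    }
  }
  return P;
}
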