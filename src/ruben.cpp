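#include <Rcpp.h>

// Coefficient recursion for Ruben's central chi-square mixture expansion.
// The series coefficients c_k of f(z) = c0 * prod_i (1 - b_i z)^{-1/2}
// satisfy the linear recurrence induced by P(z) f'(z) = R(z) f(z) with
// P(z) = prod_i (1 - b_i z) and R = -P'/2:
//   (k+1) c_{k+1} = sum_j R_j c_{k-j} - sum_{j>=1} P_j (k+1-j) c_{k+1-j}.
// Hot path of the SKAT-O machinery, hence compiled.
// [[Rcpp::export(name = ".ruben_coef_rec")]]
Rcpp::NumericVector ruben_coef_rec(Rcpp::NumericVector P,
                                   Rcpp::NumericVector R,
                                   double c0, int K) {
  int deg = P.size() - 1;
  Rcpp::NumericVector cf(K + 1);
  cf[0] = c0;
  for (int k = 0; k < K; ++k) {
    double acc = 0.0;
    int jr = std::min(k, deg - 1);
    for (int j = 0; j <= jr; ++j) acc += R[j] * cf[k - j];
    int jp = std::min(k + 1, deg);
    for (int j = 1; j <= jp; ++j) acc -= P[j] * (k + 1 - j) * cf[k + 1 - j];
    cf[k + 1] = acc / (k + 1);
  }
  return cf;
}
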