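// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Divide-and-conquer symmetric eigendecomposition; the hot kernel of the
// per-fit REML step (H = W^{1/2} K W^{1/2} changes at every outer iteration).
// [[Rcpp::export(name = ".eig_sym_dc")]]
Rcpp::List eig_sym_dc(const arma::mat& H) {
  arma::vec d;
  arma::mat U;
  arma::eig_sym(d, U, H, "dc");
  return Rcpp::List::create(Rcpp::Named("values") = d,
                            Rcpp::Named("vectors") = U);
}
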