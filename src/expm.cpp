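#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

//' Dense matrix exponential (scaling-and-squaring Pade approximation).
//'
//' @param x a square numeric matrix.
//' @return the matrix exponential of \code{x}.
//' @keywords internal
// [[Rcpp::export(name = ".expmDense")]]
arma::mat expmDense(const arma::mat& x) {
    return arma::expmat(x);
}
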