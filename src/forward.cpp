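#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Forward propagation through an untrained feed-forward network.
// Layer 1 (input map) and the final layer are affine without activation;
// intermediate layers apply an in-place ELU after the affine map. Doing
// the bias add and activation in place avoids the large temporary
// allocations an R-level loop would make on frame-major matrices.
// [[Rcpp::export]]
arma::mat cpp_forward(const arma::mat& x, const List& weights,
                      const List& biases, double alpha) {
  const int L = weights.size();
  arma::mat h = x;
  for (int l = 0; l < L; ++l) {
    arma::mat W = as<arma::mat>(weights[l]);
    arma::rowvec b = as<arma::rowvec>(biases[l]);
    h = h * W.t();
    h.each_row() += b;
    if (l > 0 && l < L - 1) {
      h.transform([alpha](double v) {
        return v >= 0.0 ? v : alpha * (std::exp(v) - 1.0);
      });
    }
  }
  return h;
}
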