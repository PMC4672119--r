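#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

// Cascade of n identical complex one-pole resonator stages with pole
// rho*exp(i*theta) (the standard complex-valued all-pole gammatone
// realisation). Input is real; output is 2*Re of the complex cascade
// output, unnormalised (the R wrapper divides by the analytic gain at CF).
// [[Rcpp::export]]
NumericVector gammatone_core_cpp(NumericVector x, double rho, double theta,
                                 int n) {
  R_xlen_t len = x.size();
  std::complex<double> p = std::polar(rho, theta);
  std::vector< std::complex<double> > state(n, std::complex<double>(0.0, 0.0));
  NumericVector out(len);
  for (R_xlen_t k = 0; k < len; ++k) {
    std::complex<double> v(x[k], 0.0);
    for (int s = 0; s < n; ++s) {
      state[s] = v + p * state[s];
      v = state[s];
    }
    out[k] = 2.0 * v.real();
  }
  return out;
}
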