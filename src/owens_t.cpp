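#include <Rcpp.h>
#include <boost/math/special_functions/owens_t.hpp>
using namespace Rcpp;

// Vectorized Owen's T function T(h, a), via the Patefield-Tandy
// algorithm as implemented in Boost.Math (abs error well below 1e-14).
// [[Rcpp::export]]
NumericVector owens_t_cpp(NumericVector h, double a) {
  const int n = h.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (!std::isfinite(h[i])) {
      out[i] = 0.0;
    } else {
      out[i] = boost::math::owens_t(h[i], a);
    }
  }
  return out;
}
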