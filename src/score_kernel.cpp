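#include <Rcpp.h>
using namespace Rcpp;

// Score statistics for B permutation resamples at treatment size t.
// orderings: n x B matrix of 1-based permuted cell indices; the
// treatment set of resample b is the first t entries of column b.
// Returns NA for a resample whose variance term is nonpositive.
// [[Rcpp::export]]
NumericVector score_stats_prefix_cpp(NumericVector a, NumericVector w,
                                     NumericMatrix D, NumericMatrix S,
                                     IntegerMatrix orderings, int t) {
  const int B = orderings.ncol();
  const int q = D.ncol();
  NumericVector out(B);
  std::vector<double> u(q);
  for (int b = 0; b < B; ++b) {
    double num = 0.0, sw = 0.0;
    std::fill(u.begin(), u.end(), 0.0);
    for (int k = 0; k < t; ++k) {
      const int i = orderings(k, b) - 1;
      num += a[i];
      sw += w[i];
      for (int j = 0; j < q; ++j) u[j] += D(i, j);
    }
    double quad = 0.0;
    for (int r = 0; r < q; ++r) {
      double s = 0.0;
      for (int j = 0; j < q; ++j) s += S(r, j) * u[j];
      quad += s * s;
    }
    const double v2 = sw - quad;
    out[b] = (v2 > 0.0) ? num / std::sqrt(v2) : NA_REAL;
  }
  return out;
}

// Sums of y over permutation prefixes (plain-sum permutation test).
// [[Rcpp::export]]
NumericVector sum_stats_prefix_cpp(NumericVector y, IntegerMatrix orderings,
                                   int t) {
  const int B = orderings.ncol();
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    double s = 0.0;
    for (int k = 0; k < t; ++k) s += y[orderings(k, b) - 1];
    out[b] = s;
  }
  return out;
}
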