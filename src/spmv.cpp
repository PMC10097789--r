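#include <Rcpp.h>
using namespace Rcpp;

// Sparse (column-compressed) matrix-vector product with long-double
// accumulation. The solver's residual r = f - K u suffers catastrophic
// cancellation in double when ||K|| ||u|| >> ||f||; the extra mantissa bits
// push the attainable residual floor down by ~3 decades.
// [[Rcpp::export]]
NumericVector spmv_longdouble_cpp(IntegerVector p, IntegerVector i,
                                  NumericVector x, NumericVector u,
                                  int nrow) {
  const int ncol = p.size() - 1;
  std::vector<long double> acc(nrow, 0.0L);
  for (int j = 0; j < ncol; ++j) {
    const long double uj = u[j];
    if (uj == 0.0L) continue;
    for (int k = p[j]; k < p[j + 1]; ++k)
      acc[i[k]] += (long double)x[k] * uj;
  }
  NumericVector y(nrow);
  for (int r = 0; r < nrow; ++r) y[r] = (double)acc[r];
  return y;
}
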