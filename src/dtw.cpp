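#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-programming accumulator for DTW.
// costs: t1 x t2 nonnegative frame costs. Returns the (t1+1) x (t2+1)
// matrix M with M(0,0) = 0, first row/column +Inf, and
// M(i,j) = costs(i-1,j-1) + min(M(i,j-1), M(i-1,j-1), M(i-1,j)).
// [[Rcpp::export]]
NumericMatrix dtw_accumulate(NumericMatrix costs) {
  const int t1 = costs.nrow(), t2 = costs.ncol();
  NumericMatrix M(t1 + 1, t2 + 1);
  const double inf = R_PosInf;
  for (int j = 1; j <= t2; ++j) M(0, j) = inf;
  for (int i = 1; i <= t1; ++i) M(i, 0) = inf;
  M(0, 0) = 0.0;
  for (int i = 1; i <= t1; ++i) {
    for (int j = 1; j <= t2; ++j) {
      double c = costs(i - 1, j - 1);
      if (ISNAN(c)) stop("NaN cost at (%d, %d)", i, j);
      double best = M(i - 1, j - 1);
      if (M(i, j - 1) < best) best = M(i, j - 1);
      if (M(i - 1, j) < best) best = M(i - 1, j);
      M(i, j) = c + best;
    }
  }
  return M;
}
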