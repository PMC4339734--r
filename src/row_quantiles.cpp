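#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Per-row sample quantile (type 7) of a numeric matrix.
// Used for per-frequency-bin noise-floor tracking, where apply()+quantile()
// over ~500 bins every few hundred frames is prohibitively slow in R.
// Rows are gathered through a transposed copy so the selection runs on
// contiguous memory.
// [[Rcpp::export]]
NumericVector row_quantiles(NumericMatrix x, double p) {
  const int nr = x.nrow(), nc = x.ncol();
  if (nc == 0) stop("matrix has zero columns");
  if (p < 0.0 || p > 1.0) stop("p must be in [0, 1]");
  NumericVector out(nr);
  // transpose into row-major scratch: column-wise reads are contiguous
  std::vector<double> t((size_t)nr * nc);
  const double *xp = x.begin();
  for (int j = 0; j < nc; ++j) {
    const double *col = xp + (size_t)j * nr;
    for (int i = 0; i < nr; ++i) t[(size_t)i * nc + j] = col[i];
  }
  const double h = p * (nc - 1);
  const int lo = (int)std::floor(h);
  const double g = h - lo;
  for (int i = 0; i < nr; ++i) {
    double *row = &t[(size_t)i * nc];
    std::nth_element(row, row + lo, row + nc);
    double v_lo = row[lo];
    double v_hi = v_lo;
    if (g > 0.0 && lo < nc - 1) {
      v_hi = *std::min_element(row + lo + 1, row + nc);
    }
    out[i] = (1.0 - g) * v_lo + g * v_hi;
  }
  return out;
}
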