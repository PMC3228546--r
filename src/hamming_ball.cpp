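#include <Rcpp.h>
using namespace Rcpp;

// Weighted count of observed words inside the Hamming ball of each query.
//
// query, obs: integer matrices with one column per word and one row per
// position (base codes 1..4).  For query word q the return value is
// sum of w[j] over all observed columns j with Hamming(q, obs_j) <= d.
// Early exit once the running mismatch count exceeds d keeps the scan
// cheap for the small radii (d <= L/2) used by the mutation-degree model.
// [[Rcpp::export(name = ".hamming_ball_sums")]]
NumericVector hamming_ball_sums(IntegerMatrix query, IntegerMatrix obs,
                                NumericVector w, int d) {
  const int L = query.nrow();
  const int m = query.ncol();
  const int n = obs.ncol();
  if (obs.nrow() != L)
    stop("query and observed word matrices must have the same word length");
  if (w.size() != n)
    stop("one weight per observed word required");
  NumericVector out(m);
  const int *q = INTEGER(query);
  const int *x = INTEGER(obs);
  for (int i = 0; i < m; ++i) {
    const int *qi = q + (size_t)i * L;
    double s = 0.0;
    for (int j = 0; j < n; ++j) {
      const int *xj = x + (size_t)j * L;
      int mm = 0;
      for (int k = 0; k < L; ++k) {
        if (qi[k] != xj[k] && ++mm > d) break;
      }
      if (mm <= d) s += w[j];
    }
    out[i] = s;
  }
  return out;
}
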