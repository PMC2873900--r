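#include <Rcpp.h>
using namespace Rcpp;

// G2 (likelihood-ratio) statistic for x vs t stratified by the joint
// configuration of the conditioning columns. x, t are 0-based codes of
// length n; z is an n x k matrix of 0-based codes; cx, ct, cz are the
// cardinalities. Returns {statistic, nonempty_strata}.
// Strata with no observations contribute nothing; within a stratum, cells
// with zero row or column margins contribute nothing (0 * log 0 = 0).
// [[Rcpp::export]]
NumericVector g2_stat_cpp(IntegerVector x, IntegerVector t, IntegerMatrix z,
                          int cx, int ct, IntegerVector cz) {
  const int n = x.size();
  const int k = cz.size();
  double nstrata = 1;
  for (int j = 0; j < k; ++j) nstrata *= cz[j];
  if (nstrata * cx * ct > 5e7) stop("contingency table too large");
  const int S = (int) nstrata;
  std::vector<double> counts((size_t) S * cx * ct, 0.0);
  for (int i = 0; i < n; ++i) {
    int s = 0, mult = 1;
    for (int j = 0; j < k; ++j) { s += z(i, j) * mult; mult *= cz[j]; }
    counts[((size_t) s * cx + x[i]) * ct + t[i]] += 1.0;
  }
  double stat = 0.0;
  int nonempty = 0;
  std::vector<double> rowm(cx), colm(ct);
  for (int s = 0; s < S; ++s) {
    const size_t base = (size_t) s * cx * ct;
    double ns = 0.0;
    std::fill(rowm.begin(), rowm.end(), 0.0);
    std::fill(colm.begin(), colm.end(), 0.0);
    for (int a = 0; a < cx; ++a)
      for (int b = 0; b < ct; ++b) {
        double o = counts[base + (size_t) a * ct + b];
        rowm[a] += o; colm[b] += o; ns += o;
      }
    if (ns == 0.0) continue;
    ++nonempty;
    for (int a = 0; a < cx; ++a) {
      if (rowm[a] == 0.0) continue;
      for (int b = 0; b < ct; ++b) {
        double o = counts[base + (size_t) a * ct + b];
        if (o > 0.0) stat += 2.0 * o * std::log(o * ns / (rowm[a] * colm[b]));
      }
    }
  }
  return NumericVector::create(stat, (double) nonempty);
}
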