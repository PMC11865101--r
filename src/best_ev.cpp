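#include <Rcpp.h>
using namespace Rcpp;

// Best explained variance over all admissible single-feature threshold
// splits, given precomputed per-feature sort orders. Used in the
// permutation loop of the distribution of false discoveries, where the
// feature geometry is fixed and only the target changes.
//
// ord: n x p matrix, column j = 0-based indices sorting feature j ascending.
// bnd: n x p logical matrix, bnd(i, j) TRUE when sorted position i closes a
//      run of equal values of feature j (a distinct-value boundary).
// Splits with subgroup fraction (prefix or suffix) inside
// [min_frac, max_frac] are admissible; returns NA when none is, or when the
// target is constant.
// [[Rcpp::export]]
double cpp_best_split_ev(const IntegerMatrix& ord, const LogicalMatrix& bnd,
                         const NumericVector& y, double min_frac,
                         double max_frac) {
  const int n = ord.nrow(), p = ord.ncol();
  double total = 0.0;
  for (int i = 0; i < n; i++) total += y[i];
  const double mu = total / n;
  double ss_total = 0.0;
  for (int i = 0; i < n; i++) {
    const double d = y[i] - mu;
    ss_total += d * d;
  }
  if (ss_total <= 0.0) return NA_REAL;

  double best = NA_REAL;
  bool found = false;
  for (int j = 0; j < p; j++) {
    double cs = 0.0;
    for (int i = 0; i < n - 1; i++) {
      cs += y[ord(i, j)];
      if (!bnd(i, j)) continue;
      const int m = i + 1;
      const double f = (double)m / n;
      const bool pre = (f >= min_frac && f <= max_frac);
      const bool suf = ((1.0 - f) >= min_frac && (1.0 - f) <= max_frac);
      if (!pre && !suf) continue;
      const double rest = total - cs;
      double between = cs * cs / m + rest * rest / (n - m) -
        total * total / n;
      double ev = between / ss_total;
      if (ev < 0.0) ev = 0.0;
      if (ev > 1.0) ev = 1.0;
      if (!found || ev > best) {
        best = ev;
        found = true;
      }
    }
  }
  return best;
}
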