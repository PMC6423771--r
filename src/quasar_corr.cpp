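#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Banded interaction-correlation matrix for the QuASAR transform.
//
// counts: full symmetric count matrix (original bin coordinates).
// valid:  logical mask of bins retained by the band filter.
// bg:     background mean count per inter-bin distance, bg[d] for
//         d = 1..window (bg[0] unused); NaN where undefined.
// window: band half-width in bins (100 in the published method).
//
// For every retained row pair (A, B) with 1 <= B - A <= window, the
// Pearson correlation of the log-enrichment vectors of rows A and B is
// computed over columns j with |j - A| <= window and |j - B| <= window,
// excluding j == A, j == B, filtered columns, and cells with zero counts
// (whose log enrichment is undefined). Entries with fewer than 3 shared
// columns or zero variance are NA. The weight matrix holds
// sqrt(counts[A,B] / bg[B-A] + 1) wherever the correlation is defined.
// [[Rcpp::export]]
List quasar_corr_cpp(NumericMatrix counts, LogicalVector valid,
                     NumericVector bg, int window) {
  const int n = counts.nrow();
  NumericMatrix corr(n, n), weight(n, n);
  std::fill(corr.begin(), corr.end(), NA_REAL);
  std::fill(weight.begin(), weight.end(), NA_REAL);

  for (int A = 0; A < n; ++A) {
    if (!valid[A]) continue;
    const int bmax = std::min(n - 1, A + window);
    for (int B = A + 1; B <= bmax; ++B) {
      if (!valid[B]) continue;
      const int d_ab = B - A;
      if (ISNAN(bg[d_ab]) || bg[d_ab] <= 0) continue;
      const int jlo = std::max(0, B - window);
      const int jhi = std::min(n - 1, A + window);
      double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
      int m = 0;
      for (int j = jlo; j <= jhi; ++j) {
        if (j == A || j == B || !valid[j]) continue;
        const int da = std::abs(j - A), db = std::abs(j - B);
        if (da < 1 || db < 1) continue;
        if (ISNAN(bg[da]) || bg[da] <= 0 || ISNAN(bg[db]) || bg[db] <= 0)
          continue;
        const double ca = counts(A, j), cb = counts(B, j);
        if (ca <= 0 || cb <= 0) continue;
        const double x = std::log(ca / bg[da]);
        const double y = std::log(cb / bg[db]);
        sx += x; sy += y; sxx += x * x; syy += y * y; sxy += x * y;
        ++m;
      }
      if (m < 3) continue;
      const double vx = sxx - sx * sx / m;
      const double vy = syy - sy * sy / m;
      if (vx <= 1e-12 || vy <= 1e-12) continue;
      const double cov = sxy - sx * sy / m;
      double r = cov / std::sqrt(vx * vy);
      if (r > 1.0) r = 1.0;
      if (r < -1.0) r = -1.0;
      corr(A, B) = r;
      weight(A, B) = std::sqrt(counts(A, B) / bg[d_ab] + 1.0);
    }
  }
  return List::create(Named("corr") = corr, Named("weight") = weight);
}
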