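#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Gamma map by exhaustive search over an upsampled evaluation grid.
// ref: coarse reference plane (nr x nc), pixel pitch spacing_ref (mm).
// fine: upsampled evaluation plane sharing the physical origin of ref,
//       pixel pitch spacing_fine (mm).
// scored: logical mask on ref of points to score (others -> NA).
// dd_denom: per-point dose denominators in the same dose units as the
//           planes (already includes the % criterion).
// Candidates are visited in order of increasing spatial distance so the
// search can stop once the pure distance term exceeds the running minimum.
// [[Rcpp::export]]
NumericMatrix gamma_map_cpp(const NumericMatrix& ref,
                            const NumericMatrix& fine,
                            const LogicalMatrix& scored,
                            const NumericMatrix& dd_denom,
                            double spacing_ref,
                            double spacing_fine,
                            double dta_mm,
                            double radius_mm) {
  const int nr = ref.nrow(), nc = ref.ncol();
  const int fr = fine.nrow(), fc = fine.ncol();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_REAL);

  // precompute candidate offsets within radius, sorted by distance
  const int rad_px = (int)std::ceil(radius_mm / spacing_fine);
  struct Off { int di, dj; double d2; };
  std::vector<Off> offs;
  offs.reserve((2 * rad_px + 1) * (2 * rad_px + 1));
  const double rad2 = radius_mm * radius_mm;
  for (int di = -rad_px; di <= rad_px; ++di)
    for (int dj = -rad_px; dj <= rad_px; ++dj) {
      const double d2 = (di * (double)di + dj * (double)dj) *
                        spacing_fine * spacing_fine;
      if (d2 <= rad2) offs.push_back({di, dj, d2});
    }
  std::sort(offs.begin(), offs.end(),
            [](const Off& a, const Off& b) { return a.d2 < b.d2; });

  const double dta2 = dta_mm * dta_mm;
  const double ratio = spacing_ref / spacing_fine;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!scored(i, j)) continue;
      const double dref = ref(i, j);
      const double denom = dd_denom(i, j);
      const int ci = (int)std::lround(i * ratio);
      const int cj = (int)std::lround(j * ratio);
      double best = R_PosInf;
      for (const Off& o : offs) {
        const double dist_term = o.d2 / dta2;
        if (dist_term >= best) break;  // sorted: no better candidate remains
        const int ei = ci + o.di, ej = cj + o.dj;
        if (ei < 0 || ej < 0 || ei >= fr || ej >= fc) continue;
        const double dd = (fine(ei, ej) - dref) / denom;
        const double g2 = dist_term + dd * dd;
        if (g2 < best) best = g2;
      }
      out(i, j) = std::sqrt(best);
    }
  }
  return out;
}
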