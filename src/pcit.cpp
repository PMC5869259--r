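#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exhaustive trio screen of the PCIT algorithm.
//
// For every unordered trio (x, y, z) the three first-order partial
// correlations are computed, the tolerance eps is the arithmetic mean of
// the signed ratios partial/direct (ratios with |direct| < guard, or with
// an undefined partial, are excluded; a trio with no defined ratio imposes
// no flag), and edge (x, y) is flagged non-significant in the context of z
// when |r_xy| <= |eps * r_xz| and |r_xy| <= |eps * r_yz|. An edge survives
// iff no third node flags it.
//
// [[Rcpp::export]]
LogicalMatrix pcit_keep_cpp(NumericMatrix r, double guard = 1e-12) {
  const int n = r.nrow();
  LogicalMatrix flagged(n, n);

  for (int x = 0; x < n - 2; ++x) {
    for (int y = x + 1; y < n - 1; ++y) {
      const double rxy = r(x, y);
      for (int z = y + 1; z < n; ++z) {
        const double rxz = r(x, z);
        const double ryz = r(y, z);

        // partial correlations; NaN when a denominator vanishes
        const double dxy = (1.0 - rxz * rxz) * (1.0 - ryz * ryz);
        const double dxz = (1.0 - rxy * rxy) * (1.0 - ryz * ryz);
        const double dyz = (1.0 - rxy * rxy) * (1.0 - rxz * rxz);
        const double pxy = dxy > 0 ? (rxy - rxz * ryz) / std::sqrt(dxy) : NA_REAL;
        const double pxz = dxz > 0 ? (rxz - rxy * ryz) / std::sqrt(dxz) : NA_REAL;
        const double pyz = dyz > 0 ? (ryz - rxy * rxz) / std::sqrt(dyz) : NA_REAL;

        double sum = 0.0;
        int m = 0;
        if (!ISNAN(pxy) && std::fabs(rxy) >= guard) { sum += pxy / rxy; ++m; }
        if (!ISNAN(pxz) && std::fabs(rxz) >= guard) { sum += pxz / rxz; ++m; }
        if (!ISNAN(pyz) && std::fabs(ryz) >= guard) { sum += pyz / ryz; ++m; }
        if (m == 0) continue;
        const double eps = sum / m;

        const double axy = std::fabs(rxy);
        const double axz = std::fabs(rxz);
        const double ayz = std::fabs(ryz);
        const double ae = std::fabs(eps);

        if (axy <= ae * axz && axy <= ae * ayz) flagged(x, y) = true;
        if (axz <= ae * axy && axz <= ae * ayz) flagged(x, z) = true;
        if (ayz <= ae * axy && ayz <= ae * axz) flagged(y, z) = true;
      }
    }
  }

  LogicalMatrix keep(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      keep(i, j) = keep(j, i) = !flagged(i, j);
  return keep;
}
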