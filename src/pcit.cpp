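#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// PCIT trio filter over a full correlation matrix.
//
// Every off-diagonal pair starts significant. For each unordered trio
// {x,y,z} the three first-order partial correlations and the trio tolerance
// eps (mean ratio of partial to direct correlation) are computed; a pair is
// discarded when its direct correlation fails the tolerance-scaled test
// against BOTH other legs of the trio. A pair discarded in any trio stays
// discarded. Trios containing a zero direct correlation are skipped
// (undefined ratio => non-informative); the caller clamps |r| = 1 entries
// beforehand so the partial-correlation denominators never vanish.
//
// corrected = true  : |r_ab| <= |eps*r_ac| && |r_ab| <= |eps*r_bc|
// corrected = false : literal printed variant, for audit:
//                     |r_ac| <= |eps*r_ac| && |r_ab| <= |eps*r_bc|
// [[Rcpp::export(name = ".pcit_cpp")]]
List pcit_cpp(NumericMatrix r, bool corrected) {
  const int n = r.nrow();
  LogicalMatrix sig(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      sig(i, j) = (i != j);

  long skipped = 0;
  for (int x = 0; x < n - 2; ++x) {
    for (int y = x + 1; y < n - 1; ++y) {
      const double rxy = r(x, y);
      for (int z = y + 1; z < n; ++z) {
        const double rxz = r(x, z);
        const double ryz = r(y, z);
        if (rxy == 0.0 || rxz == 0.0 || ryz == 0.0) {
          ++skipped;
          continue;
        }
        const double pxy = (rxy - rxz * ryz) /
          std::sqrt((1.0 - rxz * rxz) * (1.0 - ryz * ryz));
        const double pxz = (rxz - rxy * ryz) /
          std::sqrt((1.0 - rxy * rxy) * (1.0 - ryz * ryz));
        const double pyz = (ryz - rxy * rxz) /
          std::sqrt((1.0 - rxy * rxy) * (1.0 - rxz * rxz));
        const double eps = (pxy / rxy + pxz / rxz + pyz / ryz) / 3.0;
        const double ae = std::fabs(eps);
        const double axy = std::fabs(rxy), axz = std::fabs(rxz),
                     ayz = std::fabs(ryz);
        bool dxy, dxz, dyz;
        if (corrected) {
          dxy = axy <= ae * axz && axy <= ae * ayz;
          dxz = axz <= ae * axy && axz <= ae * ayz;
          dyz = ayz <= ae * axy && ayz <= ae * axz;
        } else {
          // literal reading: first leg compared against itself, by role
          dxy = axz <= ae * axz && axy <= ae * ayz;
          dxz = axy <= ae * axy && axz <= ae * ayz;
          dyz = axy <= ae * axy && ayz <= ae * axz;
        }
        if (dxy) { sig(x, y) = sig(y, x) = false; }
        if (dxz) { sig(x, z) = sig(z, x) = false; }
        if (dyz) { sig(y, z) = sig(z, y) = false; }
      }
    }
  }
  return List::create(_["significant"] = sig,
                      _["skipped_trios"] = (double)skipped);
}
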