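#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Accumulate the dose of a batch of spot-delivery events (one energy
// layer: shared per-slice IDD and sigma tables) into a 3D grid, in
// place. The lateral kernel is a double Gaussian
//   (1-w) G2(sigma1) + w G2(k sigma1)
// evaluated at voxel centers and truncated per lateral axis at
// trunc_factor * k * sigma1(z). Separability of the Gaussian lets each
// slice update be two rank-1 outer products.
//
// `values` is modified in place: callers must pass an array they own.
// Returns the summed MU of events whose kernel support lies fully
// outside the grid (clipped, for spillage accounting).
// [[Rcpp::export]]
double cpp_rasterize_events(NumericVector values, IntegerVector dim,
                            NumericVector origin, NumericVector spacing,
                            NumericVector sx, NumericVector sy,
                            NumericVector mu,
                            NumericVector sigma_cm, NumericVector idd,
                            double w, double k, double trunc_factor) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double ox = origin[0], oy = origin[1];
  const double dx = spacing[0], dy = spacing[1];
  const int ne = sx.size();
  double *val = REAL(values);
  double clipped = 0.0;
  std::vector<double> gx1(nx), gx2(nx), gy1(ny), gy2(ny);

  for (int e = 0; e < ne; ++e) {
    const double cx = sx[e], cy = sy[e], m = mu[e];
    if (m == 0.0) continue;
    bool touched = false;
    for (int iz = 0; iz < nz; ++iz) {
      const double id = idd[iz];
      if (id <= 0.0) continue;
      const double s1 = sigma_cm[iz], s2 = k * s1;
      const double rt = trunc_factor * s2;
      int i0 = (int)std::ceil((cx - rt - ox) / dx);
      int i1 = (int)std::floor((cx + rt - ox) / dx);
      int j0 = (int)std::ceil((cy - rt - oy) / dy);
      int j1 = (int)std::floor((cy + rt - oy) / dy);
      if (i0 < 0) i0 = 0;
      if (i1 > nx - 1) i1 = nx - 1;
      if (j0 < 0) j0 = 0;
      if (j1 > ny - 1) j1 = ny - 1;
      if (i0 > i1 || j0 > j1) continue;
      touched = true;
      const double a1 = m * id * (1.0 - w) / (2.0 * M_PI * s1 * s1);
      const double a2 = m * id * w / (2.0 * M_PI * s2 * s2);
      for (int i = i0; i <= i1; ++i) {
        const double u = ox + i * dx - cx;
        gx1[i] = std::exp(-u * u / (2.0 * s1 * s1));
        gx2[i] = std::exp(-u * u / (2.0 * s2 * s2));
      }
      for (int j = j0; j <= j1; ++j) {
        const double v = oy + j * dy - cy;
        gy1[j] = std::exp(-v * v / (2.0 * s1 * s1));
        gy2[j] = std::exp(-v * v / (2.0 * s2 * s2));
      }
      double *base = val + (size_t)iz * nx * ny;
      for (int j = j0; j <= j1; ++j) {
        const double b1 = a1 * gy1[j], b2 = a2 * gy2[j];
        double *col = base + (size_t)j * nx;
        for (int i = i0; i <= i1; ++i)
          col[i] += b1 * gx1[i] + b2 * gx2[i];
      }
    }
    if (!touched) clipped += m;
  }
  return clipped;
}
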