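// Shrake-Rupley numerical solvent-accessible surface area.
// Test points are placed on a deterministic golden-section spiral lattice,
// so results are exactly reproducible for a fixed point count (no RNG).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".sasa_points")]]
NumericVector sasa_points(NumericMatrix coords, NumericVector radii,
                          double probe, int nPoints) {
  int N = coords.nrow();
  if ((int)radii.size() != N) stop("radii length must match atom count");
  if (nPoints < 12) stop("nPoints too small");

  // golden-spiral unit sphere lattice
  std::vector<double> px(nPoints), py(nPoints), pz(nPoints);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < nPoints; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / nPoints;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * k;
    px[k] = r * std::cos(phi);
    py[k] = r * std::sin(phi);
    pz[k] = z;
  }

  std::vector<double> R(N);
  for (int i = 0; i < N; ++i) R[i] = radii[i] + probe;

  NumericVector area(N);
  std::vector<int> nb;
  for (int i = 0; i < N; ++i) {
    nb.clear();
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      double dx = coords(j, 0) - coords(i, 0);
      double dy = coords(j, 1) - coords(i, 1);
      double dz = coords(j, 2) - coords(i, 2);
      double lim = R[i] + R[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < nPoints; ++k) {
      double qx = coords(i, 0) + R[i] * px[k];
      double qy = coords(i, 1) + R[i] * py[k];
      double qz = coords(i, 2) + R[i] * pz[k];
      bool occ = false;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double dx = qx - coords(j, 0), dy = qy - coords(j, 1),
               dz = qz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < R[j] * R[j]) { occ = true; break; }
      }
      if (!occ) ++exposed;
    }
    area[i] = 4.0 * M_PI * R[i] * R[i] * exposed / nPoints;
  }
  return area;
}
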