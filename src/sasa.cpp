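// Shrake-Rupley solvent-accessible surface area: each atom's extended
// sphere (vdW + probe radius) is sampled with a deterministic golden-spiral
// point set; a sample is accessible when outside every other atom's
// extended sphere.  SASA_i = accessible fraction * 4*pi*(r_i + probe)^2.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".shrake_rupley_cpp")]]
NumericVector shrake_rupley_cpp(NumericMatrix coords, NumericVector radii,
                                double probe, int n_points) {
  const int n = coords.nrow();
  NumericVector area(n);
  if (n == 0) return area;

  // golden-spiral unit sphere samples
  std::vector<double> sx(n_points), sy(n_points), sz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    const double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    const double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    sx[k] = r * std::cos(ga * k);
    sy[k] = r * std::sin(ga * k);
    sz[k] = z;
  }

  std::vector<double> er(n);
  for (int i = 0; i < n; ++i) er[i] = radii[i] + probe;

  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = coords(j, 0) - coords(i, 0);
      const double dy = coords(j, 1) - coords(i, 1);
      const double dz = coords(j, 2) - coords(i, 2);
      const double lim = er[i] + er[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nbr.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      const double px = coords(i, 0) + er[i] * sx[k];
      const double py = coords(i, 1) + er[i] * sy[k];
      const double pz = coords(i, 2) + er[i] * sz[k];
      bool free_pt = true;
      for (size_t m = 0; m < nbr.size(); ++m) {
        const int j = nbr[m];
        const double dx = px - coords(j, 0);
        const double dy = py - coords(j, 1);
        const double dz = pz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < er[j] * er[j]) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * er[i] * er[i] * acc / n_points;
  }
  return area;
}
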