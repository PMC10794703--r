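#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area.
// Each atom's solvent-expanded sphere (radius r_i + probe) is sampled with a
// deterministic golden-section spiral point set; the accessible area is the
// fraction of points outside every neighbouring expanded sphere times the
// sphere area. Neighbours are pre-filtered by centre distance.
// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix coords, NumericVector radii,
                       double probe, int n_points) {
  const int n = coords.nrow();
  NumericVector area(n);

  // golden-section spiral on the unit sphere
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * k;
    px[k] = r * std::cos(th);
    py[k] = r * std::sin(th);
    pz[k] = z;
  }

  std::vector<double> er(n);
  for (int i = 0; i < n; ++i) er[i] = radii[i] + probe;

  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
             dz = coords(j, 2) - zi;
      double cut = er[i] + er[j];
      if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(j);
    }
    int accessible = 0;
    const double ri = er[i];
    for (int k = 0; k < n_points; ++k) {
      const double sx = xi + ri * px[k], sy = yi + ri * py[k],
                   sz = zi + ri * pz[k];
      bool buried = false;
      for (size_t m = 0; m < nb.size(); ++m) {
        const int j = nb[m];
        double dx = sx - coords(j, 0), dy = sy - coords(j, 1),
               dz = sz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < er[j] * er[j]) {
          buried = true;
          break;
        }
      }
      if (!buried) ++accessible;
    }
    area[i] = 4.0 * M_PI * ri * ri * accessible / n_points;
  }
  return area;
}
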