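#include <Rcpp.h>
using namespace Rcpp;

// Hard maximum-overlap constraint: no pair of cells may indent deeper than
// a quarter of the smaller cell's diameter (h_max = min(Ra, Rb) / 2).
// Excess overlap is removed by Gauss-Seidel sweeps that push the two cells
// apart symmetrically along their centre line, so the resolution is
// Newton-like (equal and opposite). Converges in a few sweeps for the
// near-rigid packings that arise here.
// [[Rcpp::export]]
List resolve_overlaps_cpp(NumericVector x0, NumericVector y0,
                          NumericVector radius, int max_iter = 20,
                          double tol = 1e-9) {
  NumericVector x = clone(x0), y = clone(y0);
  const int n = x.size();
  for (int it = 0; it < max_iter; ++it) {
    double worst = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        const double hmax = 0.5 * std::min(radius[i], radius[j]);
        const double rsum = radius[i] + radius[j];
        double dx = x[j] - x[i], dy = y[j] - y[i];
        double d = std::sqrt(dx * dx + dy * dy);
        const double h = rsum - d;
        if (h > hmax + tol) {
          double ux = 1.0, uy = 0.0;
          if (d > 0.0) { ux = dx / d; uy = dy / d; }
          const double push = 0.5 * (h - hmax);
          x[i] -= push * ux; y[i] -= push * uy;
          x[j] += push * ux; y[j] += push * uy;
          if (h - hmax > worst) worst = h - hmax;
        }
      }
    }
    if (worst <= tol) break;
  }
  return List::create(_["x"] = x, _["y"] = y);
}
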