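#include <Rcpp.h>
using namespace Rcpp;

// All-pairs mechanical kernel for one integration step.
//
// For every unordered pair it accumulates, in one O(n^2) pass:
//  - the remote strain-energy stimulus M_remote exchanged among
//    epithelial/cancer cells (decay M0 exp(-lambda d / R), cut beyond the
//    detection radius d_hat and below the runtime cutoff eps),
//  - the energy-weighted direction resultants z (pointing toward
//    neighbours),
//  - the contacting pairs with indentation h = min(Ra + Rb - d, Ra + Rb - 0.1),
//    contact energy (4 / (15 sqrt 2)) (Ec / pi) (h / min(Ra, Rb))^(5/2),
//    per-cell contact sums and repulsion resultants (pointing away).
//
// Indices in the returned pair vectors are 1-based.
// [[Rcpp::export]]
List pair_kernel_cpp(NumericVector x, NumericVector y, NumericVector radius,
                     LogicalVector big, double M0, double lambda, double R,
                     double d_hat, double eps, double Ec) {
  const int n = x.size();
  NumericVector Mrem(n), zx(n), zy(n), csum(n), repx(n), repy(n);
  std::vector<int> pa, pb;
  std::vector<double> ph, pM, pux, puy;
  const double coef = 4.0 / (15.0 * std::sqrt(2.0)) * (Ec / M_PI);

  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      const double d = std::sqrt(dx * dx + dy * dy);
      if (big[i] && big[j] && d <= d_hat) {
        const double w = M0 * std::exp(-lambda * d / R);
        if (eps <= 0.0 || w >= eps) {
          Mrem[i] += w;
          Mrem[j] += w;
          if (d > 0.0) {
            zx[i] += w * dx / d; zy[i] += w * dy / d;
            zx[j] -= w * dx / d; zy[j] -= w * dy / d;
          }
        }
      }
      const double rsum = radius[i] + radius[j];
      if (d < rsum) {
        double h = rsum - d;
        if (h > rsum - 0.1) h = rsum - 0.1; // near-coincident clamp
        const double rmin = std::min(radius[i], radius[j]);
        const double M = coef * std::pow(h / rmin, 2.5);
        const double ux = d > 0.0 ? dx / d : 1.0;
        const double uy = d > 0.0 ? dy / d : 0.0;
        pa.push_back(i + 1); pb.push_back(j + 1);
        ph.push_back(h); pM.push_back(M);
        pux.push_back(ux); puy.push_back(uy);
        csum[i] += M; csum[j] += M;
        repx[i] -= M * ux; repy[i] -= M * uy;
        repx[j] += M * ux; repy[j] += M * uy;
      }
    }
  }
  return List::create(
      _["M_remote"] = Mrem, _["zx"] = zx, _["zy"] = zy, _["csum"] = csum,
      _["repx"] = repx, _["repy"] = repy, _["a"] = wrap(pa), _["b"] = wrap(pb),
      _["h"] = wrap(ph), _["M_contact"] = wrap(pM), _["ux"] = wrap(pux),
      _["uy"] = wrap(puy));
}
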