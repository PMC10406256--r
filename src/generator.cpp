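#include <Rcpp.h>
using namespace Rcpp;

// Hard-core dart throwing with a uniform bin grid for neighbor lookup.
// Radii must arrive sorted decreasing (large cells first pack better).
// Candidate positions are thinned by the acceptance field before the
// neighbor check; centers may overlap by at most 20% of the smaller
// radius. Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export(name = ".placeCellsCpp")]]
List placeCellsCpp(NumericVector radii, int nr, int nc,
                   Nullable<NumericMatrix> acceptProb,
                   int maxAttempts) {
  const int n = radii.size();
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);
  const double binSize = std::max(4.0, 2.2 * rmax);
  const int nbr = (int)std::ceil(nr / binSize);
  const int nbc = (int)std::ceil(nc / binSize);
  std::vector< std::vector<int> > bins((size_t)nbr * nbc);
  std::vector<double> cx(n), cy(n), cr(n);
  bool hasAccept = acceptProb.isNotNull();
  NumericMatrix accept;
  if (hasAccept) accept = NumericMatrix(acceptProb);

  int placed = 0, attempts = 0;
  while (placed < n && attempts < maxAttempts) {
    ++attempts;
    double x = R::runif(1.0, (double)nr);
    double y = R::runif(1.0, (double)nc);
    if (hasAccept) {
      int ix = (int)std::ceil(x - 0.5) - 1;
      int iy = (int)std::ceil(y - 0.5) - 1;
      if (ix < 0) ix = 0; if (ix >= nr) ix = nr - 1;
      if (iy < 0) iy = 0; if (iy >= nc) iy = nc - 1;
      if (R::unif_rand() > accept(ix, iy)) continue;
    }
    double r = radii[placed];
    int bi = (int)std::ceil(x / binSize) - 1;
    int bj = (int)std::ceil(y / binSize) - 1;
    bool ok = true;
    for (int ii = std::max(0, bi - 1); ok && ii <= std::min(nbr - 1, bi + 1); ++ii)
      for (int jj = std::max(0, bj - 1); ok && jj <= std::min(nbc - 1, bj + 1); ++jj) {
        const std::vector<int> &nb = bins[(size_t)jj * nbr + ii];
        for (size_t k = 0; k < nb.size(); ++k) {
          double dx = cx[nb[k]] - x, dy = cy[nb[k]] - y;
          double minD = cr[nb[k]] + r - 0.2 * std::min(cr[nb[k]], r);
          if (dx * dx + dy * dy < minD * minD) { ok = false; break; }
        }
      }
    if (!ok) continue;
    cx[placed] = x; cy[placed] = y; cr[placed] = r;
    bins[(size_t)bj * nbr + bi].push_back(placed);
    ++placed;
  }
  return List::create(_["x"] = NumericVector(cx.begin(), cx.begin() + placed),
                      _["y"] = NumericVector(cy.begin(), cy.begin() + placed),
                      _["r"] = NumericVector(cr.begin(), cr.begin() + placed),
                      _["attempts"] = attempts);
}

// Rasterize filled ellipses with the pixel-center convention: pixel
// (i, j) is inside if its center satisfies the ellipse equation.
// [[Rcpp::export(name = ".rasterizeEllipsesCpp")]]
LogicalMatrix rasterizeEllipsesCpp(int nr, int nc, NumericVector cx,
                                   NumericVector cy, NumericVector r,
                                   NumericVector axisRatio,
                                   NumericVector theta) {
  LogicalMatrix mask(nr, nc);
  for (int k = 0; k < cx.size(); ++k) {
    double rk = r[k], qk = axisRatio[k];
    double ct = std::cos(theta[k]), st = std::sin(theta[k]);
    int i0 = std::max(1, (int)std::floor(cx[k] - rk));
    int i1 = std::min(nr, (int)std::ceil(cx[k] + rk));
    int j0 = std::max(1, (int)std::floor(cy[k] - rk));
    int j1 = std::min(nc, (int)std::ceil(cy[k] + rk));
    for (int i = i0; i <= i1; ++i) {
      double dx = i - cx[k];
      for (int j = j0; j <= j1; ++j) {
        double dy = j - cy[k];
        double u = (dx * ct + dy * st) / rk;
        double v = (-dx * st + dy * ct) / (qk * rk);
        if (u * u + v * v <= 1.0) mask(i - 1, j - 1) = true;
      }
    }
  }
  return mask;
}
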