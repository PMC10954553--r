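#include <Rcpp.h>
using namespace Rcpp;

// Kernel-weighted neighborhood densities via a cell-list spatial index.
//
// Focal trees and the neighbor pool are passed separately: the pool is the
// set of trees alive at the census preceding the interval, of all sizes.
// A neighbor is skipped when it carries the same tree id as the focal
// (a tree is never its own neighbor). Cell size equals the search radius,
// so only the 3x3 block of cells around a focal must be scanned; results
// are exactly equal to the O(n^2) scan, not approximated.
//
// kind: 0 = exponential exp(-d/mu), 1 = exponential-normal exp(-d^2/mu^2)
// use_ba: 1 = weight by basal area pi*(dbh/2)^2 (cm^2), 0 = count
// [[Rcpp::export]]
NumericMatrix cpp_densities(NumericVector fx, NumericVector fy,
                            IntegerVector fsp, IntegerVector fid,
                            NumericVector nx, NumericVector ny,
                            NumericVector ndbh, IntegerVector nsp,
                            IntegerVector nid,
                            double radius, int kind,
                            double mu_con, double mu_tot, int use_ba) {
  const int nf = fx.size(), nn = nx.size();
  NumericMatrix out(nf, 2);
  if (nn == 0) return out;

  double xmin = R_PosInf, ymin = R_PosInf, xmax = R_NegInf, ymax = R_NegInf;
  for (int k = 0; k < nn; ++k) {
    if (nx[k] < xmin) xmin = nx[k];
    if (nx[k] > xmax) xmax = nx[k];
    if (ny[k] < ymin) ymin = ny[k];
    if (ny[k] > ymax) ymax = ny[k];
  }
  const double cell = radius;
  const int ncx = std::max(1, (int)std::floor((xmax - xmin) / cell) + 1);
  const int ncy = std::max(1, (int)std::floor((ymax - ymin) / cell) + 1);

  // counting sort of neighbors into cells (CSR layout)
  std::vector<int> cell_of(nn), count(ncx * ncy + 1, 0);
  for (int k = 0; k < nn; ++k) {
    int cx = std::min(ncx - 1, std::max(0, (int)std::floor((nx[k] - xmin) / cell)));
    int cy = std::min(ncy - 1, std::max(0, (int)std::floor((ny[k] - ymin) / cell)));
    cell_of[k] = cy * ncx + cx;
    ++count[cell_of[k] + 1];
  }
  for (int c = 0; c < ncx * ncy; ++c) count[c + 1] += count[c];
  std::vector<int> order(nn);
  {
    std::vector<int> pos(count.begin(), count.end() - 1);
    for (int k = 0; k < nn; ++k) order[pos[cell_of[k]]++] = k;
  }

  const double r2 = radius * radius;
  for (int i = 0; i < nf; ++i) {
    const double xi = fx[i], yi = fy[i];
    const int spi = fsp[i], idi = fid[i];
    int cx = (int)std::floor((xi - xmin) / cell);
    int cy = (int)std::floor((yi - ymin) / cell);
    double con = 0.0, tot = 0.0;
    for (int dy = -1; dy <= 1; ++dy) {
      int gy = cy + dy;
      if (gy < 0 || gy >= ncy) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int gx = cx + dx;
        if (gx < 0 || gx >= ncx) continue;
        const int c = gy * ncx + gx;
        for (int q = count[c]; q < count[c + 1]; ++q) {
          const int k = order[q];
          if (nid[k] == idi) continue;  // self (any stem of the same tree)
          const double ddx = nx[k] - xi, ddy = ny[k] - yi;
          const double d2 = ddx * ddx + ddy * ddy;
          if (d2 > r2) continue;
          const double contrib = use_ba ? M_PI * ndbh[k] * ndbh[k] / 4.0 : 1.0;
          double wc, wt;
          if (kind == 0) {
            const double d = std::sqrt(d2);
            wc = std::exp(-d / mu_con);
            wt = std::exp(-d / mu_tot);
          } else {
            wc = std::exp(-d2 / (mu_con * mu_con));
            wt = std::exp(-d2 / (mu_tot * mu_tot));
          }
          tot += wt * contrib;
          if (nsp[k] == spi) con += wc * contrib;
        }
      }
    }
    out(i, 0) = con;
    out(i, 1) = tot;
  }
  colnames(out) = CharacterVector::create("conD", "totD");
  return out;
}
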