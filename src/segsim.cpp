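#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Directed nearest-neighbour distances between two point sets in mm.
// Exact all-pairs minimum; O(n_from * n_to) but cheap in compiled code for
// the boundary-set sizes that voxel lattices produce.
// [[Rcpp::export]]
NumericVector nn_min_distances_cpp(NumericMatrix from, NumericMatrix to) {
  const int n = from.nrow(), m = to.nrow();
  // contiguous per-coordinate copies keep the hot inner loop cache-friendly
  std::vector<double> tx(m), ty(m), tz(m);
  for (int j = 0; j < m; ++j) {
    tx[j] = to(j, 0); ty[j] = to(j, 1); tz[j] = to(j, 2);
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double x = from(i, 0), y = from(i, 1), z = from(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = x - tx[j], dy = y - ty[j], dz = z - tz[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Exact permutation p-value for Spearman's rho: enumerate the distinct
// arrangements of the y-ranks (uniform over the permutation null even under
// ties) and count |rho_perm| >= |rho_obs|. Feasible up to n = 10.
// [[Rcpp::export]]
List spearman_exact_perm_cpp(NumericVector rank_x, NumericVector rank_y) {
  const int n = rank_x.size();
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += rank_x[i]; my += rank_y[i]; }
  mx /= n; my /= n;
  std::vector<double> cx(n), cy(n);
  double ssx = 0, ssy = 0;
  for (int i = 0; i < n; ++i) {
    cx[i] = rank_x[i] - mx; ssx += cx[i] * cx[i];
    cy[i] = rank_y[i] - my; ssy += cy[i] * cy[i];
  }
  const double denom = std::sqrt(ssx * ssy);
  double dot_obs = 0;
  for (int i = 0; i < n; ++i) dot_obs += cx[i] * cy[i];
  const double rho_obs = dot_obs / denom;
  const double thr = std::fabs(rho_obs) - 1e-12;

  std::sort(cy.begin(), cy.end());
  long long n_perm = 0, n_extreme = 0;
  do {
    double dot = 0;
    for (int i = 0; i < n; ++i) dot += cx[i] * cy[i];
    if (std::fabs(dot / denom) >= thr) ++n_extreme;
    ++n_perm;
  } while (std::next_permutation(cy.begin(), cy.end()));

  return List::create(_["rho"] = rho_obs,
                      _["p_value"] = (double)n_extreme / (double)n_perm,
                      _["n_perm"] = (double)n_perm);
}
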