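#include <RcppArmadillo.h>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Multi-scale shape-operator curvature estimation on an oriented point cloud.
//
// For each point i and Gaussian window sigma, neighbours are weighted by
// w = exp(-d^2 / (2 sigma^2)) and a quadric
//   z = A u^2 + B u v + C v^2 + D u + E v
// is fit by weighted least squares in the tangent frame (e1, e2, n_i).
// The shape operator is S = -[[2A, B], [B, 2C]] so that a convex region
// (outward normals diverging) has positive trace: on a sphere of radius R
// sampled with outward normals, trace(S) = 2/R and det(S) = 1/R^2.
//
// Points with fewer than 6 usable neighbours at a scale get 0 at that scale
// and are counted in `low_support`.

// [[Rcpp::export(name = ".curvature_features")]]
List curvature_features(const arma::mat& pts, const arma::mat& nrm,
                        const arma::vec& scales, int max_neighbors = 128,
                        double wmin = 1e-4) {
  const int n = pts.n_rows;
  const int ns = scales.n_elem;
  arma::mat out(n, 2 * ns, arma::fill::zeros);
  int low_support = 0;

  arma::vec d2row(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double d2 = 0;
      for (int k = 0; k < 3; ++k) {
        double d = pts(i, k) - pts(j, k);
        d2 += d * d;
      }
      d2row[j] = d2;
    }

    // tangent frame at i
    arma::vec3 ni{nrm(i, 0), nrm(i, 1), nrm(i, 2)};
    arma::vec3 a = (std::abs(ni[0]) < 0.9) ? arma::vec3{1, 0, 0}
                                           : arma::vec3{0, 1, 0};
    arma::vec3 e1 = arma::normalise(arma::cross(ni, a));
    arma::vec3 e2 = arma::cross(ni, e1);

    for (int s = 0; s < ns; ++s) {
      const double sigma = scales[s];
      const double s2 = 2.0 * sigma * sigma;
      const double r2 = 9.0 * sigma * sigma; // 3-sigma cutoff

      std::vector<std::pair<double, int>> nb;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        if (d2row[j] <= r2 && std::exp(-d2row[j] / s2) > wmin)
          nb.push_back({d2row[j], j});
      }
      if ((int)nb.size() < 6) { ++low_support; continue; }
      if ((int)nb.size() > max_neighbors) {
        std::nth_element(nb.begin(), nb.begin() + max_neighbors, nb.end());
        nb.resize(max_neighbors);
      }

      arma::mat AtA(5, 5, arma::fill::zeros);
      arma::vec Atz(5, arma::fill::zeros);
      for (auto& pr : nb) {
        int j = pr.second;
        arma::vec3 d{pts(j, 0) - pts(i, 0), pts(j, 1) - pts(i, 1),
                     pts(j, 2) - pts(i, 2)};
        double u = arma::dot(e1, d);
        double v = arma::dot(e2, d);
        double z = arma::dot(ni, d);
        double w = std::exp(-pr.first / s2);
        arma::vec5 row{u * u, u * v, v * v, u, v};
        AtA += w * (row * row.t());
        Atz += w * z * row;
      }
      AtA.diag() += 1e-10;
      arma::vec coef;
      bool ok = arma::solve(coef, AtA, Atz, arma::solve_opts::no_approx);
      if (!ok) { ++low_support; continue; }
      double A = coef[0], B = coef[1], C = coef[2];
      // S = -[[2A, B], [B, 2C]]
      out(i, s) = 4.0 * A * C - B * B;          // det
      out(i, ns + s) = -(2.0 * A + 2.0 * C);    // trace
    }
  }
  return List::create(_["features"] = out, _["low_support"] = low_support);
}
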