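// Radius-neighbourhood quadric curvature estimation.
// For each vertex, all vertices within a Euclidean ball are expressed in the
// local tangent frame and a quadric patch w = a u^2 + b uv + c v^2 + d u + e v
// is fitted by least squares; principal curvatures come from the shape
// operator of the Monge patch. Sign convention: convex-outward regions have
// positive curvature when vertex normals point outward.

#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline long long cell_key(int ix, int iy, int iz) {
  // pack three 21-bit signed cell indices into one 64-bit key
  const long long B = 1 << 20;
  return (((long long)(ix + B)) << 42) | (((long long)(iy + B)) << 21) |
         ((long long)(iz + B));
}

// [[Rcpp::export(name = ".curvature_quadric")]]
List curvature_quadric(const arma::mat& V, const arma::mat& N, double radius) {
  const int n = V.n_rows;
  const double r2 = radius * radius;

  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(n * 2);
  for (int i = 0; i < n; ++i) {
    int ix = (int)std::floor(V(i, 0) / radius);
    int iy = (int)std::floor(V(i, 1) / radius);
    int iz = (int)std::floor(V(i, 2) / radius);
    grid[cell_key(ix, iy, iz)].push_back(i);
  }

  arma::vec k1(n), k2(n), gauss(n);
  arma::mat nfit(n, 3);
  arma::ivec nnb(n);

  std::vector<int> nbr;
  nbr.reserve(256);
  for (int i = 0; i < n; ++i) {
    const arma::rowvec p = V.row(i);
    int ix = (int)std::floor(p(0) / radius);
    int iy = (int)std::floor(p(1) / radius);
    int iz = (int)std::floor(p(2) / radius);
    nbr.clear();
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(cell_key(ix + dx, iy + dy, iz + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j == i) continue;
            double ddx = V(j, 0) - p(0), ddy = V(j, 1) - p(1),
                   ddz = V(j, 2) - p(2);
            if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) nbr.push_back(j);
          }
        }
    nnb(i) = (int)nbr.size();
    if ((int)nbr.size() < 5) {
      k1(i) = k2(i) = gauss(i) = NA_REAL;
      nfit.row(i) = N.row(i);
      continue;
    }
    // local frame from the input normal
    arma::vec nv = N.row(i).t();
    nv /= arma::norm(nv);
    arma::vec a = (std::fabs(nv(0)) < 0.9) ? arma::vec({1, 0, 0})
                                           : arma::vec({0, 1, 0});
    arma::vec e1 = arma::normalise(arma::cross(nv, a));
    arma::vec e2 = arma::cross(nv, e1);

    const int m = nbr.size();
    arma::mat A(m, 5);
    arma::vec w(m);
    for (int t = 0; t < m; ++t) {
      arma::vec d = V.row(nbr[t]).t() - p.t();
      double u = arma::dot(d, e1), v = arma::dot(d, e2),
             h = arma::dot(d, nv);
      A(t, 0) = u * u;
      A(t, 1) = u * v;
      A(t, 2) = v * v;
      A(t, 3) = u;
      A(t, 4) = v;
      w(t) = h;
    }
    arma::vec coef;
    bool ok = arma::solve(coef, A, w);
    if (!ok) {
      k1(i) = k2(i) = gauss(i) = NA_REAL;
      nfit.row(i) = N.row(i);
      continue;
    }
    double ca = coef(0), cb = coef(1), cc = coef(2), hu = coef(3),
           hv = coef(4);
    double W2 = 1.0 + hu * hu + hv * hv;
    double W = std::sqrt(W2);
    // first and second fundamental forms of the Monge patch
    arma::mat22 I = {{1 + hu * hu, hu * hv}, {hu * hv, 1 + hv * hv}};
    arma::mat22 II = {{2 * ca / W, cb / W}, {cb / W, 2 * cc / W}};
    arma::mat22 S = arma::solve(I, II);
    arma::cx_vec ev = arma::eig_gen(S);
    // shape operator of w measured along the outward normal is negative on
    // convex regions; flip so cusps come out positive
    double l1 = -ev(0).real(), l2 = -ev(1).real();
    k1(i) = std::max(l1, l2);
    k2(i) = std::min(l1, l2);
    gauss(i) = k1(i) * k2(i);
    arma::vec nf = (nv - hu * e1 - hv * e2) / W;
    nf /= arma::norm(nf);
    nfit.row(i) = nf.t();
  }

  return List::create(_["kappa1"] = k1, _["kappa2"] = k2,
                      _["gaussian"] = gauss, _["normal"] = nfit,
                      _["n_neighbors"] = nnb);
}
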