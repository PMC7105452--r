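#ifndef CARDIOEM_FEM_COMMON_H
#define CARDIOEM_FEM_COMMON_H

#include <RcppArmadillo.h>

// Shared mesh/basis plumbing for the assembly kernels. Basis tables are
// precomputed in R (reference-element values and gradients at quadrature
// points) and passed in; the kernels only apply the affine geometry map.

namespace cem {

struct BasisTables {
  arma::mat phi;    // nq x nb
  arma::cube dphi;  // nq x nb x d (reference gradients)
  arma::vec qw;     // nq
  int nq, nb, d;
};

inline BasisTables tables_from_list(const Rcpp::List& tb) {
  BasisTables t;
  t.phi = Rcpp::as<arma::mat>(tb["phi"]);
  t.dphi = Rcpp::as<arma::cube>(tb["dphi"]);
  t.qw = Rcpp::as<arma::vec>(tb["qw"]);
  t.nq = t.phi.n_rows;
  t.nb = t.phi.n_cols;
  t.d = t.dphi.n_slices;
  return t;
}

struct CellGeom {
  arma::mat Jg, Jginv;
  double detJ;
  arma::rowvec x0;
};

// Affine geometry of a simplex cell: x = x0 + Jg * xref
inline CellGeom cell_geom(const arma::mat& coords, const arma::uvec& verts) {
  CellGeom g;
  int d = coords.n_cols;
  g.x0 = coords.row(verts(0));
  g.Jg.set_size(d, d);
  for (int j = 0; j < d; ++j)
    g.Jg.col(j) = (coords.row(verts(j + 1)) - g.x0).t();
  g.detJ = arma::det(g.Jg);
  g.Jginv = arma::inv(g.Jg);
  return g;
}

// Physical gradients of all basis functions at quadrature point q: nb x d
inline arma::mat phys_grads(const BasisTables& t, const CellGeom& g, int q) {
  arma::mat gr(t.nb, t.d);
  for (int b = 0; b < t.nb; ++b)
    for (int k = 0; k < t.d; ++k) {
      double s = 0.0;
      for (int m = 0; m < t.d; ++m) s += t.dphi(q, b, m) * g.Jginv(m, k);
      gr(b, k) = s;
    }
  return gr;
}

struct Triplets {
  std::vector<int> i, j;
  std::vector<double> x;
  void add(int ii, int jj, double v) {
    if (v != 0.0) { i.push_back(ii); j.push_back(jj); x.push_back(v); }
  }
  Rcpp::List as_list() const {
    return Rcpp::List::create(Rcpp::_["i"] = i, Rcpp::_["j"] = j,
                              Rcpp::_["x"] = x);
  }
};

}  // namespace cem

#endif
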