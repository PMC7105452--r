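#ifndef CARDIOEM_MECH_COMMON_H
#define CARDIOEM_MECH_COMMON_H

#include "pointwise.h"
#include "fem_common.h"

namespace cem {

struct MechParams {
  int mode;       // 0 active stress, 1 active strain
  int mat;        // 0 Holzapfel-Ogden, 1 Guccione
  Frame fr;
  HOParams ho;
  GuccioneParams guc;
  ActiveStressParams ap;
  double K0, delta, beta, rho0;
  double c_a, c_v;  // Newmark acceleration/velocity factors (0 = static)
};

inline MechParams mech_params(const Rcpp::List& pl) {
  MechParams mp;
  mp.mode = Rcpp::as<int>(pl["mode"]);
  mp.mat = Rcpp::as<int>(pl["mat"]);
  mp.fr = make_frame(Rcpp::as<arma::vec>(pl["f0"]),
                     Rcpp::as<arma::vec>(pl["s0"]));
  Rcpp::List ho = pl["ho"];
  mp.ho.a = ho["a"]; mp.ho.b = ho["b"]; mp.ho.af = ho["af"];
  mp.ho.bf = ho["bf"]; mp.ho.as = ho["as"]; mp.ho.bs = ho["bs"];
  mp.ho.afs = ho["afs"]; mp.ho.bfs = ho["bfs"];
  if (ho.containsElementNamed("gated"))
    mp.ho.gated = Rcpp::as<bool>(ho["gated"]);
  if (pl.containsElementNamed("guccione")) {
    Rcpp::List g = pl["guccione"];
    mp.guc.a = g["a"]; mp.guc.bf = g["bf"]; mp.guc.bt = g["bt"];
    mp.guc.bfs = g["bfs"];
  } else { mp.guc.a = 0; mp.guc.bf = mp.guc.bt = mp.guc.bfs = 1; }
  mp.ap.ksn = Rcpp::as<double>(pl["ksn"]);
  mp.ap.knn = Rcpp::as<double>(pl["knn"]);
  mp.K0 = Rcpp::as<double>(pl["K0"]);
  mp.delta = Rcpp::as<double>(pl["delta"]);
  mp.beta = Rcpp::as<double>(pl["beta"]);
  mp.rho0 = Rcpp::as<double>(pl["rho0"]);
  mp.c_a = Rcpp::as<double>(pl["c_a"]);
  mp.c_v = Rcpp::as<double>(pl["c_v"]);
  return mp;
}

// Pressure-free Kirchhoff contribution G at one material point
inline arma::mat kirchhoff_G(const MechParams& mp, const arma::mat& F,
                             double act, const arma::mat& Fdot,
                             bool with_visc) {
  Kinematics k = kinematics(F, mp.fr);
  arma::mat G;
  if (mp.mat == 1) {
    G = pk1_guccione(F, 0.0, mp.fr, mp.guc) * F.t();
    if (mp.mode == 0 && act != 0.0)
      G += pk1_active(k, act, mp.fr, mp.ap) * F.t();
  } else if (mp.mode == 0) {
    G = dpsi_dF_ho(k, mp.fr, mp.ho) * F.t();
    if (act != 0.0) G += pk1_active(k, act, mp.fr, mp.ap) * F.t();
  } else {
    ActiveStrain as_ = active_strain_tensors(act, mp.fr, mp.K0);
    Kinematics kE = kinematics(F * as_.FAinv, mp.fr);
    G = (dpsi_dF_ho(kE, mp.fr, mp.ho) * as_.FAinv.t()) * F.t();
  }
  if (with_visc && mp.delta != 0.0) {
    arma::mat Bdot = Fdot * F.t() + F * Fdot.t();
    G += k.J * sigma_viscous(Bdot, mp.delta, mp.beta);
  }
  return G;
}

// L2 projection of per-quadrature-point tensors onto the cell-local
// degree-l space spanned by piPhi columns; returns the projected values
// back at the quadrature points.
inline void project_pi(const arma::mat& piPhi, const arma::vec& qw,
                       const std::vector<arma::mat>& Sq,
                       std::vector<arma::mat>& Pi) {
  int nq = Sq.size(), nbPi = piPhi.n_cols;
  int d = Sq[0].n_rows;
  if (nbPi == 1) {
    arma::mat Pi0(d, d, arma::fill::zeros);
    double ws = 0.0;
    for (int q = 0; q < nq; ++q) { Pi0 += qw(q) * Sq[q]; ws += qw(q); }
    Pi0 /= ws;
    for (int q = 0; q < nq; ++q) Pi[q] = Pi0;
    return;
  }
  arma::mat M(nbPi, nbPi, arma::fill::zeros);
  std::vector<arma::mat> b(nbPi, arma::mat(d, d, arma::fill::zeros));
  for (int q = 0; q < nq; ++q)
    for (int m = 0; m < nbPi; ++m) {
      for (int n = 0; n < nbPi; ++n)
        M(m, n) += qw(q) * piPhi(q, m) * piPhi(q, n);
      b[m] += qw(q) * piPhi(q, m) * Sq[q];
    }
  arma::mat Minv = arma::inv(M);
  for (int q = 0; q < nq; ++q) {
    arma::mat P(d, d, arma::fill::zeros);
    for (int m = 0; m < nbPi; ++m)
      for (int n = 0; n < nbPi; ++n) P += piPhi(q, m) * Minv(m, n) * b[n];
    Pi[q] = P;
  }
}

}  // namespace cem

#endif
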