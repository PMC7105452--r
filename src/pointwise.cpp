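// [[Rcpp::depends(RcppArmadillo)]]
#include "pointwise.h"

using namespace Rcpp;

cem::Frame frame_from_list(const List& fr) {
  arma::vec f0 = as<arma::vec>(fr["f0"]);
  arma::vec s0 = as<arma::vec>(fr["s0"]);
  return cem::make_frame(f0, s0);
}

cem::HOParams ho_from_list(const List& mp) {
  cem::HOParams p;
  p.a = mp["a"]; p.b = mp["b"];
  p.af = mp["af"]; p.bf = mp["bf"];
  p.as = mp["as"]; p.bs = mp["bs"];
  p.afs = mp["afs"]; p.bfs = mp["bfs"];
  if (mp.containsElementNamed("gated"))
    p.gated = Rcpp::as<bool>(mp["gated"]);
  return p;
}

cem::GuccioneParams guc_from_list(const List& gp) {
  cem::GuccioneParams g;
  g.a = gp["a"]; g.bf = gp["bf"]; g.bt = gp["bt"]; g.bfs = gp["bfs"];
  return g;
}

// [[Rcpp::export(name = ".cpp_kinematics")]]
List cpp_kinematics(const arma::mat& F, const List& frame) {
  cem::Frame fr = frame_from_list(frame);
  cem::Kinematics k = cem::kinematics(F, fr);
  return List::create(_["F"] = k.F, _["J"] = k.J, _["C"] = k.C, _["B"] = k.B,
                      _["I1"] = k.I1, _["I4f"] = k.I4f, _["I4s"] = k.I4s,
                      _["I4n"] = k.I4n, _["I8fs"] = k.I8fs,
                      _["lambda_f"] = k.lamf, _["lambda_s"] = k.lams,
                      _["lambda_n"] = k.lamn);
}

// [[Rcpp::export(name = ".cpp_psi_ho")]]
double cpp_psi_ho(const arma::mat& F, const List& frame, const List& params) {
  return cem::psi_ho(F, frame_from_list(frame), ho_from_list(params));
}

// [[Rcpp::export(name = ".cpp_pk1_ho")]]
arma::mat cpp_pk1_ho(const arma::mat& F, double p, const List& frame,
                     const List& params) {
  return cem::pk1_ho(F, p, frame_from_list(frame), ho_from_list(params));
}

// [[Rcpp::export(name = ".cpp_sigma_active")]]
arma::mat cpp_sigma_active(const arma::mat& F, double Ta, const List& frame,
                           double ksn, double knn) {
  cem::Frame fr = frame_from_list(frame);
  cem::Kinematics k = cem::kinematics(F, fr);
  cem::ActiveStressParams ap; ap.ksn = ksn; ap.knn = knn;
  return cem::sigma_active(k, Ta, fr, ap);
}

// [[Rcpp::export(name = ".cpp_pk1_active")]]
arma::mat cpp_pk1_active(const arma::mat& F, double Ta, const List& frame,
                         double ksn, double knn) {
  cem::Frame fr = frame_from_list(frame);
  cem::Kinematics k = cem::kinematics(F, fr);
  cem::ActiveStressParams ap; ap.ksn = ksn; ap.knn = knn;
  return cem::pk1_active(k, Ta, fr, ap);
}

// [[Rcpp::export(name = ".cpp_active_strain_tensors")]]
List cpp_active_strain_tensors(double xi, const List& frame, double K0) {
  cem::Frame fr = frame_from_list(frame);
  cem::ActiveStrain as = cem::active_strain_tensors(xi, fr, K0);
  return List::create(_["FA"] = as.FA, _["FAinv"] = as.FAinv,
                      _["detFA"] = as.detFA, _["gamma_f"] = as.gf,
                      _["gamma_s"] = as.gs, _["gamma_n"] = as.gn);
}

// [[Rcpp::export(name = ".cpp_psi_active_strain")]]
double cpp_psi_active_strain(const arma::mat& F, double xi, const List& frame,
                             const List& params, double K0) {
  return cem::psi_active_strain(F, xi, frame_from_list(frame),
                                ho_from_list(params), K0);
}

// [[Rcpp::export(name = ".cpp_pk1_active_strain")]]
arma::mat cpp_pk1_active_strain(const arma::mat& F, double xi, double p,
                                const List& frame, const List& params,
                                double K0) {
  return cem::pk1_active_strain(F, xi, p, frame_from_list(frame),
                                ho_from_list(params), K0);
}

// [[Rcpp::export(name = ".cpp_sigma_viscous")]]
arma::mat cpp_sigma_viscous(const arma::mat& Bdot, double delta, double beta) {
  return cem::sigma_viscous(Bdot, delta, beta);
}

// [[Rcpp::export(name = ".cpp_psi_guccione")]]
double cpp_psi_guccione(const arma::mat& F, const List& frame,
                        const List& params) {
  return cem::psi_guccione(F, frame_from_list(frame), guc_from_list(params));
}

// [[Rcpp::export(name = ".cpp_pk1_guccione")]]
arma::mat cpp_pk1_guccione(const arma::mat& F, double p, const List& frame,
                           const List& params) {
  return cem::pk1_guccione(F, p, frame_from_list(frame), guc_from_list(params));
}

// Kirchhoff stress split: G (pressure-free part) and Pi = G - p J I.
// mode: 0 = active stress (activation = Ta), 1 = active strain
// (activation = xi). Bdot may be a zero matrix for static states.
// [[Rcpp::export(name = ".cpp_kirchhoff")]]
List cpp_kirchhoff(int mode, const arma::mat& F, double p, double activation,
                   const arma::mat& Bdot, const List& frame,
                   const List& params, double ksn, double knn, double K0,
                   double delta, double beta) {
  cem::Frame fr = frame_from_list(frame);
  cem::HOParams mp = ho_from_list(params);
  cem::Kinematics k = cem::kinematics(F, fr);
  arma::mat G;
  if (mode == 0) {
    cem::ActiveStressParams ap; ap.ksn = ksn; ap.knn = knn;
    G = cem::dpsi_dF_ho(k, fr, mp) * F.t() +
        cem::pk1_active(k, activation, fr, ap) * F.t();
  } else {
    cem::ActiveStrain as = cem::active_strain_tensors(activation, fr, K0);
    arma::mat FE = F * as.FAinv;
    cem::Kinematics kE = cem::kinematics(FE, fr);
    G = (cem::dpsi_dF_ho(kE, fr, mp) * as.FAinv.t()) * F.t();
  }
  if (delta != 0.0) G += k.J * cem::sigma_viscous(Bdot, delta, beta);
  arma::mat Pi = G - p * k.J * arma::eye(fr.d, fr.d);
  return List::create(_["G"] = G, _["Pi"] = Pi);
}

// [[Rcpp::export(name = ".cpp_conductivity")]]
arma::mat cpp_conductivity(double v, const arma::mat& F, const arma::mat& Pi,
                           const List& frame, double D0, double D1, double D2,
                           bool fibre_over_J) {
  cem::Frame fr = frame_from_list(frame);
  cem::CondParams cp; cp.D0 = D0; cp.D1 = D1; cp.D2 = D2;
  cp.fibre_over_J = fibre_over_J;
  return cem::conductivity(v, F, Pi, fr, cp);
}
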