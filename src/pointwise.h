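#ifndef CARDIOEM_POINTWISE_H
#define CARDIOEM_POINTWISE_H

#include <RcppArmadillo.h>

// Pointwise kinematics and constitutive laws shared by the exported R
// wrappers and the element assembly kernels. All tensors are d x d
// (d = 2 or 3); stresses are in internal kPa units, lengths mm, time ms.

namespace cem {

struct Frame {
  arma::vec f0, s0, n0;  // n0 empty in 2D
  int d;
};

inline Frame make_frame(const arma::vec& f0, const arma::vec& s0) {
  Frame fr;
  fr.f0 = f0; fr.s0 = s0; fr.d = f0.n_elem;
  if (fr.d == 3) fr.n0 = arma::cross(f0, s0);
  return fr;
}

struct HOParams {   // Holzapfel-Ogden moduli (kPa) and exponents (-)
  double a, b, af, bf, as, bs, afs, bfs;
  bool gated = true;  // (I4 - 1)_+ compression switch-off
};

struct ActiveStressParams { double ksn, knn; };

struct GuccioneParams { double a, bf, bt, bfs; };

struct Kinematics {
  arma::mat F, C, B, Finv;
  double J, I1, I4f, I4s, I4n, I8fs, lamf, lams, lamn;
};

inline Kinematics kinematics(const arma::mat& F, const Frame& fr) {
  Kinematics k;
  k.F = F;
  k.J = arma::det(F);
  if (!(k.J > 0.0)) Rcpp::stop("inverted element: det F = %g <= 0", k.J);
  k.C = F.t() * F;
  k.B = F * F.t();
  k.Finv = arma::inv(F);
  k.I1 = arma::trace(k.C);
  k.I4f = arma::as_scalar(fr.f0.t() * k.C * fr.f0);
  k.I4s = arma::as_scalar(fr.s0.t() * k.C * fr.s0);
  k.I8fs = arma::as_scalar(fr.f0.t() * k.C * fr.s0);
  k.I4n = (fr.d == 3) ? arma::as_scalar(fr.n0.t() * k.C * fr.n0) : 1.0;
  k.lamf = std::sqrt(k.I4f);
  k.lams = std::sqrt(k.I4s);
  k.lamn = std::sqrt(k.I4n);
  return k;
}

// (u)_+ with strict positivity: zero at u = 0 and below
inline double pos(double u) { return u > 0.0 ? u : 0.0; }

// Holzapfel-Ogden strain energy; anisotropic terms gated by (I4 - 1)_+
inline double psi_ho(const arma::mat& F, const Frame& fr, const HOParams& mp) {
  Kinematics k = kinematics(F, fr);
  double d = (double)fr.d;
  double psi = mp.a / (2.0 * mp.b) * std::exp(mp.b * (k.I1 - d));
  double gf = mp.gated ? pos(k.I4f - 1.0) : k.I4f - 1.0;
  double gs = mp.gated ? pos(k.I4s - 1.0) : k.I4s - 1.0;
  psi += mp.af / (2.0 * mp.bf) * (std::exp(mp.bf * gf * gf) - 1.0);
  psi += mp.as / (2.0 * mp.bs) * (std::exp(mp.bs * gs * gs) - 1.0);
  psi += mp.afs / (2.0 * mp.bfs) * (std::exp(mp.bfs * k.I8fs * k.I8fs) - 1.0);
  return psi;
}

// dPsi/dF for the Holzapfel-Ogden law (no pressure term)
inline arma::mat dpsi_dF_ho(const Kinematics& k, const Frame& fr,
                            const HOParams& mp) {
  double d = (double)fr.d;
  arma::mat P = mp.a * std::exp(mp.b * (k.I1 - d)) * k.F;
  double gf = mp.gated ? pos(k.I4f - 1.0) : k.I4f - 1.0;
  double gs = mp.gated ? pos(k.I4s - 1.0) : k.I4s - 1.0;
  if (gf != 0.0)
    P += 2.0 * mp.af * gf * std::exp(mp.bf * gf * gf) *
         (k.F * fr.f0) * fr.f0.t();
  if (gs != 0.0)
    P += 2.0 * mp.as * gs * std::exp(mp.bs * gs * gs) *
         (k.F * fr.s0) * fr.s0.t();
  P += mp.afs * k.I8fs * std::exp(mp.bfs * k.I8fs * k.I8fs) *
       ((k.F * fr.s0) * fr.f0.t() + (k.F * fr.f0) * fr.s0.t());
  return P;
}

// First Piola-Kirchhoff stress, passive HO law: dPsi/dF - p J F^{-t}
inline arma::mat pk1_ho(const arma::mat& F, double p, const Frame& fr,
                        const HOParams& mp) {
  Kinematics k = kinematics(F, fr);
  return dpsi_dF_ho(k, fr, mp) - p * k.J * k.Finv.t();
}

// Active Cauchy stress (active stress formulation); no s0 x s0 diagonal term.
// In 2D only the fibre term survives (n0 is undefined).
inline arma::mat sigma_active(const Kinematics& k, double Ta, const Frame& fr,
                              const ActiveStressParams& ap) {
  if (!(k.lamf > 0.0) || !(k.lams > 0.0) || !(k.lamn > 0.0))
    Rcpp::stop("active stress: zero direction stretch");
  arma::vec Ff = k.F * fr.f0;
  arma::mat s = (Ta / (k.J * k.lamf)) * (Ff * Ff.t());
  if (fr.d == 3) {
    arma::vec Fs = k.F * fr.s0, Fn = k.F * fr.n0;
    arma::mat sn = Fs * Fn.t();
    s += (ap.ksn * Ta / (k.J * k.lams * k.lamn)) * 0.5 * (sn + sn.t());
    s += (ap.knn * Ta / (k.J * k.lamn)) * (Fn * Fn.t());
  }
  return s;
}

inline arma::mat pk1_active(const Kinematics& k, double Ta, const Frame& fr,
                            const ActiveStressParams& ap) {
  return k.J * sigma_active(k, Ta, fr, ap) * k.Finv.t();
}

// Active strain: gamma_f = xi, gamma_s = (1+xi)^{-1}(1+K0 xi)^{-1} - 1,
// gamma_n = K0 xi; det F_A = 1 by construction.
struct ActiveStrain {
  arma::mat FA, FAinv;
  double detFA, gf, gs, gn;
};

inline ActiveStrain active_strain_tensors(double xi, const Frame& fr,
                                          double K0) {
  ActiveStrain as;
  as.gf = xi;
  as.gs = 1.0 / ((1.0 + xi) * (1.0 + K0 * xi)) - 1.0;
  as.gn = K0 * xi;
  if (1.0 + as.gf <= 0.0 || 1.0 + as.gs <= 0.0 || 1.0 + as.gn <= 0.0)
    Rcpp::stop("degenerate activation: 1 + gamma_i <= 0 at xi = %g", xi);
  int d = fr.d;
  as.FA.eye(d, d);
  as.FAinv.eye(d, d);
  as.FA += as.gf * (fr.f0 * fr.f0.t());
  as.FAinv -= as.gf / (1.0 + as.gf) * (fr.f0 * fr.f0.t());
  as.FA += as.gs * (fr.s0 * fr.s0.t());
  as.FAinv -= as.gs / (1.0 + as.gs) * (fr.s0 * fr.s0.t());
  if (d == 3) {
    as.FA += as.gn * (fr.n0 * fr.n0.t());
    as.FAinv -= as.gn / (1.0 + as.gn) * (fr.n0 * fr.n0.t());
  }
  as.detFA = arma::det(as.FA);
  return as;
}

// Active strain energy evaluated through F_E = F F_A^{-1} directly
inline double psi_active_strain(const arma::mat& F, double xi,
                                const Frame& fr, const HOParams& mp,
                                double K0) {
  ActiveStrain as = active_strain_tensors(xi, fr, K0);
  return psi_ho(F * as.FAinv, fr, mp);
}

// P = dPsihat/dF - p J F^{-t} = [dPsi/dF_E] F_A^{-t} - p J F^{-t}
inline arma::mat pk1_active_strain(const arma::mat& F, double xi, double p,
                                   const Frame& fr, const HOParams& mp,
                                   double K0) {
  ActiveStrain as = active_strain_tensors(xi, fr, K0);
  arma::mat FE = F * as.FAinv;
  Kinematics kE = kinematics(FE, fr);
  arma::mat PE = dpsi_dF_ho(kE, fr, mp);
  double J = arma::det(F);
  if (!(J > 0.0)) Rcpp::stop("inverted element: det F <= 0");
  return PE * as.FAinv.t() - p * J * arma::inv(F).t();
}

// Kelvin-Voigt viscous Cauchy stress sigma = delta * exp(beta tr(Bdot)) * Bdot
inline arma::mat sigma_viscous(const arma::mat& Bdot, double delta,
                               double beta) {
  return delta * std::exp(beta * arma::trace(Bdot)) * Bdot;
}

// Guccione transversally isotropic law (fibre-frame Green-Lagrange strain)
inline double psi_guccione(const arma::mat& F, const Frame& fr,
                           const GuccioneParams& gp) {
  int d = fr.d;
  arma::mat E = 0.5 * (F.t() * F - arma::eye(d, d));
  arma::mat R(d, d);
  R.col(0) = fr.f0; R.col(1) = fr.s0;
  if (d == 3) R.col(2) = fr.n0;
  arma::mat Et = R.t() * E * R;  // (f,s,n) components
  double Q = gp.bf * Et(0, 0) * Et(0, 0);
  Q += gp.bt * Et(1, 1) * Et(1, 1);
  Q += gp.bfs * (Et(0, 1) * Et(0, 1) + Et(1, 0) * Et(1, 0));
  if (d == 3) {
    Q += gp.bt * (Et(2, 2) * Et(2, 2) + Et(1, 2) * Et(1, 2) +
                  Et(2, 1) * Et(2, 1));
    Q += gp.bfs * (Et(0, 2) * Et(0, 2) + Et(2, 0) * Et(2, 0));
  }
  return 0.5 * gp.a * (std::exp(Q) - 1.0);
}

inline arma::mat pk1_guccione(const arma::mat& F, double p, const Frame& fr,
                              const GuccioneParams& gp) {
  int d = fr.d;
  double J = arma::det(F);
  if (!(J > 0.0)) Rcpp::stop("inverted element: det F <= 0");
  arma::mat E = 0.5 * (F.t() * F - arma::eye(d, d));
  arma::mat R(d, d);
  R.col(0) = fr.f0; R.col(1) = fr.s0;
  if (d == 3) R.col(2) = fr.n0;
  arma::mat Et = R.t() * E * R;
  double Q = gp.bf * Et(0, 0) * Et(0, 0) + gp.bt * Et(1, 1) * Et(1, 1) +
             gp.bfs * (Et(0, 1) * Et(0, 1) + Et(1, 0) * Et(1, 0));
  arma::mat W(d, d, arma::fill::zeros);
  W(0, 0) = 2.0 * gp.bf * Et(0, 0);
  W(1, 1) = 2.0 * gp.bt * Et(1, 1);
  W(0, 1) = 2.0 * gp.bfs * Et(0, 1);
  W(1, 0) = 2.0 * gp.bfs * Et(1, 0);
  if (d == 3) {
    Q += gp.bt * (Et(2, 2) * Et(2, 2) + Et(1, 2) * Et(1, 2) +
                  Et(2, 1) * Et(2, 1));
    Q += gp.bfs * (Et(0, 2) * Et(0, 2) + Et(2, 0) * Et(2, 0));
    W(2, 2) = 2.0 * gp.bt * Et(2, 2);
    W(1, 2) = 2.0 * gp.bt * Et(1, 2);
    W(2, 1) = 2.0 * gp.bt * Et(2, 1);
    W(0, 2) = 2.0 * gp.bfs * Et(0, 2);
    W(2, 0) = 2.0 * gp.bfs * Et(2, 0);
  }
  // S = dPsi/dE (2nd Piola-Kirchhoff), P = F S - p J F^{-t}
  arma::mat S = 0.5 * gp.a * std::exp(Q) * (R * W * R.t());
  return F * S - p * J * arma::inv(F).t();
}

// Stress-assisted, deformation-dependent conductivity tensor (internal units
// mm^2/ms; Pi is expected in the diffusion stress unit, see R wrapper)
struct CondParams {
  double D0, D1, D2;
  bool fibre_over_J;  // alternative (D0/(2J)) reading of the fibre term
};

inline arma::mat conductivity(double v, const arma::mat& F,
                              const arma::mat& Pi, const Frame& fr,
                              const CondParams& cp) {
  double J = arma::det(F);
  if (!(J > 0.0)) Rcpp::stop("inverted element: det F <= 0");
  arma::mat Finv = arma::inv(F);
  arma::mat Cinv = Finv * Finv.t();
  double fib = cp.fibre_over_J ? cp.D0 / (2.0 * J) : 0.5 * cp.D0 * J;
  arma::mat D = (cp.D0 + cp.D1 * v) * J * Cinv +
                fib * (fr.f0 * fr.f0.t()) +
                cp.D2 * J * Finv * Pi * Finv.t();
  return 0.5 * (D + D.t());  // symmetric up to round-off by construction
}

}  // namespace cem

#endif
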