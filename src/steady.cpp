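// [[Rcpp::depends(RcppArmadillo)]]
#include "mech_common.h"

using namespace Rcpp;
using namespace cem;

// ---------------------------------------------------------------------------
// Steady manufactured-solution electromechanics on the unit square
// (active stress, no viscosity), used by the convergence driver.
// Closed-form fields; fibre frame f0 = (0,1), s0 = (-1,0).
// Simplified kinetics: m(v,r) = v - r^2, g(v,r) = (v-1) v r,
// l(Ta,r) = -Ta + r.
//
// Global unknowns: u, p, v, Ta (continuous degree l+1). The gating field r
// lives in the cell-wise discontinuous degree-(l+1) space, as the weak form
// only asks r in L2; its cell-local algebraic equation
//   int_K (v - r^2 + f_r) phi = 0
// is eliminated per element by a local Newton iteration (the continuous
// choice degenerates on the zero set of the manufactured r).
// ---------------------------------------------------------------------------

struct ExactState {
  arma::vec u;
  arma::mat F;
  double p, v, r, Ta, J;
  arma::vec gradv;
};

static ExactState exact_state(double x, double y) {
  ExactState s;
  const double pi = M_PI;
  double sx = std::sin(pi * x), cx = std::cos(pi * x);
  double sy = std::sin(pi * y), cy = std::cos(pi * y);
  s.u = {0.1 * sx * cy, 0.1 * cx * sy};
  s.F = {{1.0 + 0.1 * pi * cx * cy, -0.1 * pi * sx * sy},
         {-0.1 * pi * sx * sy, 1.0 + 0.1 * pi * cx * cy}};
  s.p = 0.1 * sx * sy;
  s.v = 1.0 + 0.1 * cx * cy;
  s.gradv = {-0.1 * pi * sx * cy, -0.1 * pi * cx * sy};
  s.r = 0.1 * cx * sx * sy;
  s.Ta = 1.0 + 0.1 * cx * sy;
  s.J = arma::det(s.F);
  return s;
}

struct SteadyParams {
  MechParams mp;
  CondParams cp;
  double alpha_hat;
};

static SteadyParams steady_params(const List& pl) {
  SteadyParams sp;
  sp.mp = mech_params(pl);
  List cd = pl["cond"];
  sp.cp.D0 = cd["D0"]; sp.cp.D1 = cd["D1"]; sp.cp.D2 = cd["D2"];
  sp.cp.fibre_over_J = as<bool>(cd["fibre_over_J"]);
  sp.alpha_hat = as<double>(pl["alpha_hat"]);
  return sp;
}

// Exact Kirchhoff stress (continuous, unprojected)
static arma::mat exact_pi(const SteadyParams& sp, const ExactState& s) {
  arma::mat Fdot(2, 2, arma::fill::zeros);
  arma::mat G = kirchhoff_G(sp.mp, s.F, s.Ta, Fdot, false);
  return G - s.p * s.J * arma::eye(2, 2);
}

// [[Rcpp::export(name = ".manufactured_exact")]]
List manufactured_exact(const arma::mat& pts, const List& params) {
  SteadyParams sp = steady_params(params);
  int n = pts.n_rows;
  arma::mat u(n, 2), Pi(n, 4);
  arma::vec p(n), v(n), r(n), Ta(n), J(n);
  for (int i = 0; i < n; ++i) {
    ExactState s = exact_state(pts(i, 0), pts(i, 1));
    u.row(i) = s.u.t();
    p(i) = s.p; v(i) = s.v; r(i) = s.r; Ta(i) = s.Ta; J(i) = s.J;
    Pi.row(i) = arma::vectorise(exact_pi(sp, s)).t();
  }
  return List::create(_["u"] = u, _["p"] = p, _["v"] = v, _["r"] = r,
                      _["Ta"] = Ta, _["J"] = J, _["Pi"] = Pi);
}

// Forcing terms so that the closed forms solve the steady coupled system:
// f_u = -div(Pi F^{-t}), J_ex, f_v = -div(D grad v) - g(v,r),
// f_r = -m(v,r), f_Ta = -alpha_hat Lap(Ta) - l(Ta,r).
// Divergences by central differences of the closed-form fluxes.
// [[Rcpp::export(name = ".manufactured_forcing")]]
List manufactured_forcing(const arma::mat& pts, const List& params,
                          double h) {
  SteadyParams sp = steady_params(params);
  const double pi = M_PI;
  int n = pts.n_rows;
  arma::mat fu(n, 2);
  arma::vec Jex(n), fv(n), fr(n), fTa(n);

  auto mechflux = [&](double x, double y) {
    ExactState s = exact_state(x, y);
    return arma::mat(exact_pi(sp, s) * arma::inv(s.F).t());
  };
  auto elecflux = [&](double x, double y) {
    ExactState s = exact_state(x, y);
    arma::mat D = conductivity(s.v, s.F, exact_pi(sp, s), sp.mp.fr, sp.cp);
    return arma::vec(D * s.gradv);
  };

  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1);
    ExactState s = exact_state(x, y);
    Jex(i) = s.J;
    arma::mat Mxp = mechflux(x + h, y), Mxm = mechflux(x - h, y);
    arma::mat Myp = mechflux(x, y + h), Mym = mechflux(x, y - h);
    for (int k = 0; k < 2; ++k)
      fu(i, k) = -((Mxp(k, 0) - Mxm(k, 0)) + (Myp(k, 1) - Mym(k, 1))) /
                 (2.0 * h);
    arma::vec Nxp = elecflux(x + h, y), Nxm = elecflux(x - h, y);
    arma::vec Nyp = elecflux(x, y + h), Nym = elecflux(x, y - h);
    double divN = ((Nxp(0) - Nxm(0)) + (Nyp(1) - Nym(1))) / (2.0 * h);
    fv(i) = -divN - (s.v - 1.0) * s.v * s.r;
    fr(i) = -(s.v - s.r * s.r);
    double lapTa = -0.2 * pi * pi * std::cos(pi * x) * std::sin(pi * y);
    fTa(i) = -sp.alpha_hat * lapTa - (-s.Ta + s.r);
  }
  return List::create(_["fu"] = fu, _["Jex"] = Jex, _["fv"] = fv,
                      _["fr"] = fr, _["fTa"] = fTa);
}

// Cell-local gating solve: find r_loc (coefficients on the local basis)
// with sum_q w_q phi_a(q) [v_q - r(q)^2 + f_q] = 0 for all a.
// Newton from r_init; the local Jacobian -2 sum w phi_a phi_b r_q is
// nonsingular because r keeps one sign inside a cell.
// Damped Gauss-Newton (Levenberg) iteration: deterministic and monotone in
// |g|; in cells crossed by the zero set of r the local system may have no
// exact root (the quadratic moment map need not cover the target), in which
// case the least-squares argmin is returned (its defect is a localised
// O(h^{l+2}) perturbation of the gating equation).
// Pointwise gating elimination: at each quadrature point the steady gating
// relation v - r^2 + f_r = 0 is solved on the branch of the exact field,
//   r_q = s_q sqrt(max(v_q + f_q, 0) + eps^2),
// with s_q the sign of the manufactured r at that point and a small
// smoothing eps that bounds the square root's derivative at the branch
// point. This matches the quadrature-point storage of internal variables
// used by the transient solver and keeps the elimination deterministic.
static const double kREps2 = 1e-12;

static inline double elim_r(double s, double arg) {
  return s * std::sqrt(std::max(arg, 0.0) + kREps2);
}
static inline double elim_drdv(double s, double arg) {
  if (arg <= 0.0) return 0.0;
  return s / (2.0 * std::sqrt(arg + kREps2));
}

// Element residual of the monolithic steady system.
// zl = [u (2nb); p (nb); v (nb); Ta (nb)], r eliminated locally.
static arma::vec steady_elem_res(const SteadyParams& sp,
                                 const BasisTables& tb,
                                 const arma::mat& piPhi, const CellGeom& g,
                                 const std::vector<arma::mat>& gr,
                                 const arma::vec& zl, const arma::mat& fu,
                                 const arma::vec& Jex, const arma::vec& fv,
                                 const arma::vec& fr, const arma::vec& fTa,
                                 const arma::vec& rsgn,
                                 const arma::vec* r_frozen = nullptr) {
  int nb = tb.nb, nq = tb.nq;
  const int d = 2;
  arma::vec res(nb * 5, arma::fill::zeros);
  int op = 2 * nb, ov = 3 * nb, oTa = 4 * nb;

  std::vector<arma::mat> Finvt(nq), Sq(nq), Fq(nq);
  arma::vec Jq(nq), pq(nq), vq(nq), Taq(nq);
  arma::mat gvq(nq, d), gTaq(nq, d);

  for (int q = 0; q < nq; ++q) {
    arma::mat gradu(d, d, arma::fill::zeros);
    double pv = 0, vv = 0, Tav = 0;
    arma::vec gv(d, arma::fill::zeros), gTa(d, arma::fill::zeros);
    for (int a = 0; a < nb; ++a) {
      for (int k = 0; k < d; ++k)
        for (int j = 0; j < d; ++j)
          gradu(k, j) += zl(a * d + k) * gr[q](a, j);
      pv += tb.phi(q, a) * zl(op + a);
      vv += tb.phi(q, a) * zl(ov + a);
      Tav += tb.phi(q, a) * zl(oTa + a);
      gv += zl(ov + a) * gr[q].row(a).t();
      gTa += zl(oTa + a) * gr[q].row(a).t();
    }
    arma::mat F = arma::eye(d, d) + gradu;
    double J = arma::det(F);
    if (!(J > 0.0)) stop("inverted element at quadrature point");
    Fq[q] = F;
    Finvt[q] = arma::inv(F).t();
    Jq(q) = J; pq(q) = pv; vq(q) = vv; Taq(q) = Tav;
    gvq.row(q) = gv.t();
    gTaq.row(q) = gTa.t();
    arma::mat Fdot(d, d, arma::fill::zeros);
    arma::mat G = kirchhoff_G(sp.mp, F, Tav, Fdot, false);
    Sq[q] = G - pv * J * arma::eye(d, d);
  }
  std::vector<arma::mat> Pi(nq);
  project_pi(piPhi, tb.qw, Sq, Pi);

  // pointwise gating elimination (frozen during FD sweeps)
  arma::vec rq(nq);
  if (r_frozen) rq = *r_frozen;
  else for (int q = 0; q < nq; ++q)
    rq(q) = elim_r(rsgn(q), vq(q) + fr(q));

  for (int q = 0; q < nq; ++q) {
    double wdet = tb.qw(q) * g.detJ;
    arma::mat PiFt = Pi[q] * Finvt[q];
    arma::mat D = conductivity(vq(q), Fq[q], Pi[q], sp.mp.fr, sp.cp);
    arma::vec Dgv = D * gvq.row(q).t();
    double gre = (vq(q) - 1.0) * vq(q) * rq(q) + fv(q);
    double lre = (-Taq(q) + rq(q)) + fTa(q);
    for (int a = 0; a < nb; ++a) {
      double ph = tb.phi(q, a);
      for (int k = 0; k < d; ++k) {
        double rr = 0.0;
        for (int j = 0; j < d; ++j) rr += PiFt(k, j) * gr[q](a, j);
        res(a * d + k) += wdet * (rr - fu(q, k) * ph);
      }
      res(op + a) += wdet * (Jq(q) - Jex(q)) * ph;
      res(ov + a) +=
          wdet * (arma::dot(Dgv, gr[q].row(a).t()) - gre * ph);
      res(oTa + a) +=
          wdet * (sp.alpha_hat * arma::dot(gTaq.row(q), gr[q].row(a)) -
                  lre * ph);
    }
  }
  return res;
}

// [[Rcpp::export(name = ".asm_steady")]]
List asm_steady(const arma::mat& coords, const arma::imat& cells,
                const arma::imat& dof, const List& tables,
                const arma::mat& piPhi, const arma::vec& z,
                const List& params, const arma::mat& fu,
                const arma::vec& Jex, const arma::vec& fv,
                const arma::vec& fr, const arma::vec& fTa,
                const arma::vec& rsgn, bool jac, double eps) {
  BasisTables tb = tables_from_list(tables);
  SteadyParams sp = steady_params(params);
  const int d = 2;
  int nb = tb.nb, nc = cells.n_rows, nq = tb.nq, nn = dof.max();
  int nloc = 5 * nb;
  arma::vec res(5 * nn, arma::fill::zeros);
  Triplets tr;

  for (int e = 0; e < nc; ++e) {
    arma::uvec verts(d + 1);
    for (int i = 0; i <= d; ++i) verts(i) = cells(e, i) - 1;
    CellGeom g = cell_geom(coords, verts);
    std::vector<arma::mat> gr(nq);
    for (int q = 0; q < nq; ++q) gr[q] = phys_grads(tb, g, q);

    arma::ivec ldof(nb);
    arma::vec zl(nloc);
    std::vector<int> gidx(nloc);
    for (int a = 0; a < nb; ++a) {
      ldof(a) = dof(e, a) - 1;
      for (int k = 0; k < d; ++k) {
        zl(a * d + k) = z(ldof(a) * d + k);
        gidx[a * d + k] = ldof(a) * d + k;
      }
      for (int f = 0; f < 3; ++f) {  // p, v, Ta blocks
        zl((2 + f) * nb + a) = z((2 + f) * nn + ldof(a));
        gidx[(2 + f) * nb + a] = (2 + f) * nn + ldof(a);
      }
    }
    arma::mat fue = fu.rows(e * nq, (e + 1) * nq - 1);
    arma::vec Jexe = Jex.subvec(e * nq, (e + 1) * nq - 1);
    arma::vec fve = fv.subvec(e * nq, (e + 1) * nq - 1);
    arma::vec fre = fr.subvec(e * nq, (e + 1) * nq - 1);
    arma::vec fTae = fTa.subvec(e * nq, (e + 1) * nq - 1);
    arma::vec sgne = rsgn.subvec(e * nq, (e + 1) * nq - 1);

    auto rfun = [&](const arma::vec& zz, const arma::vec* rfix) {
      return steady_elem_res(sp, tb, piPhi, g, gr, zz, fue, Jexe, fve, fre,
                             fTae, sgne, rfix);
    };
    // base gating values (frozen during FD sweeps; chain added analytically)
    arma::vec vqb(nq), argb(nq), rbase(nq);
    for (int q = 0; q < nq; ++q) {
      double vv = 0;
      for (int a = 0; a < nb; ++a) vv += tb.phi(q, a) * zl(3 * nb + a);
      vqb(q) = vv;
      argb(q) = vv + fre(q);
      rbase(q) = elim_r(sgne(q), argb(q));
    }
    arma::vec r0 = rfun(zl, &rbase);
    for (int i = 0; i < nloc; ++i) res(gidx[i]) += r0(i);

    if (jac) {
      // FD sweep with the gating values frozen; their exact sensitivity to
      // v (too curved near the branch point for finite differences) is
      // added analytically below
      arma::vec zp = zl;
      for (int j = 0; j < nloc; ++j) {
        double h = eps * (1.0 + std::abs(zl(j)));
        zp(j) = zl(j) + h;
        arma::vec rp = rfun(zp, &rbase);
        zp(j) = zl(j) - h;
        arma::vec rm = rfun(zp, &rbase);
        zp(j) = zl(j);
        arma::vec col = (rp - rm) / (2.0 * h);
        for (int i = 0; i < nloc; ++i)
          if (col(i) != 0.0) tr.add(gidx[i], gidx[j], col(i));
      }
      // chain rule through r_q(v): Res_v gains -(v-1)v dr/dv, Res_Ta
      // gains -dr/dv, both mass-weighted
      for (int q = 0; q < nq; ++q) {
        double wdet = tb.qw(q) * g.detJ;
        double drdv = elim_drdv(sgne(q), argb(q));
        if (drdv == 0.0) continue;
        double cv = -(vqb(q) - 1.0) * vqb(q) * drdv;
        for (int a = 0; a < nb; ++a)
          for (int b = 0; b < nb; ++b) {
            double pp = tb.phi(q, a) * tb.phi(q, b) * wdet;
            tr.add(gidx[3 * nb + a], gidx[3 * nb + b], cv * pp);
            tr.add(gidx[4 * nb + a], gidx[3 * nb + b], -drdv * pp);
          }
      }
    }
  }
  return List::create(_["res"] = res, _["trip"] = tr.as_list());
}

// Eliminated gating field of the steady solution: values and gradients of
// the pointwise branch solution at the quadrature points. fgrad carries the
// analytic gradient of the gating forcing f_r.
// [[Rcpp::export(name = ".steady_r_qp")]]
List steady_r_qp(const arma::mat& coords, const arma::imat& cells,
                 const arma::imat& dof, const List& tables,
                 const arma::vec& z, const List& params,
                 const arma::vec& fr, const arma::mat& fgrad,
                 const arma::vec& rsgn) {
  BasisTables tb = tables_from_list(tables);
  const int d = 2;
  int nb = tb.nb, nc = cells.n_rows, nq = tb.nq, nn = dof.max();
  arma::vec rq_out(nc * nq);
  arma::mat gr_out(nc * nq, d);

  for (int e = 0; e < nc; ++e) {
    arma::uvec verts(d + 1);
    for (int i = 0; i <= d; ++i) verts(i) = cells(e, i) - 1;
    CellGeom g = cell_geom(coords, verts);
    std::vector<arma::mat> gr(nq);
    for (int q = 0; q < nq; ++q) gr[q] = phys_grads(tb, g, q);
    for (int q = 0; q < nq; ++q) {
      double vv = 0;
      arma::vec gv(d, arma::fill::zeros);
      for (int a = 0; a < nb; ++a) {
        double va = z(3 * nn + dof(e, a) - 1);
        vv += tb.phi(q, a) * va;
        gv += va * gr[q].row(a).t();
      }
      int row = e * nq + q;
      double arg = vv + fr(row);
      double s = rsgn(row);
      rq_out(row) = elim_r(s, arg);
      arma::vec garg = gv + fgrad.row(row).t();
      gr_out.row(row) = (elim_drdv(s, arg) * garg).t();
    }
  }
  return List::create(_["r"] = rq_out, _["grad"] = gr_out);
}

// Projected discrete Kirchhoff stress of the steady solution at the
// quadrature points (for error evaluation).
// [[Rcpp::export(name = ".steady_pi_qp")]]
arma::mat steady_pi_qp(const arma::mat& coords, const arma::imat& cells,
                       const arma::imat& dof, const List& tables,
                       const arma::mat& piPhi, const arma::vec& z,
                       const List& params) {
  BasisTables tb = tables_from_list(tables);
  SteadyParams sp = steady_params(params);
  const int d = 2;
  int nb = tb.nb, nc = cells.n_rows, nq = tb.nq, nn = dof.max();
  arma::mat out(nc * nq, 4);

  for (int e = 0; e < nc; ++e) {
    arma::uvec verts(d + 1);
    for (int i = 0; i <= d; ++i) verts(i) = cells(e, i) - 1;
    CellGeom g = cell_geom(coords, verts);
    std::vector<arma::mat> gr(nq);
    for (int q = 0; q < nq; ++q) gr[q] = phys_grads(tb, g, q);
    std::vector<arma::mat> Sq(nq);
    for (int q = 0; q < nq; ++q) {
      arma::mat gradu(d, d, arma::fill::zeros);
      double pv = 0, Tav = 0;
      for (int a = 0; a < nb; ++a) {
        int n = dof(e, a) - 1;
        for (int k = 0; k < d; ++k)
          for (int j = 0; j < d; ++j)
            gradu(k, j) += z(n * d + k) * gr[q](a, j);
        pv += tb.phi(q, a) * z(2 * nn + n);
        Tav += tb.phi(q, a) * z(4 * nn + n);
      }
      arma::mat F = arma::eye(d, d) + gradu;
      arma::mat Fdot(d, d, arma::fill::zeros);
      arma::mat G = kirchhoff_G(sp.mp, F, Tav, Fdot, false);
      Sq[q] = G - pv * arma::det(F) * arma::eye(d, d);
    }
    std::vector<arma::mat> Pi(nq);
    project_pi(piPhi, tb.qw, Sq, Pi);
    for (int q = 0; q < nq; ++q)
      out.row(e * nq + q) = arma::vectorise(Pi[q]).t();
  }
  return out;
}
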