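// [[Rcpp::depends(RcppArmadillo)]]
#include "mech_common.h"

using namespace Rcpp;
using namespace cem;

// ---------------------------------------------------------------------------
// Mechanics: condensed three-field residual. The cell-wise discontinuous
// symmetric Kirchhoff stress satisfies, per cell, the L2 projection
//   Pi_h = Proj_l( G(F, activation, rates) - p J I ),
// which is eliminated exactly (the Pi mass matrix is block diagonal), so the
// global unknowns are (u, p); Pi is recovered by `mech_pi_qp`.
// ---------------------------------------------------------------------------

// Element residual for the (u, p) block on one cell.
// zl = [u (nb*d, node-interleaved); p (nb)]
static arma::vec mech_elem_res(const MechParams& mp, const BasisTables& tb,
                               const arma::mat& piPhi, const CellGeom& g,
                               const std::vector<arma::mat>& gr,
                               const arma::vec& zl, const arma::vec& upred,
                               const arma::vec& vpred, const arma::vec& act,
                               const arma::mat& fb, bool dyn) {
  int d = tb.d, nb = tb.nb, nq = tb.nq;
  arma::vec res(nb * d + nb, arma::fill::zeros);
  std::vector<arma::mat> Finvt(nq), Sq(nq);
  arma::vec Jq(nq);
  arma::mat uq(nq, d);

  for (int q = 0; q < nq; ++q) {
    arma::mat gradu(d, d, arma::fill::zeros), Fdot(d, d, arma::fill::zeros);
    arma::rowvec uval(d, arma::fill::zeros);
    double pval = 0.0;
    for (int a = 0; a < nb; ++a) {
      for (int k = 0; k < d; ++k) {
        double ua = zl(a * d + k);
        uval(k) += tb.phi(q, a) * ua;
        for (int j = 0; j < d; ++j) gradu(k, j) += ua * gr[q](a, j);
        if (dyn && mp.delta != 0.0) {
          double wa = mp.c_v * (ua - upred(a * d + k)) + vpred(a * d + k);
          for (int j = 0; j < d; ++j) Fdot(k, j) += wa * gr[q](a, j);
        }
      }
      pval += tb.phi(q, a) * zl(nb * d + a);
    }
    arma::mat F = arma::eye(d, d) + gradu;
    double J = arma::det(F);
    if (!(J > 0.0)) stop("inverted element at quadrature point");
    Finvt[q] = arma::inv(F).t();
    Jq(q) = J;
    uq.row(q) = uval;
    arma::mat G = kirchhoff_G(mp, F, act(q), Fdot, dyn);
    Sq[q] = G - pval * J * arma::eye(d, d);
  }

  std::vector<arma::mat> Pi(nq);
  project_pi(piPhi, tb.qw, Sq, Pi);

  for (int q = 0; q < nq; ++q) {
    double wdet = tb.qw(q) * g.detJ;
    arma::mat PiFt = Pi[q] * Finvt[q];
    for (int a = 0; a < nb; ++a) {
      for (int k = 0; k < d; ++k) {
        double rr = 0.0;
        for (int j = 0; j < d; ++j) rr += PiFt(k, j) * gr[q](a, j);
        if (dyn && mp.c_a != 0.0) {
          double upv = 0.0;
          for (int b2 = 0; b2 < nb; ++b2)
            upv += tb.phi(q, b2) * upred(b2 * d + k);
          rr += mp.rho0 * mp.c_a * (uq(q, k) - upv) * tb.phi(q, a);
        }
        if (fb.n_elem > 0) rr -= fb(q, k) * tb.phi(q, a);
        res(a * d + k) += wdet * rr;
      }
      res(nb * d + a) += wdet * (Jq(q) - 1.0) * tb.phi(q, a);
    }
  }
  return res;
}

// [[Rcpp::export(name = ".asm_mechanics")]]
List asm_mechanics(const arma::mat& coords, const arma::imat& cells,
                   const arma::imat& dof, const List& tables,
                   const arma::mat& piPhi, const arma::vec& z,
                   const List& params, const arma::mat& act,
                   const arma::mat& bodyf, const arma::vec& u_pred,
                   const arma::vec& v_pred, bool jac, double eps,
                   bool central = true) {
  BasisTables tb = tables_from_list(tables);
  MechParams mp = mech_params(params);
  int d = coords.n_cols, nb = tb.nb, nc = cells.n_rows;
  int nn = dof.max();
  int nloc = nb * d + nb, offp = nn * d;
  arma::vec res(nn * d + nn, arma::fill::zeros);
  Triplets tr;
  bool dyn = u_pred.n_elem > 0;
  arma::vec up_loc(nb * d, arma::fill::zeros),
      vp_loc(nb * d, arma::fill::zeros);

  for (int e = 0; e < nc; ++e) {
    arma::uvec verts(d + 1);
    for (int i = 0; i <= d; ++i) verts(i) = cells(e, i) - 1;
    CellGeom g = cell_geom(coords, verts);
    std::vector<arma::mat> gr(tb.nq);
    for (int q = 0; q < tb.nq; ++q) gr[q] = phys_grads(tb, g, q);

    arma::ivec ldof(nb);
    arma::vec zl(nloc);
    for (int a = 0; a < nb; ++a) {
      ldof(a) = dof(e, a) - 1;
      for (int k = 0; k < d; ++k) {
        zl(a * d + k) = z(ldof(a) * d + k);
        if (dyn) {
          up_loc(a * d + k) = u_pred(ldof(a) * d + k);
          vp_loc(a * d + k) = v_pred(ldof(a) * d + k);
        }
      }
      zl(nb * d + a) = z(offp + ldof(a));
    }
    arma::vec acte = act.n_elem ? act.row(e).t()
                                : arma::vec(tb.nq, arma::fill::zeros);
    arma::mat fbe;
    if (bodyf.n_rows > 0) fbe = bodyf.rows(e * tb.nq, (e + 1) * tb.nq - 1);

    auto rfun = [&](const arma::vec& zz) {
      return mech_elem_res(mp, tb, piPhi, g, gr, zz, up_loc, vp_loc, acte,
                           fbe, dyn);
    };
    arma::vec r0 = rfun(zl);

    std::vector<int> gidx(nloc);
    for (int a = 0; a < nb; ++a) {
      for (int k = 0; k < d; ++k) gidx[a * d + k] = ldof(a) * d + k;
      gidx[nb * d + a] = offp + ldof(a);
    }
    for (int i = 0; i < nloc; ++i) res(gidx[i]) += r0(i);

    if (jac) {
      arma::vec zp = zl;
      for (int j = 0; j < nloc; ++j) {
        double h = eps * (1.0 + std::abs(zl(j)));
        zp(j) = zl(j) + h;
        arma::vec rp = rfun(zp);
        arma::vec col;
        if (central) {
          zp(j) = zl(j) - h;
          col = (rp - rfun(zp)) / (2.0 * h);
        } else {
          col = (rp - r0) / h;
        }
        zp(j) = zl(j);
        for (int i = 0; i < nloc; ++i)
          if (col(i) != 0.0) tr.add(gidx[i], gidx[j], col(i));
      }
    }
  }
  return List::create(_["res"] = res, _["trip"] = tr.as_list());
}

// Boundary terms (Robin springs, follower pressure, dead traction) on the
// parent cells of boundary facets. fphi/fdphi hold the parent-cell basis
// evaluated at the facet quadrature points (nf*nqf rows); fw are physical
// reference-measure weights; fnormal the reference outward unit normals.
// ftype: 1 Robin (feta), 2 follower pressure (fpn), 3 dead traction (ftrac)
// [[Rcpp::export(name = ".asm_mech_boundary")]]
List asm_mech_boundary(const arma::mat& coords, const arma::imat& cells,
                       const arma::imat& dof, const arma::ivec& fparent,
                       const arma::mat& fphi, const arma::cube& fdphi,
                       const arma::vec& fw, const arma::mat& fnormal,
                       const arma::ivec& ftype, const arma::vec& feta,
                       const arma::vec& fpn, const arma::mat& ftrac,
                       const arma::vec& z, int nqf, bool jac, double eps) {
  int d = coords.n_cols, nb = fphi.n_cols, nf = fparent.n_elem;
  int nn = dof.max();
  arma::vec res(nn * d + nn, arma::fill::zeros);
  Triplets tr;

  for (int f = 0; f < nf; ++f) {
    int e = fparent(f) - 1;
    arma::uvec verts(d + 1);
    for (int i = 0; i <= d; ++i) verts(i) = cells(e, i) - 1;
    CellGeom g = cell_geom(coords, verts);

    arma::ivec ldof(nb);
    arma::vec ul(nb * d);
    for (int a = 0; a < nb; ++a) {
      ldof(a) = dof(e, a) - 1;
      for (int k = 0; k < d; ++k) ul(a * d + k) = z(ldof(a) * d + k);
    }
    int type = ftype(f);
    arma::vec nref = fnormal.row(f).t();

    auto rfun = [&](const arma::vec& uu) {
      arma::vec rr(nb * d, arma::fill::zeros);
      for (int q = 0; q < nqf; ++q) {
        int row = f * nqf + q;
        arma::mat grf(nb, d);
        for (int b = 0; b < nb; ++b)
          for (int k = 0; k < d; ++k) {
            double s = 0.0;
            for (int m = 0; m < d; ++m) s += fdphi(row, b, m) * g.Jginv(m, k);
            grf(b, k) = s;
          }
        arma::mat gradu(d, d, arma::fill::zeros);
        arma::vec uval(d, arma::fill::zeros);
        for (int a = 0; a < nb; ++a)
          for (int k = 0; k < d; ++k) {
            gradu.row(k) += uu(a * d + k) * grf.row(a);
            uval(k) += fphi(row, a) * uu(a * d + k);
          }
        arma::mat F = arma::eye(d, d) + gradu;
        arma::vec tvec(d, arma::fill::zeros);
        if (type == 1) {
          tvec = feta(f) * arma::solve(F.t(), uval);       // eta F^{-t} u
        } else if (type == 2) {
          // follower pressure pushing into the domain: prescribed traction
          // -p_N J F^{-t} n enters the residual as -int t.v
          double J = arma::det(F);
          tvec = fpn(f) * J * arma::solve(F.t(), nref);
        } else {
          tvec = -ftrac.row(f).t();                          // dead load
        }
        for (int a = 0; a < nb; ++a)
          for (int k = 0; k < d; ++k)
            rr(a * d + k) += fw(row) * tvec(k) * fphi(row, a);
      }
      return rr;
    };

    arma::vec r0 = rfun(ul);
    std::vector<int> gidx(nb * d);
    for (int a = 0; a < nb; ++a)
      for (int k = 0; k < d; ++k) gidx[a * d + k] = ldof(a) * d + k;
    for (int i = 0; i < nb * d; ++i) res(gidx[i]) += r0(i);

    if (jac && type != 3) {
      arma::vec up = ul;
      for (int j = 0; j < nb * d; ++j) {
        double h = eps * (1.0 + std::abs(ul(j)));
        up(j) = ul(j) + h;
        arma::vec rp = rfun(up);
        up(j) = ul(j) - h;
        arma::vec rm = rfun(up);
        up(j) = ul(j);
        arma::vec col = (rp - rm) / (2.0 * h);
        for (int i = 0; i < nb * d; ++i)
          if (col(i) != 0.0) tr.add(gidx[i], gidx[j], col(i));
      }
    }
  }
  return List::create(_["res"] = res, _["trip"] = tr.as_list());
}

// Projected Kirchhoff stress at the quadrature points of `tables`
// (row e*nq+q holds Pi flattened column-major), plus per-point J and I4f.
// [[Rcpp::export(name = ".mech_pi_qp")]]
List mech_pi_qp(const arma::mat& coords, const arma::imat& cells,
                const arma::imat& dof, const List& tables,
                const arma::mat& piPhi, const arma::vec& z,
                const List& params, const arma::mat& act,
                const arma::vec& u_pred, const arma::vec& v_pred) {
  BasisTables tb = tables_from_list(tables);
  MechParams mp = mech_params(params);
  int d = coords.n_cols, nb = tb.nb, nc = cells.n_rows, nq = tb.nq;
  int nn = dof.max();
  bool dyn = u_pred.n_elem > 0;
  arma::mat Pi_out(nc * nq, d * d);
  arma::vec Jout(nc * nq), I4fout(nc * nq);

  for (int e = 0; e < nc; ++e) {
    arma::uvec verts(d + 1);
    for (int i = 0; i <= d; ++i) verts(i) = cells(e, i) - 1;
    CellGeom g = cell_geom(coords, verts);
    std::vector<arma::mat> gr(nq);
    for (int q = 0; q < nq; ++q) gr[q] = phys_grads(tb, g, q);

    std::vector<arma::mat> Sq(nq);
    for (int q = 0; q < nq; ++q) {
      arma::mat gradu(d, d, arma::fill::zeros), Fdot(d, d, arma::fill::zeros);
      double pval = 0.0;
      for (int a = 0; a < nb; ++a) {
        int n = dof(e, a) - 1;
        for (int k = 0; k < d; ++k) {
          double ua = z(n * d + k);
          for (int j = 0; j < d; ++j) gradu(k, j) += ua * gr[q](a, j);
          if (dyn && mp.delta != 0.0) {
            double wa = mp.c_v * (ua - u_pred(n * d + k)) + v_pred(n * d + k);
            for (int j = 0; j < d; ++j) Fdot(k, j) += wa * gr[q](a, j);
          }
        }
        pval += tb.phi(q, a) * z(nn * d + n);
      }
      arma::mat F = arma::eye(d, d) + gradu;
      double act_q = act.n_elem ? act(e, q) : 0.0;
      arma::mat G = kirchhoff_G(mp, F, act_q, Fdot, dyn);
      double J = arma::det(F);
      Sq[q] = G - pval * J * arma::eye(d, d);
      Jout(e * nq + q) = J;
      arma::vec Ff = F * mp.fr.f0;
      I4fout(e * nq + q) = arma::dot(Ff, Ff);
    }
    std::vector<arma::mat> Pi(nq);
    project_pi(piPhi, tb.qw, Sq, Pi);
    for (int q = 0; q < nq; ++q)
      Pi_out.row(e * nq + q) = arma::vectorise(Pi[q]).t();
  }
  return List::create(_["Pi"] = Pi_out, _["J"] = Jout, _["I4f"] = I4fout);
}

// ---------------------------------------------------------------------------
// Monodomain support
// ---------------------------------------------------------------------------

// Per-quadrature-point geometric / fibre / SAD tensors from the mechanical
// state (Pi entering the SAD term is the projected discrete stress).
// [[Rcpp::export(name = ".mono_qp_tensors")]]
List mono_qp_tensors(const arma::mat& coords, const arma::imat& cells,
                     const arma::imat& dof, const List& tables,
                     const arma::mat& piPhi, const arma::vec& z,
                     const List& params, const arma::mat& act,
                     const arma::vec& u_pred, const arma::vec& v_pred,
                     bool fibre_over_J) {
  BasisTables tb = tables_from_list(tables);
  MechParams mp = mech_params(params);
  int d = coords.n_cols, nb = tb.nb, nc = cells.n_rows, nq = tb.nq;
  int nn = dof.max();
  bool dyn = u_pred.n_elem > 0;
  arma::mat Ageo(nc * nq, d * d), Afib(nc * nq, d * d), Asad(nc * nq, d * d);
  arma::vec I4fout(nc * nq);

  for (int e = 0; e < nc; ++e) {
    arma::uvec verts(d + 1);
    for (int i = 0; i <= d; ++i) verts(i) = cells(e, i) - 1;
    CellGeom g = cell_geom(coords, verts);
    std::vector<arma::mat> gr(nq);
    for (int q = 0; q < nq; ++q) gr[q] = phys_grads(tb, g, q);

    std::vector<arma::mat> Sq(nq), Fq(nq);
    for (int q = 0; q < nq; ++q) {
      arma::mat gradu(d, d, arma::fill::zeros), Fdot(d, d, arma::fill::zeros);
      double pval = 0.0;
      for (int a = 0; a < nb; ++a) {
        int n = dof(e, a) - 1;
        for (int k = 0; k < d; ++k) {
          double ua = z(n * d + k);
          for (int j = 0; j < d; ++j) gradu(k, j) += ua * gr[q](a, j);
          if (dyn && mp.delta != 0.0) {
            double wa = mp.c_v * (ua - u_pred(n * d + k)) + v_pred(n * d + k);
            for (int j = 0; j < d; ++j) Fdot(k, j) += wa * gr[q](a, j);
          }
        }
        pval += tb.phi(q, a) * z(nn * d + n);
      }
      arma::mat F = arma::eye(d, d) + gradu;
      Fq[q] = F;
      double act_q = act.n_elem ? act(e, q) : 0.0;
      arma::mat G = kirchhoff_G(mp, F, act_q, Fdot, dyn);
      Sq[q] = G - pval * arma::det(F) * arma::eye(d, d);
    }
    std::vector<arma::mat> Pi(nq);
    project_pi(piPhi, tb.qw, Sq, Pi);
    for (int q = 0; q < nq; ++q) {
      arma::mat F = Fq[q];
      double J = arma::det(F);
      arma::mat Finv = arma::inv(F);
      arma::mat geo = J * (Finv * Finv.t());
      double fibfac = fibre_over_J ? 1.0 / (2.0 * J) : 0.5 * J;
      arma::mat fib = fibfac * (mp.fr.f0 * mp.fr.f0.t());
      arma::mat sad = J * Finv * Pi[q] * Finv.t();
      Ageo.row(e * nq + q) = arma::vectorise(geo).t();
      Afib.row(e * nq + q) = arma::vectorise(fib).t();
      Asad.row(e * nq + q) = arma::vectorise(0.5 * (sad + sad.t())).t();
      arma::vec Ff = F * mp.fr.f0;
      I4fout(e * nq + q) = arma::dot(Ff, Ff);
    }
  }
  return List::create(_["Ageo"] = Ageo, _["Afib"] = Afib, _["Asad"] = Asad,
                      _["I4f"] = I4fout);
}

// Stiffness K(v), self-diffusion Newton correction N(v) and lumped mass for
// the monodomain diffusion solve. D = (D0 + D1 v) Ageo + D0 Afib + D2 Asad
// at each quadrature point (the 1/2 fibre factor is inside Afib).
// Ellipticity safeguard: eigenvalues of D clipped at eps_ell from below.
// [[Rcpp::export(name = ".asm_mono_system")]]
List asm_mono_system(const arma::mat& coords, const arma::imat& cells,
                     const arma::imat& dof, const List& tables,
                     const arma::vec& v, const arma::mat& Ageo,
                     const arma::mat& Afib, const arma::mat& Asad,
                     double D0, double D1, double D2, double eps_ell) {
  BasisTables tb = tables_from_list(tables);
  int d = coords.n_cols, nb = tb.nb, nc = cells.n_rows, nq = tb.nq;
  int nn = dof.max();
  Triplets trK, trN;
  arma::vec ML(nn, arma::fill::zeros);
  int nclip = 0;

  for (int e = 0; e < nc; ++e) {
    arma::uvec verts(d + 1);
    for (int i = 0; i <= d; ++i) verts(i) = cells(e, i) - 1;
    CellGeom g = cell_geom(coords, verts);
    arma::ivec ldof(nb);
    for (int a = 0; a < nb; ++a) ldof(a) = dof(e, a) - 1;

    for (int q = 0; q < nq; ++q) {
      arma::mat gr = phys_grads(tb, g, q);
      double vq = 0.0;
      arma::vec gradv(d, arma::fill::zeros);
      for (int a = 0; a < nb; ++a) {
        vq += tb.phi(q, a) * v(ldof(a));
        gradv += v(ldof(a)) * gr.row(a).t();
      }
      int row = e * nq + q;
      arma::mat geo = arma::reshape(Ageo.row(row).t(), d, d);
      arma::mat D = (D0 + D1 * vq) * geo +
                    D0 * arma::reshape(Afib.row(row).t(), d, d) +
                    D2 * arma::reshape(Asad.row(row).t(), d, d);
      if (eps_ell > 0.0) {
        arma::vec eval; arma::mat evec;
        arma::eig_sym(eval, evec, D);
        if (eval(0) <= eps_ell) {
          ++nclip;
          for (arma::uword i = 0; i < eval.n_elem; ++i)
            if (eval(i) < eps_ell) eval(i) = eps_ell;
          D = evec * arma::diagmat(eval) * evec.t();
        }
      }
      double wdet = tb.qw(q) * g.detJ;
      arma::vec Dgv = D1 * (geo * gradv);
      for (int a = 0; a < nb; ++a) {
        ML(ldof(a)) += wdet * tb.phi(q, a);
        arma::vec Dga = D * gr.row(a).t();
        for (int b = 0; b < nb; ++b) {
          trK.add(ldof(a), ldof(b), wdet * arma::dot(Dga, gr.row(b).t()));
          trN.add(ldof(a), ldof(b),
                  wdet * tb.phi(q, b) * arma::dot(Dgv, gr.row(a).t()));
        }
      }
    }
  }
  return List::create(_["K"] = trK.as_list(), _["N"] = trN.as_list(),
                      _["ML"] = ML, _["n_clipped"] = nclip);
}
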