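#' Manufactured steady-state electromechanics: closed-form fields
#'
#' The smooth exact solution on the unit square used by the convergence
#' driver (fibres f0 = (0,1), sheets s0 = (-1,0)); the simplified kinetics
#' are m(v,r) = v - r^2, g(v,r) = (v-1) v r, l(Ta,r) = -Ta + r.
#'
#' @param pts coordinates (n x 2)
#' @return list of fields and their gradients
#' @export
manufactured_fields <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  sx <- sin(pi * x); cx <- cos(pi * x)
  sy <- sin(pi * y); cy <- cos(pi * y)
  list(
    u1 = 0.1 * sx * cy, u2 = 0.1 * cx * sy,
    du1 = cbind(0.1 * pi * cx * cy, -0.1 * pi * sx * sy),
    du2 = cbind(-0.1 * pi * sx * sy, 0.1 * pi * cx * cy),
    p = 0.1 * sx * sy,
    v = 1 + 0.1 * cx * cy,
    dv = cbind(-0.1 * pi * sx * cy, -0.1 * pi * cx * sy),
    r = 0.1 * cx * sx * sy,
    dr = cbind(0.1 * pi * cos(2 * pi * x) * sy,
               0.05 * pi * sin(2 * pi * x) * cy),
    Ta = 1 + 0.1 * cx * sy,
    dTa = cbind(-0.1 * pi * sx * sy, 0.1 * pi * cx * cy))
}

#' Parameter bundle for the steady convergence test
#'
#' Material constants for the manufactured steady problem. The default
#' passive law is the patient-specific healthy-myocardium Holzapfel-Ogden
#' set ([ho_params_gao2014()]), whose moderate exponents keep the
#' manufactured stress fields on the scale of the discretisation errors;
#' the baseline viscoelasticity constants are available by passing
#' `ho = ho_params()`.
#'
#' The unit-square problem is non-dimensional: the diffusion constants are
#' used as printed (`unit_scale = 1`), unlike the physical slab runs.
#'
#' @param ho passive constants; @param active active-stress weights
#' @param cond conductivity parameters; @param apars activation constants
#' @export
steady_param_list <- function(ho = ho_params_verification(),
                              active = active_stress_params(),
                              cond = conductivity_params(unit_scale = 1,
                                                         stress_unit = 1),
                              apars = NULL) {
  if (is.null(apars)) apars <- activation_params(D0i = cond$D0i)
  ho <- unclass(ho)
  ho$gated <- FALSE  # smooth (ungated) law for the manufactured test
  pl <- mech_param_list(mode = "active-stress", f0 = c(0, 1), s0 = c(-1, 0),
                        ho = ho, active = active)
  pl$cond <- list(D0 = cond$D0i, D1 = cond$D1i, D2 = cond$D2i,
                  fibre_over_J = cond$fibre_over_J)
  pl$alpha_hat <- apars$alpha_hat
  pl
}

# solve the monolithic steady coupled problem on one mesh: unknowns
# (u, p, v, Ta) plus a mean-pressure multiplier; the gating field r is a
# cell-wise discontinuous polynomial eliminated inside the element kernels
steady_solve <- function(mesh, l, zeta_stab = 0.25, params = NULL,
                         tol_rel = 1e-9, maxit = 40) {
  if (is.null(params)) params <- steady_param_list()
  d <- 2
  space <- build_space(mesh, degree = l + 1)
  quad <- simplex_quadrature(d, 2 * (l + 1) + 2)
  tables <- basis_tables(d, l + 1, quad)
  piphi <- pi_phi(d, l, quad)
  nn <- space$ndof
  qpts <- cell_qpoints(space, quad)
  frc <- .manufactured_forcing(qpts, params, 1e-5)
  sm <- scalar_matrices(space)
  massvec <- load_vector(space, tables,
                         matrix(1, mesh$nc, length(quad$weights)))
  mf <- manufactured_fields(space$node_coords)
  # branch selector for the pointwise gating elimination: the sign of the
  # exact field at each quadrature point
  rsgn <- sign(manufactured_fields(qpts)$r)
  # exact-interpolant initial guess
  z <- numeric(5 * nn)
  z[seq(1, 2 * nn, by = 2)] <- mf$u1
  z[seq(2, 2 * nn, by = 2)] <- mf$u2
  z[2 * nn + seq_len(nn)] <- mf$p
  z[3 * nn + seq_len(nn)] <- mf$v
  z[4 * nn + seq_len(nn)] <- mf$Ta
  # Dirichlet sets: u, v, Ta on the boundary nodes
  xc <- space$node_coords
  onb <- which(abs(xc[, 1]) < 1e-12 | abs(xc[, 1] - 1) < 1e-12 |
               abs(xc[, 2]) < 1e-12 | abs(xc[, 2] - 1) < 1e-12)
  dir_idx <- c((onb - 1) * 2 + 1, (onb - 1) * 2 + 2,
               3 * nn + onb, 4 * nn + onb)
  dir_val <- c(mf$u1[onb], mf$u2[onb], mf$v[onb], mf$Ta[onb])
  free <- setdiff(seq_len(5 * nn + 1), dir_idx)
  # mean-pressure constraint value from the exact pressure
  fe <- manufactured_fields(qpts)
  wdet <- rep(space$geom$detJ, each = length(quad$weights)) *
    rep(quad$weights, times = mesh$nc)
  c0 <- sum(wdet * fe$p)
  stab <- zeta_stab * sm$Kh2
  stabT <- methods::as(stab, "TsparseMatrix")

  resid <- function(z, lam, jac) {
    out <- .asm_steady(mesh$coords, mesh$cells, space$dof, tables, piphi,
                       z, params, frc$fu, frc$Jex, frc$fv, frc$fr,
                       frc$fTa, rsgn, jac, 3e-6)
    res <- out$res
    pidx <- 2 * nn + seq_len(nn)
    res[pidx] <- res[pidx] + as.vector(stab %*% z[pidx]) + lam * massvec
    rfull <- c(res, sum(massvec * z[pidx]) - c0)
    J <- NULL
    if (jac) {
      ii <- c(out$trip$i + 1L, stabT@i + 1L + 2L * nn,
              2L * nn + seq_len(nn), rep(5L * nn + 1L, nn))
      jj <- c(out$trip$j + 1L, stabT@j + 1L + 2L * nn,
              rep(5L * nn + 1L, nn), 2L * nn + seq_len(nn))
      xx <- c(out$trip$x, stabT@x, massvec, massvec)
      J <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                dims = c(5 * nn + 1, 5 * nn + 1))
    }
    list(res = rfull, J = J)
  }

  zfull <- c(z, 0)
  zfull[dir_idx] <- dir_val
  keep <- rep(1, 5 * nn + 1); keep[dir_idx] <- 0
  rj <- resid(zfull[seq_len(5 * nn)], zfull[5 * nn + 1], TRUE)
  r0 <- max(abs(rj$res[free]))
  conv <- FALSE
  for (it in seq_len(maxit)) {
    rn <- max(abs(rj$res[free]))
    if (rn < max(1e-12, tol_rel * r0)) { conv <- TRUE; break }
    J2 <- Matrix::Diagonal(x = keep) %*% rj$J +
      Matrix::Diagonal(x = 1 - keep)
    res2 <- keep * rj$res
    res2[dir_idx] <- zfull[dir_idx] - dir_val
    fac <- Matrix::lu(methods::as(J2, "CsparseMatrix"))
    dz <- as.vector(Matrix::solve(fac, -res2))
    # one step of iterative refinement (the multiplier row makes the
    # system poorly scaled)
    lr <- as.vector(J2 %*% dz) + res2
    dz <- dz - as.vector(Matrix::solve(fac, lr))
    step <- 1
    accepted <- FALSE
    for (ls in 1:12) {
      ztry <- zfull + step * dz
      rt <- tryCatch(resid(ztry[seq_len(5 * nn)], ztry[5 * nn + 1], FALSE),
                     error = function(e) NULL)
      if (!is.null(rt) && max(abs(rt$res[free])) < rn * (1 - 1e-4 * step)) {
        accepted <- TRUE; break
      }
      step <- step / 2
    }
    if (!accepted) break  # hand over to the block stage below
    zfull <- ztry
    rj <- resid(zfull[seq_len(5 * nn)], zfull[5 * nn + 1], TRUE)
  }
  # Block Gauss-Seidel polish: alternate exact sub-Newtons on the
  # mechanical block (u, p, lambda) with (v, Ta) frozen and on the
  # electrophysiology block with the mechanics frozen, iterated until the
  # full monolithic residual meets the same tolerance (so no splitting
  # error remains). The cross-block curvature of the eliminated gating
  # field is what keeps the one-shot monolithic iteration from the floor.
  if (!conv) {
    subsolve <- function(zf, extra_dir, extra_val, nit = 12) {
      dir2 <- c(dir_idx, extra_dir)
      val2 <- c(dir_val, extra_val)
      keep2 <- rep(1, 5 * nn + 1); keep2[dir2] <- 0
      free2 <- setdiff(seq_len(5 * nn + 1), dir2)
      # full-step sub-Newton: the saddle path is nonmonotone, so growth is
      # tolerated and only breakdowns are rejected
      zbest <- zf
      rbest <- Inf
      for (k in seq_len(nit)) {
        rj <- tryCatch(resid(zf[seq_len(5 * nn)], zf[5 * nn + 1], TRUE),
                       error = function(e) NULL)
        if (is.null(rj)) return(zbest)
        rnk <- max(abs(rj$res[free2]))
        if (rnk < rbest) { rbest <- rnk; zbest <- zf }
        if (rnk < 1e-12) break
        J2 <- Matrix::Diagonal(x = keep2) %*% rj$J +
          Matrix::Diagonal(x = 1 - keep2)
        res2 <- keep2 * rj$res
        res2[dir2] <- zf[dir2] - val2
        dz <- as.vector(Matrix::solve(J2, -res2))
        zf <- zf + dz
      }
      rj <- tryCatch(resid(zf[seq_len(5 * nn)], zf[5 * nn + 1], FALSE),
                     error = function(e) NULL)
      if (is.null(rj) || max(abs(rj$res[free2])) > rbest) zf <- zbest
      zf
    }
    mech_extra <- c(3 * nn + seq_len(nn), 4 * nn + seq_len(nn))
    elec_extra <- c(seq_len(2 * nn), 2 * nn + seq_len(nn), 5 * nn + 1)
    for (sweep in 1:20) {
      zf_m <- zfull[mech_extra]
      zfull <- subsolve(zfull, mech_extra, zf_m)
      zf_e <- zfull[elec_extra]
      zfull <- subsolve(zfull, elec_extra, zf_e)
      rj <- resid(zfull[seq_len(5 * nn)], zfull[5 * nn + 1], FALSE)
      if (max(abs(rj$res[free])) < max(1e-12, tol_rel * r0)) {
        conv <- TRUE; break
      }
    }
  }
  if (!conv) stop(sprintf("steady Newton did not converge (|R| = %.3e)",
                          max(abs(rj$res[free]))))
  list(z = zfull[seq_len(5 * nn)], lambda = zfull[5 * nn + 1],
       space = space, tables = tables, quad = quad, piphi = piphi,
       params = params, qpts = qpts, wdet = wdet, frc = frc,
       rsgn = rsgn)
}

# errors of one steady solve in the stated norms (r in the broken H1 norm
# of its cell-wise discontinuous space)
steady_errors <- function(mesh, sol) {
  space <- sol$space
  nn <- space$ndof
  z <- sol$z
  ex <- manufactured_fields(sol$qpts)
  exC <- .manufactured_exact(sol$qpts, sol$params)
  w <- sol$wdet
  l2 <- function(e2) sqrt(sum(w * e2))
  tovec <- function(m) as.vector(t(m))  # nc x nq -> cell-major vector

  Pih <- .steady_pi_qp(mesh$coords, mesh$cells, space$dof, sol$tables,
                       sol$piphi, z, sol$params)
  ePi <- l2(rowSums((Pih - exC$Pi)^2))
  u1 <- field_grad_at_qp(space, sol$tables, z[seq(1, 2 * nn, 2)])
  u2 <- field_grad_at_qp(space, sol$tables, z[seq(2, 2 * nn, 2)])
  e2 <- (tovec(u1$val) - ex$u1)^2 + (tovec(u2$val) - ex$u2)^2 +
    (tovec(u1$grad[, , 1]) - ex$du1[, 1])^2 +
    (tovec(u1$grad[, , 2]) - ex$du1[, 2])^2 +
    (tovec(u2$grad[, , 1]) - ex$du2[, 1])^2 +
    (tovec(u2$grad[, , 2]) - ex$du2[, 2])^2
  eu <- l2(e2)
  ph <- field_grad_at_qp(space, sol$tables, z[2 * nn + seq_len(nn)])
  ep <- l2((tovec(ph$val) - ex$p)^2)
  h1err <- function(off, val, grad) {
    fh <- field_grad_at_qp(space, sol$tables, z[off + seq_len(nn)])
    l2((tovec(fh$val) - val)^2 +
       (tovec(fh$grad[, , 1]) - grad[, 1])^2 +
       (tovec(fh$grad[, , 2]) - grad[, 2])^2)
  }
  ev <- h1err(3 * nn, ex$v, ex$dv)
  eTa <- h1err(4 * nn, ex$Ta, ex$dTa)
  # analytic gradient of the gating forcing f_r = -(v_ex - r_ex^2)
  fgrad <- -ex$dv + 2 * ex$r * ex$dr
  rr <- .steady_r_qp(mesh$coords, mesh$cells, space$dof, sol$tables, z,
                     sol$params, sol$frc$fr, fgrad, sol$rsgn)
  er <- l2((rr$r - ex$r)^2 + (rr$grad[, 1] - ex$dr[, 1])^2 +
           (rr$grad[, 2] - ex$dr[, 2])^2)
  er_l2 <- l2((rr$r - ex$r)^2)
  c(Pi = ePi, u = eu, p = ep, v = ev, r = er, Ta = eTa, r_l2 = er_l2)
}

#' Convergence study of the steady coupled scheme
#'
#' Solves the manufactured steady electromechanics problem monolithically on
#' a ladder of uniformly refined unit-square meshes and reports errors
#' (Kirchhoff stress and pressure in L2, displacement and the
#' electrophysiology fields in H1 -- broken H1 for the cell-wise gating
#' field) and observed convergence rates.
#'
#' @param l stress polynomial degree (0 or 1)
#' @param levels number of refinement levels; the ladder starts at n = 4
#'   subdivisions (on the n = 2 mesh the exact gating field vanishes at
#'   every node and the discrete problem degenerates)
#' @param zeta_stab pressure stabilisation constant
#' @param params optional parameter bundle from [steady_param_list()]
#' @param verbose print per-level progress
#' @return data.frame with h, dof and per-field errors and rates
#' @export
convergence_study <- function(l = 0, levels = 5, zeta_stab = NULL,
                              params = NULL, verbose = FALSE) {
  stopifnot(levels >= 2)
  # the equal-order pressure pair needs much less stabilisation at second
  # order; over-stabilising degrades the p (and through it u) accuracy
  if (is.null(zeta_stab)) zeta_stab <- if (l == 0) 0.25 else 0.002
  err <- NULL
  hs <- dofs <- numeric(0)
  for (lev in seq_len(levels)) {
    n <- 2^(lev + 1)
    mesh <- unit_square_mesh(n)
    sol <- tryCatch(
      steady_solve(mesh, l, zeta_stab, params),
      error = function(e) stop(sprintf("level %d: %s", lev,
                                       conditionMessage(e))))
    e <- steady_errors(mesh, sol)
    err <- rbind(err, e)
    hs <- c(hs, sqrt(2) / n)
    npi <- if (l == 0) 3 * mesh$nc else 9 * mesh$nc
    nr <- if (l == 0) 3 * mesh$nc else 6 * mesh$nc  # disc. gating dofs
    dofs <- c(dofs, npi + nr + 5 * sol$space$ndof)
    if (verbose)
      message(sprintf("level %d (h = %.4f): %s", lev, hs[lev],
                      paste(sprintf("%s %.3e", colnames(err), e),
                            collapse = ", ")))
  }
  rates <- rbind(NA, log2(err[-nrow(err), , drop = FALSE] /
                          err[-1, , drop = FALSE]))
  colnames(rates) <- paste0("rate_", colnames(err))
  out <- data.frame(h = hs, dof = dofs, err, rates, check.names = FALSE)
  rownames(out) <- NULL
  out
}
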