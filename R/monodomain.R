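#' Monodomain discretisation
#'
#' Transmembrane potential in the continuous degree l+1 space on the same
#' mesh as the mechanics; mass matrix lumped; diffusion implicit with an
#' inner Newton over the v-dependent self-diffusion; reaction explicit at
#' the nodes (operator splitting).
#'
#' @param sys a [mech_system()] (supplies mesh, mechanics state access and
#'   the fibre frame)
#' @param cond [conductivity_params()]
#' @param ionic [ionic_params_epi()]
#' @return list of class `mono_system`
#' @export
mono_system <- function(sys, cond = conductivity_params(),
                        ionic = ionic_params_epi()) {
  d <- sys$d
  quad <- simplex_quadrature(d, 2 * sys$space$degree)
  tables <- basis_tables(d, sys$space$degree, quad)
  piphi <- pi_phi(d, sys$l, quad)
  ms <- list(sys = sys, space = sys$space, quad = quad, tables = tables,
             piphi = piphi, cond = cond, ionic = ionic,
             nodes = sys$space$node_coords)
  class(ms) <- "mono_system"
  ms
}

# per-step mechanical tensors entering the conductivity, at the monodomain
# quadrature points
mono_tensors <- function(ms, z_mech, act_qp = NULL, vel = NULL) {
  sys <- ms$sys
  params <- sys$params
  u_pred <- numeric(0); v_pred <- numeric(0)
  if (!is.null(vel) && sys$viscous) {
    # evaluate the viscous part of Pi with the actual velocity field
    params$c_v <- 1
    nnd <- sys$d * sys$nn
    u_pred <- z_mech[seq_len(nnd)]   # c_v (u - u_pred) + v_pred = vel
    v_pred <- vel
  }
  act <- if (is.null(act_qp)) matrix(0, 0, 0) else act_qp
  # activation given on the mechanics quadrature; re-evaluate on the
  # monodomain rule via nodal interpolation when sizes differ
  if (!is.null(act_qp) && ncol(act_qp) != length(ms$tables$qw))
    stop("activation must be sampled on the monodomain quadrature")
  .mono_qp_tensors(sys$mesh$coords, sys$mesh$cells, sys$space$dof,
                   ms$tables, ms$piphi, z_mech, params, act,
                   u_pred, v_pred, ms$cond$fibre_over_J)
}

#' One monodomain step (implicit diffusion after explicit reaction)
#'
#' Solves chi M_L (v - v_star)/dt + K(v) v = 0 by Newton, where v_star is
#' the reaction-updated potential and K carries the stress-assisted,
#' deformation-dependent conductivity frozen at the given mechanical state.
#'
#' @param ms a [mono_system()]
#' @param v_star reaction-updated nodal potential
#' @param tensors output of the internal tensor pass (mechanical state)
#' @param dt time step (ms)
#' @param tol Newton tolerance on the l-infinity residual
#' @param maxit inner Newton cap
#' @export
monodomain_step <- function(ms, v_star, tensors, dt, tol = 1e-9,
                            maxit = 12) {
  sys <- ms$sys
  chi <- ms$ionic$chi
  cp <- ms$cond
  v <- v_star
  nn <- sys$nn
  for (it in seq_len(maxit)) {
    a <- .asm_mono_system(sys$mesh$coords, sys$mesh$cells, sys$space$dof,
                          ms$tables, v, tensors$Ageo, tensors$Afib,
                          tensors$Asad, cp$D0i, cp$D1i, cp$D2i, cp$eps_ell)
    K <- Matrix::sparseMatrix(i = a$K$i + 1L, j = a$K$j + 1L, x = a$K$x,
                              dims = c(nn, nn))
    res <- chi * a$ML * (v - v_star) / dt + as.vector(K %*% v)
    if (max(abs(res)) < tol * max(1, max(abs(v))))
      return(list(v = v, iterations = it - 1L, n_clipped = a$n_clipped))
    N <- Matrix::sparseMatrix(i = a$N$i + 1L, j = a$N$j + 1L, x = a$N$x,
                              dims = c(nn, nn))
    J <- Matrix::Diagonal(x = chi * a$ML / dt) + K + N
    v <- v + as.vector(Matrix::solve(J, -res))
  }
  res_n <- max(abs(res))
  stop(sprintf(
    "monodomain inner Newton diverged: |R| = %.3e after %d iterations",
    res_n, maxit))
}
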