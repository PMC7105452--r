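#' Active tension step
#'
#' Semi-implicit step of the regularised active tension law
#' dTa/dt = alpha_hat Lap(Ta) + l(Ta, r3, I4f) with zero-flux boundaries.
#' In the default stable convention l = -Ta + alpha2 r3
#' + alpha3 (I4f - stretch_offset); the `literal_sign` convention
#' l = Ta - alpha2 r3 + alpha3 I4f is available for comparison and is
#' linearly unstable in Ta (growth is capped by `Ta_cap`).
#'
#' @param Ta nodal active tension
#' @param r3 nodal slow gate (calcium proxy)
#' @param I4f nodal fibre stretch invariant
#' @param dt time step (ms)
#' @param apars [activation_params()]
#' @param tsys transport matrices for the Ta space (list with `ML`, `K`)
#' @param Ta_cap divergence guard for the literal sign convention
#' @export
active_tension_step <- function(Ta, r3, I4f, dt, apars, tsys,
                                Ta_cap = 1e3) {
  nn <- length(Ta)
  sgn <- if (apars$literal_sign) -1 else 1
  # (ML/dt + sgn ML + alpha_hat K) Ta_new = ML (Ta/dt + drive)
  A <- if (!is.null(tsys$fac)) tsys$fac
       else Matrix::Diagonal(x = tsys$ML * (1 / dt + sgn)) +
         apars$alpha_hat * tsys$K
  drive <- if (apars$literal_sign) {
    -apars$alpha2 * r3 + apars$alpha3 * I4f
  } else {
    apars$alpha2 * r3 + apars$alpha3 * (I4f - apars$stretch_offset)
  }
  rhs <- tsys$ML * (Ta / dt + drive)
  Ta_new <- as.vector(Matrix::solve(A, rhs))
  if (max(abs(Ta_new)) > Ta_cap)
    stop(sprintf(
      "active tension diverged (cap %.3g) under the %s sign convention",
      Ta_cap, if (apars$literal_sign) "literal" else "stable"))
  Ta_new
}

#' Shortening (active strain) step
#'
#' Exponential (exact for frozen r3) or explicit Euler update of
#' dxi/dt = K1/(1 + r3) + K2 xi per quadrature point.
#'
#' @param xi shortening values (any shape)
#' @param r3 calcium-proxy gate values, same shape
#' @param dt time step (ms)
#' @param apars [activation_params()]
#' @param method "exponential" or "euler"
#' @export
shortening_step <- function(xi, r3, dt, apars,
                            method = c("exponential", "euler")) {
  if (dt <= 0) stop("dt must be > 0")
  if (any(1 + r3 <= 0)) stop("1 + r3 must be positive")
  method <- match.arg(method)
  if (method == "euler")
    return(xi + dt * (apars$K1 / (1 + r3) + apars$K2 * xi))
  xi_star <- -apars$K1 / ((1 + r3) * apars$K2)
  xi_star + (xi - xi_star) * exp(apars$K2 * dt)
}

#' Electromechanics problem container
#'
#' Bundles the mechanics, monodomain and activation discretisations for the
#' coupled semi-implicit time loop.
#'
#' @param mesh a labelled `cem_mesh` ("R"/"N"/"T"/"D" facets)
#' @param l polynomial degree of the stress space (0 or 1)
#' @param frame a [fibre_frame()]
#' @param mode "active-stress" or "active-strain"
#' @param ho,active,visco,cond,ionic,apars parameter blocks
#' @param viscous include Kelvin-Voigt stress
#' @param eta,p_N,traction boundary data (see [mech_set_bcs()])
#' @param dirichlet_nodes,dirichlet_comp normal-displacement constraints
#' @param zeta_stab pressure stabilisation constant
#' @param protocol a [stimulus_protocol()]
#' @param newmark_beta,newmark_gamma Newmark parameters
#' @export
em_problem <- function(mesh, l = 0, frame, mode = "active-stress",
                       ho = ho_params(), active = active_stress_params(),
                       visco = visco_params(), viscous = FALSE,
                       cond = conductivity_params(),
                       ionic = ionic_params_epi(),
                       apars = NULL, eta = 0.01, p_N = NULL,
                       traction = NULL, dirichlet_nodes = integer(0),
                       dirichlet_comp = NULL, zeta_stab = 2.5,
                       protocol = stimulus_protocol(),
                       newmark_beta = 0.25, newmark_gamma = 0.5) {
  if (is.null(apars)) apars <- activation_params(D0i = cond$D0i)
  sys <- mech_system(mesh, l = l, frame = frame, mode = mode, ho = ho,
                     active = active, visco = visco, viscous = viscous,
                     K0 = apars$K0, zeta_stab = zeta_stab)
  if (is.null(dirichlet_comp)) dirichlet_comp <- seq_len(mesh$d)
  sys <- mech_set_bcs(sys, eta = eta, p_N = p_N, traction = traction,
                      dirichlet_nodes = dirichlet_nodes,
                      dirichlet_comp = dirichlet_comp)
  ms <- mono_system(sys, cond = cond, ionic = ionic)
  sm <- scalar_matrices(sys$space)
  prob <- list(mesh = mesh, l = l, frame = frame, mode = mode, sys = sys,
               ms = ms, tsys = list(ML = sm$ML, K = sm$K), apars = apars,
               ionic = ionic, cond = cond, protocol = protocol,
               beta = newmark_beta, gamma = newmark_gamma,
               cache = new.env(parent = emptyenv()))
  class(prob) <- "em_problem"
  prob
}

#' Initial (rest) state of a coupled problem
#'
#' v = 0, r = (1, 1, 0), zero displacement and velocity, rest pressure
#' p = a (the Holzapfel-Ogden isotropic modulus) so the reference
#' configuration is stress free, and zero activation.
#'
#' @param prob an [em_problem()]
#' @export
em_init_state <- function(prob) {
  sys <- prob$sys
  nn <- sys$nn
  d <- sys$d
  z <- numeric(sys$nz)
  p_rest <- if (sys$material == "guccione") 0 else sys$ho$a
  z[d * nn + seq_len(nn)] <- p_rest
  nq <- length(prob$ms$tables$qw)
  st <- list(
    t = 0, z = z, vel = numeric(d * nn), acc = numeric(d * nn),
    v = numeric(nn), r = cbind(rep(1, nn), rep(1, nn), rep(0, nn)),
    Ta = numeric(nn), xi = matrix(0, prob$mesh$nc, nq))
  class(st) <- "em_state"
  st
}

# activation sampled on a quadrature rule (tables) from the state
activation_qp <- function(prob, state, tables) {
  if (prob$mode == "active-stress")
    field_at_qp(prob$sys$space, tables, state$Ta)
  else
    state$xi
}

#' One coupled semi-implicit step
#'
#' (1) explicit ionic reaction + stimulus at the nodes; (2) implicit
#' stress-assisted diffusion using the last-step deformation and Kirchhoff
#' stress; (3) activation update (active tension PDE or shortening ODE);
#' (4) mechanics Newton solve with Newmark inertia and the updated
#' activation.
#'
#' @param prob an [em_problem()]
#' @param state an `em_state`
#' @param dt time step (ms)
#' @param gate_method reaction integrator for the gates
#' @param mech_tol mechanics Newton tolerance
#' @return advanced `em_state`
#' @export
coupled_step <- function(prob, state, dt, gate_method = "rush-larsen",
                         mech_tol = 1e-6) {
  sys <- prob$sys
  ms <- prob$ms
  d <- sys$d
  nn <- sys$nn
  # (1) reaction + stimulus
  Iext <- protocol_value(prob$protocol, state$t, pts = ms$nodes)
  rs <- step_0d(list(v = state$v, r = state$r), dt, Iext, gate_method,
                prob$ionic)
  v_star <- rs$v
  r_new <- rs$r
  # (2) diffusion with last-step mechanics
  act_mono <- activation_qp(prob, state, ms$tables)
  tens <- tryCatch(
    mono_tensors(ms, state$z, act_mono, state$vel),
    error = function(e) stop("stage diffusion-tensors: ",
                             conditionMessage(e)))
  dstep <- tryCatch(monodomain_step(ms, v_star, tens, dt),
                    error = function(e) stop("stage diffusion: ",
                                             conditionMessage(e)))
  v_new <- dstep$v
  # (3) activation
  if (prob$mode == "active-stress") {
    I4f_nodal <- qp_to_nodal(sys$space, ms$tables, tens$I4f)
    tsys <- prob$tsys
    if (is.null(prob$cache$tafac) || !identical(prob$cache$tadt, dt)) {
      sgn <- if (prob$apars$literal_sign) -1 else 1
      A <- Matrix::Diagonal(x = tsys$ML * (1 / dt + sgn)) +
        prob$apars$alpha_hat * tsys$K
      prob$cache$tafac <- Matrix::lu(methods::as(A, "CsparseMatrix"))
      prob$cache$tadt <- dt
    }
    tsys$fac <- prob$cache$tafac
    Ta_new <- tryCatch(
      active_tension_step(state$Ta, r_new[, 3], I4f_nodal, dt, prob$apars,
                          tsys),
      error = function(e) stop("stage activation: ", conditionMessage(e)))
    xi_new <- state$xi
    act_mech <- field_at_qp(sys$space, sys$tables, Ta_new)
  } else {
    r3_qp <- field_at_qp(sys$space, ms$tables, r_new[, 3])
    xi_new <- shortening_step(state$xi, r3_qp, dt, prob$apars)
    Ta_new <- state$Ta
    act_mech <- xi_at_mech_qp(prob, xi_new)
  }
  # (4) mechanics (Newmark)
  beta <- prob$beta; gamma <- prob$gamma
  nnd <- d * nn
  u <- state$z[seq_len(nnd)]
  u_pred <- u + dt * state$vel + dt^2 * (0.5 - beta) * state$acc
  v_pred <- state$vel + dt * (1 - gamma) * state$acc
  dyn <- list(c_a = 1 / (beta * dt^2), c_v = gamma / (beta * dt),
              u_pred = u_pred, v_pred = v_pred)
  sol <- tryCatch(
    mech_solve(sys, state$z, act_mech, dyn = dyn, tol = mech_tol,
               cache = prob$cache),
    error = function(e) stop("stage mechanics: ", conditionMessage(e)))
  u_new <- sol$z[seq_len(nnd)]
  acc_new <- dyn$c_a * (u_new - u_pred)
  vel_new <- v_pred + gamma * dt * acc_new
  st <- list(t = state$t + dt, z = sol$z, vel = vel_new, acc = acc_new,
             v = v_new, r = r_new, Ta = Ta_new, xi = xi_new)
  class(st) <- "em_state"
  st
}

# lumped L2 projection of quadrature-point values to nodes
qp_to_nodal <- function(space, tables, qpvals) {
  nq <- length(tables$qw)
  cv <- matrix(qpvals, space$mesh$nc, nq, byrow = TRUE)
  num <- load_vector(space, tables, cv)
  den <- load_vector(space, tables, matrix(1, space$mesh$nc, nq))
  num / den
}

# xi stored on the monodomain rule; mechanics uses its own quadrature --
# transfer through the (lumped) nodal projection
xi_at_mech_qp <- function(prob, xi) {
  nodal <- qp_to_nodal(prob$sys$space, prob$ms$tables,
                       as.vector(t(xi)))
  field_at_qp(prob$sys$space, prob$sys$tables, nodal)
}

#' Run a coupled simulation
#'
#' Semi-implicit time loop with optional probe recording and stress
#' tracking.
#'
#' @param prob an [em_problem()]
#' @param T_end final time (ms)
#' @param dt time step (ms)
#' @param probes node indices whose potential trace is recorded
#' @param record_stress record peak |u| and Frobenius |Pi| every
#'   `record_stress` steps (0 = never)
#' @param state optional starting state (default [em_init_state()])
#' @param verbose print progress every 100 steps
#' @return list with final `state`, `times`, probe `traces`,
#'   `active_fraction` (share of nodes with v > 0.5 per step) and the
#'   `peak_displacement` / `peak_stress` summaries when tracked
#' @export
simulate_coupled <- function(prob, T_end, dt, probes = integer(0),
                             record_stress = 0, state = NULL,
                             verbose = FALSE) {
  if (is.null(state)) state <- em_init_state(prob)
  nt <- round(T_end / dt)
  times <- state$t + dt * seq_len(nt)
  traces <- matrix(NA_real_, nt, length(probes))
  afrac <- numeric(nt)
  peak_u <- 0
  peak_pi <- 0
  peak_pi_l2 <- 0
  d <- prob$sys$d
  nnd <- d * prob$sys$nn
  for (i in seq_len(nt)) {
    state <- coupled_step(prob, state, dt)
    if (length(probes)) traces[i, ] <- state$v[probes]
    afrac[i] <- mean(state$v > 0.5)
    if (record_stress > 0 && (i %% record_stress == 0)) {
      um <- matrix(state$z[seq_len(nnd)], ncol = d, byrow = TRUE)
      peak_u <- max(peak_u, sqrt(max(rowSums(um^2))))
      act <- activation_qp(prob, state, prob$sys$tables)
      if (prob$mode == "active-strain") act <- xi_at_mech_qp(prob, state$xi)
      ps <- mech_stress(prob$sys, state$z, act)
      peak_pi <- max(peak_pi, ps$frobenius_max)
      peak_pi_l2 <- max(peak_pi_l2, ps$frobenius_l2)
    }
    if (verbose && i %% 100 == 0)
      message(sprintf("t = %.1f ms, active fraction %.3f", state$t,
                      afrac[i]))
  }
  list(state = state, times = times, traces = traces,
       active_fraction = afrac, peak_displacement = peak_u,
       peak_stress = peak_pi, peak_stress_l2 = peak_pi_l2)
}
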