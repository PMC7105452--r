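#' Minimal human ventricular cell model (epicardial parameter set)
#'
#' Four-variable phenomenological model of the human ventricular action
#' potential: a dimensionless transmembrane potential `v` and three gating
#' variables `r1`, `r2`, `r3`. The constants below are the epicardial set in
#' this model's renamed notation; the mapping to the originally published
#' (u, v, w, s) symbols is:
#'
#' | here            | original | here             | original  |
#' |-----------------|----------|------------------|-----------|
#' | v, r1, r2, r3   | u,v,w,s  | tau1m1, tau1m2   | tau_v1-, tau_v2- |
#' | v0, vv          | u_o, u_u | tau1p            | tau_v+    |
#' | th1, th2        | theta_v, theta_w | tau2m1, tau2m2 | tau_w1-, tau_w2- |
#' | th1m, tho       | theta_v-, theta_o | tau2p           | tau_w+    |
#' | v2m, vso, v3    | u_w-, u_so, u_s | tau2inf, r2inf  | tau_w_inf, w_inf* |
#' | k2m, kso, k3    | k_w-, k_so, k_s | tauo1, tauo2    | tau_o1, tau_o2 |
#' | taufi, tausi    | tau_fi, tau_si | tauso1, tauso2  | tau_so1, tau_so2 |
#' | tau31, tau32    | tau_s1, tau_s2 | chi             | chi       |
#'
#' All quantities are dimensionless except the time constants (ms).
#' Heaviside gates use the H(0) = 0 convention (strict threshold crossing),
#' so the rest state v = v0 = 0 carries no current.
#'
#' @param ... named overrides of individual constants
#' @return list of class `ionic_params`
#' @export
ionic_params_epi <- function(...) {
  p <- list(
    v0 = 0, vv = 1.55, th1 = 0.3, th2 = 0.13, th1m = 0.006, tho = 0.006,
    v2m = 0.03, vso = 0.65, v3 = 0.908,
    k2m = 65, kso = 2.045, k3 = 2.099,
    tau1m1 = 60, tau1m2 = 1150, tau1p = 1.451,
    tau2m1 = 60, tau2m2 = 15, tau2p = 200,
    tau2inf = 0.07, r2inf = 0.94,
    taufi = 0.11, tauo1 = 400, tauo2 = 6,
    tauso1 = 30.0181, tauso2 = 0.9957,
    tau31 = 2.734, tau32 = 16, tausi = 1.888,
    chi = 1)
  over <- list(...)
  stopifnot(all(names(over) %in% names(p)))
  p[names(over)] <- over
  tc <- c("tau1m1", "tau1m2", "tau1p", "tau2m1", "tau2m2", "tau2p",
          "taufi", "tauo1", "tauo2", "tauso1", "tauso2", "tau31", "tau32",
          "tausi")
  stopifnot(all(unlist(p[tc]) > 0))
  class(p) <- "ionic_params"
  p
}

# Heaviside with H(0) = 0
H <- function(x) as.numeric(x > 0)

#' Ionic currents of the minimal model
#'
#' Returns the fast-inward, slow-outward and slow-inward currents and the
#' total reaction g = -(Jfi + Jso + Jsi). Vectorised over states.
#'
#' @param v potential (dimensionless)
#' @param r length-3 gating vector, or a matrix with 3 columns
#' @param params [ionic_params_epi()] constants
#' @return list with `Jfi`, `Jso`, `Jsi`, `g`
#' @export
ionic_currents <- function(v, r, params = ionic_params_epi()) {
  if (is.null(dim(r))) r <- matrix(r, ncol = 3)
  if (!all(is.finite(v)) || !all(is.finite(r)))
    stop("non-finite ionic state")
  p <- params
  h1 <- H(v - p$th1); h2 <- H(v - p$th2); ho <- H(v - p$tho)
  tauo <- (1 - ho) * p$tauo1 + ho * p$tauo2
  tauso <- p$tauso1 +
    (p$tauso2 - p$tauso1) * (1 + tanh(p$kso * (v - p$vso))) / 2
  Jfi <- -r[, 1] * h1 * (v - p$th1) * (p$vv - v) / p$taufi
  Jso <- (v - p$v0) * (1 - h2) / tauo + h2 / tauso
  Jsi <- -h2 * r[, 2] * r[, 3] / p$tausi
  list(Jfi = Jfi, Jso = Jso, Jsi = Jsi, g = -(Jfi + Jso + Jsi))
}

#' Gating kinetics of the minimal model
#'
#' Right-hand side of the gating ODEs dr/dt = m(v, r), using the same
#' Heaviside convention as [ionic_currents()].
#'
#' @inheritParams ionic_currents
#' @return matrix with columns dr1, dr2, dr3
#' @export
gating_rhs <- function(v, r, params = ionic_params_epi()) {
  if (is.null(dim(r))) r <- matrix(r, ncol = 3)
  if (!all(is.finite(v)) || !all(is.finite(r)))
    stop("non-finite ionic state")
  ss <- gating_steady(v, params)
  cbind((ss$r1inf - r[, 1]) / ss$tau1,
        (ss$r2inf - r[, 2]) / ss$tau2,
        (ss$r3inf - r[, 3]) / ss$tau3)
}

# steady states and effective time constants of the (linear in r) gate ODEs;
# for gates 1 and 2 the above/below-threshold branches are merged into a
# single relaxation (r_inf, tau) pair, which is what Rush-Larsen exploits
gating_steady <- function(v, p) {
  h1 <- H(v - p$th1); h2 <- H(v - p$th2); ho <- H(v - p$tho)
  h1m <- H(v - p$th1m)
  tau1m <- (1 - h1m) * p$tau1m1 + h1m * p$tau1m2
  tau2m <- p$tau2m1 +
    (p$tau2m2 - p$tau2m1) * (1 + tanh(p$k2m * (v - p$v2m))) / 2
  r1inf_sub <- as.numeric(v < p$th1m)
  r2inf_sub <- (1 - ho) * (1 - v / p$tau2inf) + ho * p$r2inf
  tau1 <- ifelse(h1 > 0, p$tau1p, tau1m)
  r1inf <- ifelse(h1 > 0, 0, r1inf_sub)
  tau2 <- ifelse(h2 > 0, p$tau2p, tau2m)
  r2inf <- ifelse(h2 > 0, 0, r2inf_sub)
  tau3 <- (1 - h2) * p$tau31 + h2 * p$tau32
  r3inf <- (1 + tanh(p$k3 * (v - p$v3))) / 2
  list(r1inf = r1inf, tau1 = tau1, r2inf = r2inf, tau2 = tau2,
       r3inf = r3inf, tau3 = tau3)
}

#' One reaction step of the 0D cell model
#'
#' Advances (v, r) by an explicit potential update plus either an explicit
#' Euler or a Rush-Larsen (exponential, exact for frozen v) gate update.
#'
#' @param state list with `v` and `r` (vectorised: v vector, r matrix)
#' @param dt time step (ms), > 0
#' @param Istim stimulus current (dimensionless)
#' @param method "rush-larsen" or "explicit-euler"
#' @param params [ionic_params_epi()] constants
#' @export
step_0d <- function(state, dt, Istim = 0,
                    method = c("rush-larsen", "explicit-euler"),
                    params = ionic_params_epi()) {
  if (dt <= 0) stop("dt must be > 0")
  method <- match.arg(method)
  v <- state$v
  r <- if (is.null(dim(state$r))) matrix(state$r, ncol = 3) else state$r
  cur <- ionic_currents(v, r, params)
  v_new <- v + dt * (cur$g + Istim) / params$chi
  if (method == "explicit-euler") {
    r_new <- r + dt * gating_rhs(v, r, params)
  } else {
    ss <- gating_steady(v, params)
    r_new <- cbind(ss$r1inf + (r[, 1] - ss$r1inf) * exp(-dt / ss$tau1),
                   ss$r2inf + (r[, 2] - ss$r2inf) * exp(-dt / ss$tau2),
                   ss$r3inf + (r[, 3] - ss$r3inf) * exp(-dt / ss$tau3))
  }
  list(v = v_new, r = r_new)
}

#' Stimulus protocol
#'
#' A list of stimuli, each with an onset (ms), duration (ms), amplitude and
#' an optional spatial support predicate `where(x)` (NULL = everywhere).
#'
#' @param ... individual stimuli created by [stimulus()]
#' @export
stimulus_protocol <- function(...) {
  st <- list(...)
  for (s in st) stopifnot(inherits(s, "cem_stimulus"))
  on <- vapply(st, function(s) s$onset, 0)
  off <- on + vapply(st, function(s) s$duration, 0)
  if (length(st) > 1) {
    o <- order(on)
    if (any(off[o][-length(o)] > on[o][-1]))
      warning("overlapping stimuli in protocol")
  }
  structure(list(stimuli = st), class = "cem_protocol")
}

#' @rdname stimulus_protocol
#' @param onset,duration onset time and duration (ms)
#' @param amplitude dimensionless amplitude
#' @param where predicate on coordinates (matrix rows), or NULL
#' @export
stimulus <- function(onset, duration, amplitude, where = NULL) {
  stopifnot(duration > 0)
  structure(list(onset = onset, duration = duration, amplitude = amplitude,
                 where = where), class = "cem_stimulus")
}

# stimulus value at time t for points `pts` (n x d matrix or NULL for 0D)
protocol_value <- function(protocol, t, pts = NULL, n = 1L) {
  if (!is.null(pts)) n <- nrow(pts)
  out <- numeric(n)
  for (s in protocol$stimuli) {
    if (t >= s$onset && t < s$onset + s$duration) {
      if (is.null(s$where) || is.null(pts)) out <- out + s$amplitude
      else out <- out + s$amplitude * as.numeric(s$where(pts))
    }
  }
  out
}

#' Run the 0D cell model
#'
#' Integrates a single cell under a pacing protocol from the rest state
#' v = 0, r = (1, 1, 0) and reports the trace and action-potential features.
#'
#' @param params [ionic_params_epi()] constants
#' @param protocol a [stimulus_protocol()] (spatial predicates ignored)
#' @param T_end final time (ms)
#' @param dt time step (ms)
#' @param method gate integrator, see [step_0d()]
#' @param apd_level fractional repolarisation for the APD measure (default
#'   0.9, i.e. APD90 relative to the beat's own amplitude)
#' @return list with `trace` (data.frame t, v, r1, r2, r3) and `features`
#'   (peak v, APD)
#' @export
run_0d <- function(params = ionic_params_epi(), protocol, T_end, dt,
                   method = "rush-larsen", apd_level = 0.9) {
  stopifnot(T_end > dt, dt > 0)
  if (missing(protocol)) stop("a stimulus protocol is required")
  nt <- floor(T_end / dt)
  v <- numeric(nt + 1)
  r <- matrix(0, nt + 1, 3)
  v[1] <- 0; r[1, ] <- c(1, 1, 0)
  st <- list(v = 0, r = matrix(c(1, 1, 0), 1))
  tgrid <- (0:nt) * dt
  for (i in seq_len(nt)) {
    Ist <- protocol_value(protocol, tgrid[i], n = 1L)
    st <- step_0d(st, dt, Ist, method, params)
    v[i + 1] <- st$v
    r[i + 1, ] <- st$r
  }
  trace <- data.frame(t = tgrid, v = v, r1 = r[, 1], r2 = r[, 2],
                      r3 = r[, 3])
  list(trace = trace,
       features = ap_features(tgrid, v, apd_level = apd_level))
}

#' Action-potential features of a voltage trace
#'
#' Peak potential and action-potential duration at a fractional
#' repolarisation level of the beat's own amplitude (default APD90),
#' measured from the upstroke mid-level crossing with linear interpolation.
#'
#' @param t,v time (ms) and potential vectors
#' @param apd_level fractional repolarisation (0.9 = APD90)
#' @export
ap_features <- function(t, v, apd_level = 0.9) {
  vmax <- max(v)
  base <- v[1]
  amp <- vmax - base
  if (amp <= 0.1) return(list(peak = vmax, apd = NA_real_))
  thr <- vmax - apd_level * amp
  ipk <- which.max(v)
  up <- which(v[seq_len(ipk)] >= thr)
  t_up <- t[up[1]]
  dn <- which(v >= thr & seq_along(v) >= ipk)
  iend <- dn[length(dn)]
  t_dn <- if (iend < length(v)) {
    # linear interpolation of the downward crossing
    t[iend] + (t[iend + 1] - t[iend]) *
      (v[iend] - thr) / (v[iend] - v[iend + 1])
  } else t[iend]
  list(peak = vmax, apd = t_dn - t_up)
}
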