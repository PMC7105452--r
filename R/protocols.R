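#' Experiment fixtures
#'
#' Meshes with boundary labels and constant analytic fibre frames for the
#' bundled experiments:
#' \itemize{
#' \item `unit-square`: (0,1)^2, n = 2^resolution per side, frame
#'   f0 = (0,1), s0 = (-1,0) (convergence test).
#' \item `slab2d`: Lx x Ly mm slab (default 50 x 50), f0 = (1,0),
#'   s0 = (0,-1), Robin boundary everywhere.
#' \item `slab3d`: 50 x 50 x 10 mm slab (scalable), f0 = (1,0,0),
#'   s0 = (0,1,0), Robin everywhere.
#' \item `cook`: the tapered Cook membrane, clamped left edge, dead shear
#'   traction on the right edge, f0 = (1,0), s0 = (0,-1).
#' \item `beam`: (0,10) x (0,1) x (0,1) mm cantilever, clamped at x = 0,
#'   follower pressure on the bottom face, f0 = (1,0,0), s0 = (0,1,0).
#' }
#'
#' @param kind fixture name
#' @param resolution mesh resolution (meaning depends on the fixture)
#' @param Lx,Ly,Lz overrides of the slab dimensions (mm)
#' @return list with `mesh` and `frame`
#' @export
make_fixture <- function(kind = c("unit-square", "slab2d", "slab3d",
                                  "cook", "beam"),
                         resolution = 1, Lx = NULL, Ly = NULL, Lz = NULL) {
  kind <- match.arg(kind)
  stopifnot(resolution >= 1)
  switch(kind,
    "unit-square" = {
      mesh <- unit_square_mesh(2^resolution)
      list(mesh = mesh, frame = fibre_frame(c(0, 1), c(-1, 0)))
    },
    "slab2d" = {
      if (is.null(Lx)) Lx <- 50
      if (is.null(Ly)) Ly <- Lx
      mesh <- rect_mesh(resolution, resolution, Lx, Ly)
      mesh$blabel[] <- "R"
      list(mesh = mesh, frame = fibre_frame(c(1, 0), c(0, -1)),
           Lx = Lx, Ly = Ly)
    },
    "slab3d" = {
      if (is.null(Lx)) Lx <- 50
      if (is.null(Ly)) Ly <- 50
      if (is.null(Lz)) Lz <- 10
      n <- resolution
      mesh <- box_mesh(n, n, max(1, round(n * Lz / Lx)), Lx, Ly, Lz)
      mesh$blabel[] <- "R"
      list(mesh = mesh, frame = fibre_frame(c(1, 0, 0), c(0, 1, 0)),
           Lx = Lx, Ly = Ly, Lz = Lz)
    },
    "cook" = {
      mesh <- cook_mesh(resolution)
      cen <- facet_centroids(mesh)
      mesh$blabel[] <- "free"
      mesh$blabel[cen[, 1] > 48 - 1e-9] <- "T"
      list(mesh = mesh, frame = fibre_frame(c(1, 0), c(0, -1)))
    },
    "beam" = {
      n <- resolution
      mesh <- box_mesh(10 * n, n, n, 10, 1, 1)
      cen <- facet_centroids(mesh)
      mesh$blabel[] <- "free"
      mesh$blabel[cen[, 3] < 1e-9] <- "N"
      list(mesh = mesh, frame = fibre_frame(c(1, 0, 0), c(0, 1, 0)))
    })
}

#' S1-S2 cross-field stimulation protocol
#'
#' S1 is a planar wave from the left edge (2D) or the bottom section (3D)
#' at t = 0; S2 excites the bottom-left quadrant at t = 330 ms (2D) or the
#' bottom-left octant at t = 335 ms (3D). Both stimuli have dimensionless
#' amplitude 3 and duration 3 ms.
#'
#' @param Lx,Ly,Lz slab dimensions (mm); Lz = NULL for 2D
#' @param s1_frac fraction of the domain width covered by S1
#' @param s2_onset override of the S2 onset time
#' @return a [stimulus_protocol()]
#' @export
s1s2_protocol <- function(Lx, Ly = Lx, Lz = NULL, s1_frac = 0.05,
                          s2_onset = NULL) {
  if (is.null(Lz)) {
    if (is.null(s2_onset)) s2_onset <- 330
    stimulus_protocol(
      stimulus(0, 3, 3, function(x) x[, 1] <= s1_frac * Lx + 1e-9),
      stimulus(s2_onset, 3, 3,
               function(x) x[, 1] <= Lx / 2 + 1e-9 &
                 x[, 2] <= Ly / 2 + 1e-9))
  } else {
    if (is.null(s2_onset)) s2_onset <- 335
    stimulus_protocol(
      stimulus(0, 3, 3, function(x) x[, 3] <= s1_frac * Lz + 1e-9),
      stimulus(s2_onset, 3, 3,
               function(x) x[, 1] <= Lx / 2 + 1e-9 &
                 x[, 2] <= Ly / 2 + 1e-9 & x[, 3] <= Lz / 2 + 1e-9))
  }
}

#' @rdname s1s2_protocol
#' @param t time (ms); @param pts coordinates
#' @param protocol a protocol built by [s1s2_protocol()]
#' @export
s1s2_stimulus <- function(t, pts, protocol) {
  protocol_value(protocol, t, pts = pts)
}

#' Conduction velocity from activation traces
#'
#' First-crossing times of a threshold at two probes with linear-in-time
#' interpolation; CV = distance / time difference.
#'
#' @param times time grid (ms)
#' @param traces matrix of potential traces (rows = times, two columns)
#' @param x1,x2 probe abscissae (mm)
#' @param threshold crossing level (mid-upstroke default 0.5)
#' @return conduction velocity (mm/ms)
#' @export
conduction_velocity <- function(times, traces, x1, x2, threshold = 0.5) {
  tc <- vapply(1:2, function(j) {
    v <- traces[, j]
    i <- which(v >= threshold)[1]
    if (is.na(i)) stop(sprintf("probe %d never activated", j))
    if (i == 1) return(times[1])
    times[i - 1] + (times[i] - times[i - 1]) *
      (threshold - v[i - 1]) / (v[i] - v[i - 1])
  }, numeric(1))
  (x2 - x1) / (tc[2] - tc[1])
}

#' Conduction-velocity study on the small slab
#'
#' Coupled electromechanics on the 12 x 12 mm slab (f0 = (1,0),
#' s0 = (0,-1), Robin boundaries, active stress, lowest-order elements,
#' zeta_stab = 2.5): S1 planar wave from the left edge, horizontal
#' propagation measured between probes on the line y = 7 mm.
#'
#' @param n mesh subdivisions per side (44 gives the ~27k-dof
#'   configuration, h = 0.39 mm)
#' @param dts time steps to test (ms)
#' @param x_probe probe abscissae (mm)
#' @param D2 stress-assisted diffusion weight (printed units)
#' @param viscous include the Kelvin-Voigt stress
#' @param T_max simulation cutoff (ms)
#' @param verbose progress
#' @return data.frame with dt and cv (mm/ms)
#' @export
cv_study <- function(n = 44, dts = c(0.3, 0.1, 0.05), x_probe = c(3, 9),
                     D2 = 0.01, viscous = FALSE, T_max = 150,
                     verbose = FALSE) {
  fx <- make_fixture("slab2d", n, Lx = 12)
  cond <- conductivity_params(D2 = D2)
  prob <- em_problem(fx$mesh, l = 0, frame = fx$frame,
                     mode = "active-stress", cond = cond,
                     viscous = viscous, eta = 0.01, zeta_stab = 2.5,
                     protocol = s1s2_protocol(12, s1_frac = 0.05))
  nodes <- prob$ms$nodes
  probes <- vapply(x_probe, function(xx)
    which.min((nodes[, 1] - xx)^2 + (nodes[, 2] - 7)^2), 0L)
  out <- data.frame(dt = dts, cv = NA_real_)
  for (k in seq_along(dts)) {
    dt <- dts[k]
    st <- em_init_state(prob)
    nt <- round(T_max / dt)
    times <- dt * seq_len(nt)
    traces <- matrix(NA_real_, nt, 2)
    for (i in seq_len(nt)) {
      st <- coupled_step(prob, st, dt)
      traces[i, ] <- st$v[probes]
      # stop a few steps after the far probe activates
      if (st$v[probes[2]] > 0.8 && i > 5) {
        traces <- traces[seq_len(i), , drop = FALSE]
        times <- times[seq_len(i)]
        break
      }
    }
    out$cv[k] <- conduction_velocity(times, traces, x_probe[1], x_probe[2])
    if (verbose) message(sprintf("dt = %.3g ms: CV = %.4f mm/ms", dt,
                                 out$cv[k]))
  }
  out
}

#' Cook membrane benchmark
#'
#' Fully incompressible Holzapfel-Ogden material with constant active
#' tension Ta = 0.7 kPa (0.07 N/cm^2), clamped left edge and an upward
#' in-plane dead shear load t = (0, 100) kPa on the right edge (read in
#' kPa like the neighbouring beam benchmark's pressure), applied
#' incrementally. Reports the vertical
#' deflection of the upper-right vertex.
#'
#' @param resolution subdivisions per side
#' @param l stress degree (0 or 1)
#' @param zeta_stab stabilisation constant
#' @param Ta active tension (kPa)
#' @param load final shear traction (kPa)
#' @param nsteps load increments
#' @return list with `deflection` (mm), `tip` node id and the solution
#' @export
cook_membrane <- function(resolution = 4, l = 0, zeta_stab = 0.25,
                          Ta = 0.7, load = 100, nsteps = 20) {
  fx <- make_fixture("cook", resolution)
  mesh <- fx$mesh
  sys <- mech_system(mesh, l = l, frame = fx$frame, mode = "active-stress",
                     zeta_stab = zeta_stab)
  clamp <- which(sys$space$node_coords[, 1] < 1e-9)
  act <- matrix(Ta, mesh$nc, length(sys$tables$qw))
  z <- numeric(sys$nz)
  z[2 * sys$nn + seq_len(sys$nn)] <- sys$ho$a
  # adaptive incremental loading (the panel softens sharply at small load
  # and stiffens exponentially later)
  lcur <- 0
  dstep <- load / nsteps
  while (lcur < load - 1e-9) {
    ltry <- min(lcur + dstep, load)
    sysl <- mech_set_bcs(sys, traction = c(0, ltry),
                         dirichlet_nodes = clamp)
    sol <- tryCatch(mech_solve(sysl, z, act_qp = act, tol = 1e-8),
                    error = function(e) NULL)
    if (is.null(sol)) {
      dstep <- dstep / 2
      if (dstep < load / 5000)
        stop(sprintf("load stepping failed at t = (0, %.1f)", lcur))
      next
    }
    z <- sol$z
    lcur <- ltry
    dstep <- dstep * 1.3
  }
  tip <- which.min((sys$space$node_coords[, 1] - 48)^2 +
                   (sys$space$node_coords[, 2] - 60)^2)
  list(deflection = z[(tip - 1) * 2 + 2], tip = tip, z = z, sys = sys)
}

#' Cantilever beam benchmark (Guccione material)
#'
#' Passive 3D beam (0,10) x (0,1) x (0,1) mm, fibres along the axis,
#' clamped at x = 0, follower pressure p_N = 0.004 kPa on the bottom face
#' (Nanson-scaled with the deformed area), traction-free elsewhere.
#' Reports the vertical deflection of the free-end midpoint.
#'
#' @param resolution elements across the beam thickness
#' @param l stress degree
#' @param p_N follower pressure (kPa)
#' @param nsteps load increments
#' @param zeta_stab stabilisation constant
#' @export
land_beam <- function(resolution = 2, l = 0, p_N = 0.004, nsteps = 4,
                      zeta_stab = 0.25) {
  fx <- make_fixture("beam", resolution)
  mesh <- fx$mesh
  sys <- mech_system(mesh, l = l, frame = fx$frame,
                     material = "guccione", mode = "active-stress",
                     zeta_stab = zeta_stab)
  clamp <- which(sys$space$node_coords[, 1] < 1e-9)
  z <- numeric(sys$nz)   # Guccione rest pressure is zero
  pcur <- 0
  dstep <- p_N / nsteps
  while (pcur < p_N - 1e-15) {
    ptry <- min(pcur + dstep, p_N)
    sysl <- mech_set_bcs(sys, p_N = ptry, dirichlet_nodes = clamp)
    sol <- tryCatch(mech_solve(sysl, z, tol = 1e-9),
                    error = function(e) NULL)
    if (is.null(sol)) {
      dstep <- dstep / 2
      if (dstep < p_N / 1000)
        stop(sprintf("load stepping failed at p_N = %.4g", pcur))
      next
    }
    z <- sol$z
    pcur <- ptry
    dstep <- dstep * 1.3
  }
  tipc <- c(10, 0.5, 0.5)
  tip <- which.min(rowSums(sweep(sys$space$node_coords, 2, tipc)^2))
  list(deflection = z[(tip - 1) * 3 + 3], tip = tip, z = z, sys = sys)
}

#' Boundary profiles for ventricle-type loading
#'
#' Linear apex-to-base Robin stiffness eta(y) and the sinusoidal endocardial
#' pressure p_N(t) = p0 sin^2(pi t).
#'
#' @param y vertical coordinate(s); @param t time(s) (in the pressure
#'   cycle's unit period)
#' @param ya,yb apical and basal vertical coordinates (ya < yb)
#' @param eta_a,eta_b apical/basal stiffnesses
#' @param p0 peak pressure
#' @return list with `eta` and `p_N`
#' @export
boundary_profiles <- function(y, t, ya = 0, yb = 1, eta_a = 0.001,
                              eta_b = 0.01, p0 = 0.1) {
  if (ya >= yb) stop("ya must be < yb")
  eta <- (eta_a * (yb - y) + eta_b * (y - ya)) / (yb - ya)
  list(eta = eta, p_N = p0 * sin(pi * t)^2)
}

#' S1-S2 spiral (reentry) run on the large slab
#'
#' Coupled electromechanics on the 50 x 50 mm slab with the S1-S2 protocol,
#' recording the active fraction (share of nodes with v > 0.5). The
#' spiral-persistence criterion asks that the active fraction stay within
#' (0.02, 0.9) throughout the assessment window, i.e. reentrant activity
#' neither dies out nor saturates the tissue.
#'
#' @param n mesh subdivisions per side
#' @param dt time step (ms)
#' @param T_end final time (ms)
#' @param window assessment window (ms)
#' @param D2 stress-assisted diffusion weight (printed units)
#' @param viscous include viscosity
#' @param verbose progress
#' @return list with the simulation output, `persistent` flag and the
#'   active-fraction range over the window
#' @export
spiral_run <- function(n = 40, dt = 0.1, T_end = 500,
                       window = c(400, 500), D2 = 0.01, viscous = TRUE,
                       verbose = FALSE) {
  fx <- make_fixture("slab2d", n, Lx = 50)
  prob <- em_problem(fx$mesh, l = 0, frame = fx$frame,
                     mode = "active-stress",
                     cond = conductivity_params(D2 = D2),
                     viscous = viscous, eta = 0.01, zeta_stab = 2.5,
                     protocol = s1s2_protocol(50))
  res <- simulate_coupled(prob, T_end, dt, verbose = verbose)
  inwin <- res$times >= window[1] & res$times <= window[2]
  af <- res$active_fraction[inwin]
  list(result = res, persistent = all(af > 0.02 & af < 0.9),
       af_range = range(af))
}

#' Hyperelastic vs viscoelastic slab comparison
#'
#' Planar S1 wave on a 3D slab (active stress, Robin boundaries, inertial
#' terms); runs the model with and without the Kelvin-Voigt stress and
#' reports the peak displacement magnitude and peak Frobenius norm of the
#' Kirchhoff stress.
#'
#' @param n in-plane subdivisions; @param Lx,Ly,Lz slab size (mm)
#' @param dt time step; @param T_end final time (ms)
#' @param record_stress stress sampling stride (steps)
#' @param verbose progress
#' @return data.frame with one row per case
#' @export
viscosity_comparison <- function(n = 8, Lx = 20, Ly = 20, Lz = 5,
                                 dt = 0.1, T_end = 60, record_stress = 10,
                                 verbose = FALSE) {
  out <- NULL
  for (visc in c(FALSE, TRUE)) {
    fx <- make_fixture("slab3d", n, Lx = Lx, Ly = Ly, Lz = Lz)
    protocol <- stimulus_protocol(
      stimulus(0, 3, 3, function(x) x[, 1] <= 0.05 * Lx + 1e-9))
    prob <- em_problem(fx$mesh, l = 0, frame = fx$frame,
                       mode = "active-stress", viscous = visc,
                       eta = 0.01, zeta_stab = 25, protocol = protocol)
    res <- simulate_coupled(prob, T_end, dt,
                            record_stress = record_stress,
                            verbose = verbose)
    out <- rbind(out, data.frame(viscous = visc,
                                 peak_displacement = res$peak_displacement,
                                 peak_stress = res$peak_stress,
                                 peak_stress_l2 = res$peak_stress_l2))
  }
  out
}
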