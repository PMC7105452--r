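test_that("discrete space dimensions match combinatorial counts", {
  mesh <- unit_square_mesh(2)
  expect_equal(mesh$nc, 8)
  expect_equal(mesh$np, 9)
  sp1 <- build_space(mesh, 1)
  expect_equal(sp1$ndof, 9)
  sp2 <- build_space(mesh, 2)
  # Euler: E = V + C + 1 - 2 for a planar triangulated disc
  expect_equal(sp2$ndof, mesh$np + (mesh$np + mesh$nc - 1))
  # stress space: 3 components per cell at lowest order in 2D
  expect_equal(ncol(cardioem:::pi_phi(2, 0, simplex_quadrature(2, 2))), 1)
  m2 <- refine_mesh(mesh)
  expect_equal(m2$nc, 4 * mesh$nc)
  expect_error(build_space(mesh, 3))
})

test_that("pressure stabilisation vanishes on constants and scales as h^2", {
  for (n in c(4, 8)) {
    mesh <- unit_square_mesh(n)
    sp <- build_space(mesh, 1)
    sm <- cardioem:::scalar_matrices(sp)
    ones <- rep(1, sp$ndof)
    expect_lt(max(abs(sm$Kh2 %*% ones)), 1e-12)
  }
  # fixed linear pressure: halving h scales the weighted form by 1/4
  val <- sapply(c(4, 8), function(n) {
    mesh <- unit_square_mesh(n)
    sp <- build_space(mesh, 1)
    sm <- cardioem:::scalar_matrices(sp)
    p <- sp$node_coords[, 1]          # grad p = (1, 0)
    as.numeric(p %*% sm$Kh2 %*% p)
  })
  expect_equal(val[2] / val[1], 0.25, tolerance = 1e-10)
})

test_that("stress-free reference state has zero mechanics residual", {
  fx <- make_fixture("slab2d", 4, Lx = 10)
  sys <- mech_system(fx$mesh, l = 0, frame = fx$frame)
  sys <- mech_set_bcs(sys, eta = 0.01)
  z <- numeric(sys$nz)
  z[2 * sys$nn + seq_len(sys$nn)] <- ho_params()$a
  rj <- cardioem:::mech_residual(sys, z, jac = FALSE)
  expect_lt(max(abs(rj$res)), 1e-11)
})

test_that("static Robin-supported solve balances momentum", {
  fx <- make_fixture("slab2d", 4, Lx = 10)
  sys <- mech_system(fx$mesh, l = 0, frame = fx$frame)
  sys <- mech_set_bcs(sys, eta = 0.1)
  z0 <- numeric(sys$nz)
  z0[2 * sys$nn + seq_len(sys$nn)] <- ho_params()$a
  act <- matrix(0.5, fx$mesh$nc, length(sys$tables$qw))  # constant tension
  sol <- mech_solve(sys, z0, act_qp = act, tol = 1e-9)
  expect_true(sol$converged)
  rj <- cardioem:::mech_residual(sys, sol$z, act, jac = FALSE)
  # converged residual => total force balance within solver tolerance
  ures <- rj$res[seq_len(2 * sys$nn)]
  expect_lt(max(abs(sum(ures[seq(1, 2 * sys$nn, 2)])),
                abs(sum(ures[seq(2, 2 * sys$nn, 2)]))), 1e-8)
  # incompressibility in the large
  ps <- mech_stress(sys, sol$z, act)
  expect_lt(ps$incompressibility_l2, 1e-2)
  # Kirchhoff stress symmetry at the quadrature points (2D: Pi12 = Pi21)
  expect_lt(max(abs(ps$Pi[, 2] - ps$Pi[, 3])), 1e-9 * max(abs(ps$Pi)))
})

test_that("monodomain leaves constants invariant and conserves charge", {
  fx <- make_fixture("slab2d", 6, Lx = 6)
  sys <- mech_system(fx$mesh, l = 0, frame = fx$frame)
  sys <- mech_set_bcs(sys, eta = 0.01)
  ms <- mono_system(sys)
  z <- numeric(sys$nz)
  z[2 * sys$nn + seq_len(sys$nn)] <- ho_params()$a
  tens <- cardioem:::mono_tensors(ms, z)
  # constant state is a zero-flux steady state
  vconst <- rep(0.3, sys$nn)
  out <- monodomain_step(ms, vconst, tens, dt = 0.1)
  expect_lt(max(abs(out$v - 0.3)), 1e-12)
  # pure diffusion conserves the lumped integral of v
  set.seed(4)
  v0 <- runif(sys$nn)
  a <- cardioem:::.asm_mono_system(fx$mesh$coords, fx$mesh$cells,
                                   sys$space$dof, ms$tables, v0,
                                   tens$Ageo, tens$Afib, tens$Asad,
                                   ms$cond$D0i, ms$cond$D1i, ms$cond$D2i,
                                   0)
  v1 <- monodomain_step(ms, v0, tens, dt = 0.5)$v
  expect_equal(sum(a$ML * v1), sum(a$ML * v0), tolerance = 1e-10)
})

test_that("implicit diffusion matches a dense finite-difference cable", {
  # thin strip, fibres along x: compare the FE solution of pure diffusion
  # of a smooth bump against a fine 1D finite-difference oracle
  L <- 8
  errs <- sapply(c(16, 32), function(n) {
    mesh <- rect_mesh(n, 1, L, L / n)
    mesh$blabel[] <- "R"
    fr <- fibre_frame(c(1, 0), c(0, -1))
    sys <- mech_system(mesh, l = 0, frame = fr)
    sys <- mech_set_bcs(sys, eta = 0.01)
    ms <- mono_system(sys, cond = conductivity_params(D1 = 0, D2 = 0))
    z <- numeric(sys$nz)
    z[2 * sys$nn + seq_len(sys$nn)] <- ho_params()$a
    tens <- cardioem:::mono_tensors(ms, z)
    x <- sys$space$node_coords[, 1]
    v <- exp(-(x - L / 2)^2)
    dt <- 0.05
    for (k in 1:40) v <- monodomain_step(ms, v, tens, dt)$v
    # dense 1D oracle (implicit Euler, very fine grid), D along fibres
    Dx <- 1.5 * ms$cond$D0i
    nfd <- 400
    xf <- seq(0, L, length.out = nfd + 1)
    h <- L / nfd
    vf <- exp(-(xf - L / 2)^2)
    A <- diag(nfd + 1)
    for (i in 2:nfd) {
      A[i, i] <- 1 + 2 * dt * Dx / h^2
      A[i, i - 1] <- A[i, i + 1] <- -dt * Dx / h^2
    }
    A[1, 1] <- 1 + dt * Dx / h^2; A[1, 2] <- -dt * Dx / h^2
    A[nfd + 1, nfd + 1] <- 1 + dt * Dx / h^2
    A[nfd + 1, nfd] <- -dt * Dx / h^2
    Ainv <- solve(A)
    for (k in 1:40) vf <- Ainv %*% vf
    vref <- approx(xf, vf, xout = sort(unique(x)))$y
    vbar <- tapply(v, x, mean)
    max(abs(vbar[order(as.numeric(names(vbar)))] - vref))
  })
  expect_lt(errs[2], 0.7 * errs[1])   # converging to the oracle
  expect_lt(errs[2], 0.02)
})

test_that("generic Newton driver converges quadratically", {
  resid <- function(z) c(z[1]^2 - 1, z[2] - 2)
  jac <- function(z) Matrix::Matrix(rbind(c(2 * z[1], 0), c(0, 1)),
                                    sparse = TRUE)
  out <- newton_solve(resid, jac, c(2, 0), tol = 1e-12)
  expect_equal(out$z, c(1, 2), tolerance = 1e-10)
  # quadratic tail: residual ratios square
  r <- out$residuals
  r <- r[r > 1e-14]
  if (length(r) >= 3) {
    n <- length(r)
    expect_lt(r[n], r[n - 1]^2 / r[n - 2] * 10)
  }
  out0 <- newton_solve(resid, jac, c(1, 2), tol = 1e-12)
  expect_equal(out0$iterations, 0L)
  expect_error(newton_solve(resid, jac, c(-50, 0), tol = 1e-12, maxit = 2),
               "Newton failed")
})
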