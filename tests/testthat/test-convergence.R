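test_that("manufactured closed forms take their printed centre values", {
  mf <- manufactured_fields(matrix(c(0.5, 0.5), 1))
  expect_equal(mf$u1, 0, tolerance = 1e-14)
  expect_equal(mf$u2, 0, tolerance = 1e-14)
  expect_equal(mf$p, 0.1, tolerance = 1e-14)
  expect_equal(mf$v, 1, tolerance = 1e-14)
  expect_equal(mf$Ta, 1, tolerance = 1e-14)
})

test_that("compiled manufactured fields match the R closed forms", {
  set.seed(31)
  pts <- matrix(runif(40), ncol = 2)
  pl <- steady_param_list()
  ex <- cardioem:::.manufactured_exact(pts, pl)
  mf <- manufactured_fields(pts)
  expect_equal(ex$u[, 1], mf$u1, tolerance = 1e-12)
  expect_equal(ex$u[, 2], mf$u2, tolerance = 1e-12)
  expect_equal(as.vector(ex$p), mf$p, tolerance = 1e-12)
  expect_equal(as.vector(ex$v), mf$v, tolerance = 1e-12)
  expect_equal(as.vector(ex$r), mf$r, tolerance = 1e-12)
  expect_equal(as.vector(ex$Ta), mf$Ta, tolerance = 1e-12)
  # the exact Kirchhoff stress is assembled from the same constitutive
  # pieces the pointwise API exposes
  fr <- fibre_frame(c(0, 1), c(-1, 0))
  ho <- ho_params_verification()
  ho$gated <- FALSE
  i <- 3
  F <- diag(2) + 0.1 * pi * matrix(
    c(cos(pi * pts[i, 1]) * cos(pi * pts[i, 2]),
      -sin(pi * pts[i, 1]) * sin(pi * pts[i, 2]),
      -sin(pi * pts[i, 1]) * sin(pi * pts[i, 2]),
      cos(pi * pts[i, 1]) * cos(pi * pts[i, 2])), 2, 2)
  ks <- kirchhoff_stress("active-stress", F, mf$p[i], Ta = mf$Ta[i],
                         params = ho, frame = fr)
  expect_equal(as.vector(ks$Pi), ex$Pi[i, ], tolerance = 1e-10)
})

test_that("manufactured forcing balances the steady equations (independent
          flux differentiation)", {
  pl <- steady_param_list()
  pts <- matrix(c(0.37, 0.61), 1)
  frc <- cardioem:::.manufactured_forcing(pts, pl, 1e-5)
  # independent R-side central differencing of the mechanical flux
  fr <- fibre_frame(c(0, 1), c(-1, 0))
  ho <- ho_params_verification(); ho$gated <- FALSE
  flux <- function(x, y) {
    mfp <- manufactured_fields(matrix(c(x, y), 1))
    F <- diag(2) + rbind(mfp$du1[1, ], mfp$du2[1, ])
    ks <- kirchhoff_stress("active-stress", F, mfp$p, Ta = mfp$Ta,
                           params = ho, frame = fr)
    ks$Pi %*% t(solve(F))
  }
  h <- 1e-6
  divM <- (flux(0.37 + h, 0.61) - flux(0.37 - h, 0.61))[, 1] / (2 * h) +
    (flux(0.37, 0.61 + h) - flux(0.37, 0.61 - h))[, 2] / (2 * h)
  expect_equal(as.vector(frc$fu), as.vector(-divM), tolerance = 1e-4)
  mfp <- manufactured_fields(pts)
  expect_equal(as.vector(frc$fr), -(mfp$v - mfp$r^2), tolerance = 1e-12)
})

test_that("steady coupled solve converges at first order on a short
          ladder", {
  errs <- NULL
  for (n in c(4, 8)) {
    mesh <- unit_square_mesh(n)
    sol <- cardioem:::steady_solve(mesh, 0)
    errs <- rbind(errs, cardioem:::steady_errors(mesh, sol))
  }
  rates <- log2(errs[1, ] / errs[2, ])
  expect_gt(rates["Pi"], 0.8)
  expect_gt(rates["u"], 0.8)
  expect_gt(rates["v"], 0.8)
  expect_gt(rates["Ta"], 0.8)
})
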