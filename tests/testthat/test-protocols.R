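test_that("boundary profiles hit their endpoints", {
  bp <- boundary_profiles(y = c(0, 0.5, 1), t = c(0, 0.5),
                          ya = 0, yb = 1, eta_a = 0.001, eta_b = 0.01,
                          p0 = 0.1)
  expect_equal(bp$eta, c(0.001, 0.0055, 0.01))
  expect_equal(bp$p_N, c(0, 0.1))
  expect_error(boundary_profiles(0, 0, ya = 1, yb = 0), "ya")
})

test_that("S1-S2 stimulus has the printed timing and support", {
  pr <- s1s2_protocol(50)
  pts <- rbind(c(1, 25), c(10, 10), c(10, 40), c(30, 10))
  expect_equal(s1s2_stimulus(1, pts, pr), c(3, 0, 0, 0))     # S1 left edge
  expect_equal(s1s2_stimulus(100, pts, pr), rep(0, 4))       # between
  expect_equal(s1s2_stimulus(331, pts, pr), c(3, 3, 0, 0))   # S2 quadrant
  expect_equal(s1s2_stimulus(334, pts, pr), rep(0, 4))       # S2 over
  pr3 <- s1s2_protocol(50, 50, 10)
  p3 <- rbind(c(1, 1, 0.2), c(10, 10, 2), c(10, 40, 2))
  expect_equal(s1s2_stimulus(336, p3, pr3), c(3, 3, 0))
})

test_that("conduction velocity is exact on a constructed travelling front", {
  c0 <- 0.06
  times <- seq(0, 400, by = 0.5)
  x1 <- 3; x2 <- 9
  mkv <- function(x) pmin(1, pmax(0, (times * c0 - x) * 5))
  cv <- conduction_velocity(times, cbind(mkv(x1), mkv(x2)), x1, x2)
  expect_equal(cv, c0, tolerance = 1e-10)
  expect_error(conduction_velocity(times, cbind(mkv(3), mkv(100)), 3, 100),
               "never activated")
})

test_that("fixtures carry the printed geometries and frames", {
  us <- make_fixture("unit-square", 1)
  expect_equal(mesh_h(us$mesh), sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(us$frame$f0, c(0, 1))
  sl <- make_fixture("slab2d", 12, Lx = 12)
  expect_equal(range(sl$mesh$coords[, 1]), c(0, 12))
  expect_equal(sl$frame$s0, c(0, -1))
  expect_true(all(sl$mesh$blabel == "R"))
  ck <- make_fixture("cook", 2)
  expect_true(all(apply(ck$mesh$coords, 1, function(p)
    p[1] >= -1e-9 & p[1] <= 48 + 1e-9)))
  expect_equal(max(ck$mesh$coords[, 2]), 60)
  bm <- make_fixture("beam", 1)
  expect_equal(apply(bm$mesh$coords, 2, max), c(10, 1, 1))
  expect_equal(bm$frame$f0, c(1, 0, 0))
  expect_equal(sum(bm$mesh$blabel == "N") > 0, TRUE)
  expect_error(make_fixture("nope"))
})

test_that("follower pressure deflects the cantilever upward; doubling the
          load more than doubles it in the finite-strain regime", {
  b0 <- land_beam(resolution = 1, p_N = 0, nsteps = 1)
  expect_lt(abs(b0$deflection), 1e-10)
  b1 <- land_beam(resolution = 1, p_N = 0.004, nsteps = 2)
  expect_gt(b1$deflection, 0)
  # at the benchmark load the response is within a percent of linear;
  # deeper into the finite-strain regime geometric stiffening makes the
  # load-deflection curve sublinear
  b2 <- land_beam(resolution = 1, p_N = 0.008, nsteps = 4)
  expect_gt(b2$deflection, 1.9 * b1$deflection)
  expect_lt(b2$deflection, 2.0 * b1$deflection)
  b3 <- land_beam(resolution = 1, p_N = 0.04, nsteps = 10)
  expect_gt(b3$deflection, b2$deflection)
  expect_lt(b3$deflection, 5 * b2$deflection)
})
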