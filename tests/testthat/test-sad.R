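test_that("baseline conductivity is the transversely isotropic tensor", {
  fr <- fibre_frame(c(1, 0), c(0, -1))
  cp <- conductivity_params()
  D <- conductivity_tensor(0, diag(2), matrix(0, 2, 2), fr, cp)
  expect_equal(D, cp$D0i * diag(2) + cp$D0i / 2 * outer(c(1, 0), c(1, 0)),
               tolerance = 1e-12)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(ev), cp$D0i * c(1, 1.5), tolerance = 1e-12)
})

test_that("full tensor matches a dense matrix oracle", {
  set.seed(23)
  fr <- fibre_frame(c(1, 0), c(0, -1))
  cp <- conductivity_params()
  for (k in 1:10) {
    F <- random_F(2, 0.1)
    S <- matrix(rnorm(4), 2, 2); Pi <- (S + t(S)) / 2
    v <- stats::runif(1, 0, 1.5)
    D <- conductivity_tensor(v, F, Pi, fr, cp)
    Finv <- solve(F); J <- det(F)
    Dref <- (cp$D0i + cp$D1i * v) * J * (Finv %*% t(Finv)) +
      cp$D0i / 2 * J * outer(fr$f0, fr$f0) +
      cp$D2i * J * Finv %*% Pi %*% t(Finv)
    expect_equal(D, (Dref + t(Dref)) / 2, tolerance = 1e-12)
    expect_lt(max(abs(D - t(D))), 1e-12)
  }
})

test_that("the alternative fibre-term reading divides by 2J", {
  fr <- fibre_frame(c(1, 0), c(0, -1))
  cp <- conductivity_params(fibre_over_J = TRUE)
  F <- diag(c(1.2, 1 / 1.2))
  D <- conductivity_tensor(0, F, matrix(0, 2, 2), fr, cp)
  Finv <- solve(F)
  Dref <- cp$D0i * (Finv %*% t(Finv)) + cp$D0i / 2 * outer(fr$f0, fr$f0)
  expect_equal(D, (Dref + t(Dref)) / 2, tolerance = 1e-12)
})

test_that("smallest eigenvalue grows with v when D1 > 0", {
  fr <- fibre_frame(c(0, 1), c(-1, 0))
  cp <- conductivity_params()
  lmins <- sapply(seq(0, 1.5, by = 0.25), function(v)
    ellipticity_check(conductivity_tensor(v, diag(2), matrix(0, 2, 2),
                                          fr, cp))$lambda_min)
  expect_true(all(diff(lmins) > 0))
})

test_that("ellipticity diagnostic flags indefinite tensors", {
  ok <- ellipticity_check(diag(c(2, 1)))
  expect_equal(ok$lambda_min, 1)
  expect_true(ok$is_elliptic)
  bad <- ellipticity_check(diag(c(1, -0.1)))
  expect_false(bad$is_elliptic)
  expect_error(ellipticity_check(matrix(c(1, 2, 0, 1), 2, 2)))
})
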