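test_that("resting state carries no current and holds the fast gates", {
  cur <- ionic_currents(0, c(1, 1, 0))
  expect_identical(cur$Jfi, 0)
  expect_identical(cur$Jso, 0)
  expect_identical(cur$Jsi, 0)
  expect_identical(cur$g, 0)
  rhs <- gating_rhs(0, c(1, 1, 0))
  expect_identical(rhs[1, 1], 0)     # r1 at its sub-threshold steady state
  expect_identical(rhs[1, 2], 0)     # r2 likewise
  expect_gt(rhs[1, 3], 0)            # r3 relaxes toward its tanh target
  expect_lt(rhs[1, 3], 0.01)
})

test_that("fast-inward current is gated strictly below threshold", {
  p <- ionic_params_epi()
  for (v in c(-0.1, 0, 0.1, 0.29, p$th1)) {
    cur <- ionic_currents(v, c(0.8, 0.9, 0.1))
    expect_identical(cur$Jfi, 0)
  }
  expect_lt(ionic_currents(0.35, c(0.8, 0.9, 0.1))$Jfi, 0)
})

test_that("currents and gating match an independent scalar transcription", {
  set.seed(11)
  for (k in 1:30) {
    v <- stats::runif(1, -0.1, 1.6)
    r <- stats::runif(3)
    cur <- ionic_currents(v, r)
    ora <- oracle_currents(v, r[1], r[2], r[3])
    expect_equal(cur$Jfi, ora$Jfi, tolerance = 1e-12)
    expect_equal(cur$Jso, ora$Jso, tolerance = 1e-12)
    expect_equal(cur$Jsi, ora$Jsi, tolerance = 1e-12)
    expect_equal(cur$g, ora$g, tolerance = 1e-12)
    expect_equal(as.vector(gating_rhs(v, r)),
                 oracle_gating(v, r[1], r[2], r[3]), tolerance = 1e-12)
  }
})

test_that("doubling all time constants halves the gating rates", {
  p <- ionic_params_epi()
  p2 <- ionic_params_epi(tau1m1 = 2 * p$tau1m1, tau1m2 = 2 * p$tau1m2,
                         tau1p = 2 * p$tau1p, tau2m1 = 2 * p$tau2m1,
                         tau2m2 = 2 * p$tau2m2, tau2p = 2 * p$tau2p,
                         tau31 = 2 * p$tau31, tau32 = 2 * p$tau32)
  v <- 0.2; r <- c(0.7, 0.8, 0.1)
  expect_equal(gating_rhs(v, r, p2), gating_rhs(v, r, p) / 2,
               tolerance = 1e-12)
})

test_that("reaction step integrators agree as dt shrinks", {
  run_to <- function(method, dt, T_end = 20) {
    st <- list(v = 0.35, r = matrix(c(0.9, 0.9, 0.05), 1))
    for (i in seq_len(round(T_end / dt))) st <- step_0d(st, dt, 0, method)
    c(st$v, st$r)
  }
  e1 <- max(abs(run_to("explicit-euler", 0.1) - run_to("rush-larsen", 0.1)))
  e2 <- max(abs(run_to("explicit-euler", 0.01) -
                run_to("rush-larsen", 0.01)))
  expect_lt(e2, e1)         # schemes converge to each other
  expect_lt(e2, 0.15 * e1)  # at least first-order consistency
})

test_that("gates stay in [0,1] under Rush-Larsen through a paced beat", {
  pr <- stimulus_protocol(stimulus(0, 3, 3))
  out <- run_0d(protocol = pr, T_end = 500, dt = 0.05)
  tr <- out$trace
  expect_true(all(tr$r1 >= -1e-12 & tr$r1 <= 1 + 1e-12))
  expect_true(all(tr$r2 >= -1e-12 & tr$r2 <= 1 + 1e-12))
  expect_true(all(tr$r3 >= -1e-12 & tr$r3 <= 1 + 1e-12))
})

test_that("a 3 ms amplitude-3 stimulus elicits a bounded action potential", {
  pr <- stimulus_protocol(stimulus(0, 3, 3))
  out <- run_0d(protocol = pr, T_end = 600, dt = 0.02)
  p <- ionic_params_epi()
  expect_gt(out$features$peak, p$th1)           # upstroke elicited
  expect_lt(out$features$peak, p$vv + 3)        # bounded by drive
  # epicardial action potential duration at 90% repolarisation
  expect_gt(out$features$apd, 200)
  expect_lt(out$features$apd, 350)
})

test_that("without stimulus the trace never leaves quiescence in v", {
  pr <- stimulus_protocol(stimulus(1e6, 1, 0))  # inert far-future stimulus
  out <- run_0d(protocol = pr, T_end = 50, dt = 0.1)
  expect_true(all(abs(out$trace$v) < 1e-12))
  expect_true(all(abs(out$trace$r1 - 1) < 1e-12))
  expect_true(all(abs(out$trace$r2 - 1) < 1e-12))
})

test_that("non-finite state and invalid dt are rejected", {
  expect_error(ionic_currents(NaN, c(1, 1, 0)), "non-finite")
  expect_error(step_0d(list(v = 0, r = c(1, 1, 0)), dt = 0), "dt")
})
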