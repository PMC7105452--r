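# independent transcription of the minimal-model currents, written directly
# from the published formulas (scalar, branch-by-branch); used as the oracle
# against the package's vectorised implementation
oracle_currents <- function(v, r1, r2, r3, p = ionic_params_epi()) {
  Hs <- function(x) if (x > 0) 1 else 0
  tau_o <- if (Hs(v - p$tho) > 0) p$tauo2 else p$tauo1
  tau_so <- p$tauso1 + (p$tauso2 - p$tauso1) *
    (1 + tanh(p$kso * (v - p$vso))) / 2
  Jfi <- if (v > p$th1) -r1 * (v - p$th1) * (p$vv - v) / p$taufi else 0
  Jso <- if (v > p$th2) 1 / tau_so else (v - p$v0) / tau_o
  Jsi <- if (v > p$th2) -r2 * r3 / p$tausi else 0
  list(Jfi = Jfi, Jso = Jso, Jsi = Jsi, g = -(Jfi + Jso + Jsi))
}

oracle_gating <- function(v, r1, r2, r3, p = ionic_params_epi()) {
  Hs <- function(x) if (x > 0) 1 else 0
  tau1m <- if (v > p$th1m) p$tau1m2 else p$tau1m1
  tau2m <- p$tau2m1 + (p$tau2m2 - p$tau2m1) *
    (1 + tanh(p$k2m * (v - p$v2m))) / 2
  r1inf <- if (v < p$th1m) 1 else 0
  r2inf <- if (v > p$tho) p$r2inf else 1 - v / p$tau2inf
  d1 <- if (v > p$th1) -r1 / p$tau1p else (r1inf - r1) / tau1m
  d2 <- if (v > p$th2) -r2 / p$tau2p else (r2inf - r2) / tau2m
  tau3 <- if (v > p$th2) p$tau32 else p$tau31
  d3 <- ((1 + tanh(p$k3 * (v - p$v3))) / 2 - r3) / tau3
  c(d1, d2, d3)
}

# random deformation gradient with positive determinant, moderate strain
random_F <- function(d, scale = 0.15) {
  repeat {
    F <- diag(d) + matrix(stats::rnorm(d * d, sd = scale), d, d)
    if (det(F) > 0.2) return(F)
  }
}

frame2d <- function() fibre_frame(c(1, 0), c(0, 1))
frame3d <- function() fibre_frame(c(1, 0, 0), c(0, 1, 0))

# central finite difference of a scalar energy w.r.t. F
fd_dpsi <- function(psi, F, h = 1e-7) {
  d <- nrow(F)
  P <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + h
    Fm <- F; Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (psi(Fp) - psi(Fm)) / (2 * h)
  }
  P
}

random_rotation <- function(d) {
  qr_ <- qr(matrix(stats::rnorm(d * d), d, d))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
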