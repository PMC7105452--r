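#' Fibre-sheet-normal frame
#'
#' Local orthonormal microstructure directions. In 3D the normal direction
#' n0 = f0 x s0 is computed; in 2D the frame is (f0, s0).
#'
#' @param f0,s0 unit vectors (length 2 or 3)
#' @export
fibre_frame <- function(f0, s0) {
  f0 <- as.numeric(f0); s0 <- as.numeric(s0)
  stopifnot(length(f0) == length(s0), length(f0) %in% 2:3)
  if (abs(sqrt(sum(f0^2)) - 1) > 1e-10 || abs(sqrt(sum(s0^2)) - 1) > 1e-10)
    stop("frame vectors must be unit length")
  if (abs(sum(f0 * s0)) > 1e-10) stop("frame vectors must be orthogonal")
  fr <- list(f0 = f0, s0 = s0, d = length(f0))
  if (fr$d == 3) fr$n0 <- pracma_cross(f0, s0)
  class(fr) <- "fibre_frame"
  fr
}

#' Pointwise kinematics
#'
#' Deformation measures at a material point: J, Cauchy-Green tensors, the
#' isotropic invariant I1, the direction pseudo-invariants I4f, I4s, I4n,
#' I8fs and the fibre-frame stretches.
#'
#' @param F deformation gradient (d x d, det F > 0)
#' @param frame a [fibre_frame()]
#' @export
compute_kinematics <- function(F, frame) {
  .cpp_kinematics(F, frame)
}

#' Passive Holzapfel-Ogden first Piola-Kirchhoff stress
#'
#' P = dPsi/dF - p J F^-t with the orthotropic exponential energy; the
#' anisotropic fibre/sheet terms are gated by (I4 - 1)_+ so compressed-fibre
#' configurations contribute no anisotropic stress.
#'
#' @inheritParams compute_kinematics
#' @param p hydrostatic pressure (kPa)
#' @param params [ho_params()]
#' @export
passive_pk1_ho <- function(F, p, params = ho_params(), frame) {
  .cpp_pk1_ho(F, p, frame, unclass(params))
}

#' @rdname passive_pk1_ho
#' @export
psi_ho <- function(F, params = ho_params(), frame) {
  .cpp_psi_ho(F, frame, unclass(params))
}

#' Active stress (orthotropic active Cauchy/first Piola-Kirchhoff stress)
#'
#' sigma_act = Ta/(J lf) Ff0 (x) Ff0 + ksn Ta/(J ls ln) sym(Fs0 (x) Fn0)
#' + knn Ta/(J ln) Fn0 (x) Fn0; there is no s0 diagonal term, and in 2D only
#' the fibre term survives. P_act = J sigma_act F^-t.
#'
#' @inheritParams compute_kinematics
#' @param Ta active tension (kPa)
#' @param params [active_stress_params()]
#' @export
active_pk1_stress <- function(F, Ta, frame,
                              params = active_stress_params()) {
  .cpp_pk1_active(F, Ta, frame, params$ksn, params$knn)
}

#' @rdname active_pk1_stress
#' @export
active_cauchy_stress <- function(F, Ta, frame,
                                 params = active_stress_params()) {
  .cpp_sigma_active(F, Ta, frame, params$ksn, params$knn)
}

#' Active strain tensors
#'
#' The multiplicative activation F_A = I + gamma_f f0(x)f0 + gamma_s s0(x)s0
#' + gamma_n n0(x)n0 with gamma_f = xi, gamma_s = (1+xi)^-1 (1+K0 xi)^-1 - 1,
#' gamma_n = K0 xi, for which det F_A = 1 identically.
#'
#' @param xi microscopic cell shortening (<= 0 in contraction)
#' @param frame a [fibre_frame()]
#' @param K0 orthotropy constant
#' @export
active_strain_tensors <- function(xi, frame, K0 = 5) {
  .cpp_active_strain_tensors(xi, frame, K0)
}

#' Active strain first Piola-Kirchhoff stress
#'
#' Elastic invariants are computed from F_E = F F_A^-1 directly (the printed
#' modified-invariant formulas, derived under gamma_s = gamma_n, are kept
#' only as a cross-check since the orthotropic activation law gives
#' gamma_n = K0 xi != gamma_s in general).
#'
#' @inheritParams active_strain_tensors
#' @inheritParams passive_pk1_ho
#' @export
pk1_active_strain <- function(F, xi, p, params = ho_params(), frame,
                              K0 = 5) {
  .cpp_pk1_active_strain(F, xi, p, frame, unclass(params), K0)
}

#' @rdname pk1_active_strain
#' @export
psi_active_strain <- function(F, xi, params = ho_params(), frame, K0 = 5) {
  .cpp_psi_active_strain(F, xi, frame, unclass(params), K0)
}

#' Kelvin-Voigt viscous Cauchy stress
#'
#' sigma_visc = delta exp(beta tr(Bdot)) Bdot, with Bdot either supplied or
#' built from a material velocity gradient via Bdot = L B + B L^t.
#'
#' @param B left Cauchy-Green tensor (only used when `gradw` is supplied)
#' @param Bdot rate of B (d x d symmetric), or NULL
#' @param gradw spatial velocity gradient used to build Bdot when Bdot is
#'   NULL
#' @param params [visco_params()]
#' @export
viscous_cauchy <- function(B, Bdot = NULL, gradw = NULL,
                           params = visco_params()) {
  if (is.null(Bdot)) {
    if (is.null(gradw)) stop("supply Bdot or gradw")
    Bdot <- gradw %*% B + B %*% t(gradw)
  }
  if (max(abs(Bdot - t(Bdot))) > 1e-8 * max(1, max(abs(Bdot))))
    stop("Bdot must be symmetric")
  .cpp_sigma_viscous(Bdot, params$delta, params$beta)
}

#' Guccione transversally isotropic stress
#'
#' Psi = a/2 (e^Q - 1) with Q quadratic in the fibre-frame components of the
#' Green-Lagrange strain; P = dPsi/dF - p J F^-t.
#'
#' @inheritParams passive_pk1_ho
#' @param params [guccione_params()]
#' @export
guccione_pk1 <- function(F, p, params = guccione_params(), frame) {
  .cpp_pk1_guccione(F, p, frame, unclass(params))
}

#' @rdname guccione_pk1
#' @export
psi_guccione <- function(F, params = guccione_params(), frame) {
  .cpp_psi_guccione(F, frame, unclass(params))
}

#' Kirchhoff stress assembly
#'
#' The pressure-free Kirchhoff contribution G (passive + viscous + active
#' stress term in active-stress mode; active-strain passive + viscous in
#' active-strain mode) and Pi = G - p J I.
#'
#' @param mode "active-stress" or "active-strain"
#' @param F deformation gradient
#' @param p pressure (kPa)
#' @param Ta active tension (kPa; active-stress mode only)
#' @param xi shortening (active-strain mode only)
#' @param Bdot rate of the left Cauchy-Green tensor (NULL = static)
#' @param params [ho_params()]; @param active [active_stress_params()]
#' @param visco [visco_params()] or NULL for the inviscid law
#' @param frame a [fibre_frame()]; @param K0 active strain constant
#' @return list with `G` and `Pi`
#' @export
kirchhoff_stress <- function(mode = c("active-stress", "active-strain"), F,
                             p, Ta = NULL, xi = NULL, Bdot = NULL,
                             params = ho_params(),
                             active = active_stress_params(),
                             visco = NULL, frame, K0 = 5) {
  mode <- match.arg(mode)
  if (mode == "active-stress") {
    if (!is.null(xi)) stop("active-stress mode takes Ta, not xi")
    act <- if (is.null(Ta)) 0 else Ta
  } else {
    if (!is.null(Ta)) stop("active-strain mode takes xi, not Ta")
    act <- if (is.null(xi)) 0 else xi
  }
  d <- nrow(F)
  if (is.null(Bdot)) Bdot <- matrix(0, d, d)
  delta <- if (is.null(visco)) 0 else visco$delta
  beta <- if (is.null(visco)) 1 else visco$beta
  .cpp_kirchhoff(as.integer(mode == "active-strain"), F, p, act, Bdot,
                 frame, unclass(params), active$ksn, active$knn, K0,
                 delta, beta)
}
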