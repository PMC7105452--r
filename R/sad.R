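#' Stress-assisted, deformation-dependent conductivity tensor
#'
#' D(v, F, Pi) = (D0 + D1 v) J C^-1 + (D0/2) J f0 (x) f0
#' + D2 J F^-1 Pi F^-t, combining porous-media self-diffusion (D1), the
#' geometric feedback of the Piola transform, a transversely isotropic fibre
#' term and stress-assisted diffusion (D2). Returned in internal mm^2/ms
#' units; `Pi` is expected in internal kPa and is rescaled by the
#' parameters' `stress_unit`.
#'
#' @param v transmembrane potential (dimensionless)
#' @param F deformation gradient (det F > 0)
#' @param Pi Kirchhoff stress (symmetric, kPa)
#' @param frame a [fibre_frame()]
#' @param params [conductivity_params()]
#' @export
conductivity_tensor <- function(v, F, Pi, frame,
                                params = conductivity_params()) {
  if (max(abs(Pi - t(Pi))) > 1e-8 * max(1, max(abs(Pi))))
    stop("Pi must be symmetric")
  .cpp_conductivity(v, F, Pi, frame, params$D0i, params$D1i, params$D2i,
                    params$fibre_over_J)
}

#' Ellipticity diagnostic
#'
#' Smallest eigenvalue of a symmetric conductivity tensor and a flag that is
#' FALSE when it does not exceed the configured floor.
#'
#' @param D symmetric tensor
#' @param eps_ell ellipticity floor (same units as D)
#' @return list with `lambda_min` and `is_elliptic`
#' @export
ellipticity_check <- function(D, eps_ell = 0) {
  stopifnot(max(abs(D - t(D))) <= 1e-8 * max(1, max(abs(D))))
  lmin <- min(eigen(D, symmetric = TRUE, only.values = TRUE)$values)
  list(lambda_min = lmin, is_elliptic = lmin > eps_ell)
}
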