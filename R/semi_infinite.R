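# Closed-form extrapolated-boundary solutions for a homogeneous
# semi-infinite medium: the dipole (source + image) construction used as the
# validation oracle for the layered solver.

#' Semi-infinite homogeneous medium model
#'
#' Precomputes the derived quantities of the classical extrapolated-boundary
#' dipole solution: `D = 1/(3 mu_sp)`, source depth `z0 = 1/mu_sp`,
#' extrapolation length `z_b = 2 A D` (with `A` from [a_coefficient()], so
#' the layered and homogeneous solutions share identical boundary
#' parameters), and `mu_eff = sqrt(mu_a / D)`.
#'
#' @param mu_a Absorption coefficient, 1/cm.
#' @param mu_sp Reduced scattering coefficient, 1/cm.
#' @param n_rel Ratio of internal to external refractive index. Default 1.4.
#' @param A Optional override for the internal-reflection coefficient.
#' @return A list of class `semiinf_medium`.
#' @export
#' @examples
#' si <- semiinf_medium(0.1, 10)
#' si$mu_eff  # sqrt(3 * 0.1 * 10)
semiinf_medium <- function(mu_a, mu_sp, n_rel = 1.4, A = NULL) {
  stopifnot(mu_a >= 0, mu_sp > 0, n_rel > 0)
  D <- 1 / (3 * mu_sp)
  A_val <- a_coefficient(n_rel, override = A)
  structure(list(
    mu_a = mu_a, mu_sp = mu_sp, n_rel = n_rel,
    D = D, z0 = 1 / mu_sp, zb = 2 * A_val * D, A = A_val,
    mu_eff = sqrt(mu_a / D), c_medium = C0_CM_NS / n_rel
  ), class = "semiinf_medium")
}

#' Steady-state semi-infinite surface fluence (closed form)
#'
#' `Phi(rho) = [exp(-mu_eff r1)/r1 - exp(-mu_eff r2)/r2] / (4 pi D)` at
#' `z = 0`, with `r1 = sqrt(rho^2 + z0^2)` and
#' `r2 = sqrt(rho^2 + (z0 + 2 zb)^2)`.
#'
#' @param model A [semiinf_medium()].
#' @param rho Radial distances in cm (>= 0).
#' @return Numeric vector of fluence values, 1/cm^2.
#' @export
fluence_ss_semiinf <- function(model, rho) {
  stopifnot(inherits(model, "semiinf_medium"))
  if (any(!is.finite(rho)) || any(rho < 0))
    abort("`rho` must be finite and >= 0.", class = "layerfluence_domain_error")
  r1 <- sqrt(rho^2 + model$z0^2)
  r2 <- sqrt(rho^2 + (model$z0 + 2 * model$zb)^2)
  if (any(r1 == 0))
    abort("Singular query: rho = 0 with z0 = 0.", class = "layerfluence_domain_error")
  (exp(-model$mu_eff * r1) / r1 - exp(-model$mu_eff * r2) / r2) / (4 * pi * model$D)
}

#' Time-resolved semi-infinite surface fluence (closed form)
#'
#' `Phi(rho, t) = c (4 pi D c t)^(-3/2) exp(-mu_a c t)
#'   [exp(-r1^2/(4 D c t)) - exp(-r2^2/(4 D c t))]` at `z = 0`, with
#' `c = c0 / n_rel` the speed of light in the medium.
#'
#' @inheritParams fluence_ss_semiinf
#' @param t Times in ns (> 0).
#' @return Numeric vector (or matrix over `rho` x `t` if both are vectors of
#'   length > 1) of fluence rates, 1/cm^2/ns.
#' @export
fluence_td_semiinf <- function(model, rho, t) {
  stopifnot(inherits(model, "semiinf_medium"))
  if (any(!is.finite(t)) || any(t <= 0))
    abort("`t` must be finite and > 0 ns.", class = "layerfluence_domain_error")
  cn <- model$c_medium
  r1s <- rho^2 + model$z0^2
  r2s <- rho^2 + (model$z0 + 2 * model$zb)^2
  f1 <- function(tt) {
    cn * (4 * pi * model$D * cn * tt)^(-1.5) * exp(-model$mu_a * cn * tt) *
      (exp(-r1s / (4 * model$D * cn * tt)) - exp(-r2s / (4 * model$D * cn * tt)))
  }
  if (length(rho) > 1 && length(t) > 1) {
    vapply(t, f1, numeric(length(rho)))
  } else {
    if (length(t) == 1) f1(t) else vapply(t, f1, numeric(1))
  }
}
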