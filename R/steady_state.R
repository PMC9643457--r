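# Steady-state fluence via the inverse finite Hankel transform
#   Phi_k(rho) = 1/(pi a'^2) sum_n G_k(s_n, z) J0(s_n rho) / J1(a' s_n)^2,
# with s_n = (n-th zero of J0) / a'.

#' Convergence control for the Hankel sum
#'
#' Either a fixed number of terms (`n_terms`) or dynamic termination:
#' the sum stops once the magnitudes of the last 10 consecutive terms are
#' each below `rel_tol` times the magnitude of the accumulated sum
#' (a run-length rule; single-term tests are unsafe because the `J0` factor
#' oscillates through zero).
#'
#' @param n_terms Fixed term count, or `NULL` (default) for dynamic stopping.
#' @param rel_tol Relative stopping tolerance. Default `1e-12`.
#' @param n_min,n_max Bounds on the dynamically chosen term count.
#' @return A list of class `hankel_control`.
#' @export
hankel_control <- function(n_terms = NULL, rel_tol = 1e-12,
                           n_min = 50, n_max = 50000) {
  if (!is.null(n_terms)) {
    stopifnot(length(n_terms) == 1, n_terms >= 1)
    n_terms <- as.integer(n_terms)
  }
  stopifnot(rel_tol > 0, n_min >= 10, n_max >= n_min)
  structure(list(n_terms = n_terms, rel_tol = rel_tol,
                 n_min = as.integer(n_min), n_max = as.integer(n_max)),
            class = "hankel_control")
}

RUN_LENGTH <- 10L

# Core Hankel summation, shared by the steady-state and per-contour-node
# paths. Evaluates, for each rho, sum_n G(s_n) J0(s_n rho) w_n / (pi a'^2)
# where G comes from `gfun(s)` (vectorised over s). Dynamic stopping is
# applied per query; G is evaluated in chunks shared across queries.
# `ref_offset` is added to |sum| in the stopping test: when the sum is a
# residual on top of an exactly summed closed-form part, convergence is
# judged relative to the full physical quantity.
hankel_sum <- function(medium, rho, gfun, control, ref_offset = NULL) {
  ap <- medium$a_prime
  n_q <- length(rho)
  fixed <- !is.null(control$n_terms)
  n_cap <- if (fixed) control$n_terms else control$n_max
  if (is.null(ref_offset)) ref_offset <- numeric(n_q)

  sums <- rep(0 + 0i, n_q)
  terms_used <- integer(n_q)
  converged <- logical(n_q)
  run <- integer(n_q)       # trailing count of consecutive small terms
  active <- rep(TRUE, n_q)
  norm <- pi * ap^2

  chunk_lo <- 1L
  chunk_size <- max(control$n_min, 128L)
  while (chunk_lo <= n_cap && any(active)) {
    chunk_hi <- min(n_cap, chunk_lo + chunk_size - 1L)
    rt <- j0_zeros(chunk_hi)
    idx <- chunk_lo:chunk_hi
    s <- rt$root[idx] / ap
    w <- rt$weight[idx]
    gw <- gfun(s) * w
    for (qi in which(active)) {
      tv <- gw * bessel_j0(s * rho[[qi]])
      if (fixed) {
        sums[[qi]] <- sums[[qi]] + sum(tv)
        terms_used[[qi]] <- chunk_hi
        next
      }
      ref <- Mod(sums[[qi]] + sum(tv)) + ref_offset[[qi]] * norm
      if (ref > 0 && chunk_hi >= control$n_min) {
        small <- Mod(tv) < control$rel_tol * ref
        # position of the last 'large' term; run length at each position
        lf <- cummax(ifelse(small, 0L, seq_along(small)))
        r_vec <- ifelse(lf == 0L, run[[qi]] + seq_along(small),
                        seq_along(small) - lf)
        stop_at <- which(r_vec >= RUN_LENGTH)
        if (length(stop_at) > 0) {
          ti <- stop_at[[1]]
          sums[[qi]] <- sums[[qi]] + sum(tv[seq_len(ti)])
          terms_used[[qi]] <- chunk_lo - 1L + ti
          active[[qi]] <- FALSE
          converged[[qi]] <- TRUE
          next
        }
        run[[qi]] <- r_vec[[length(r_vec)]]
      }
      sums[[qi]] <- sums[[qi]] + sum(tv)
      terms_used[[qi]] <- chunk_hi
    }
    if (fixed && chunk_hi == n_cap) {
      active[] <- FALSE
      converged[] <- TRUE
    }
    chunk_lo <- chunk_hi + 1L
    chunk_size <- min(chunk_size * 2L, 4096L)
  }
  list(values = sums / norm, terms_used = terms_used, converged = converged)
}

finish_curve <- function(rho, z, values, terms_used, converged, medium, mode, control) {
  v <- Re(values)
  clamped <- v < 0
  v[clamped] <- 0
  out <- tibble(
    rho = rho, z = z, fluence = v,
    terms_used = terms_used, converged = converged, clamped = clamped,
    at_lateral_boundary = rho == medium$radius
  )
  class(out) <- c("fluence_curve", class(out))
  attr(out, "mode") <- mode
  attr(out, "medium") <- medium
  attr(out, "control") <- control
  out
}

check_rho <- function(rho, medium) {
  if (any(!is.finite(rho)) || any(rho < 0))
    abort("`rho` must be finite and >= 0.", class = "layerfluence_domain_error")
  if (any(rho > medium$radius))
    abort("`rho` must not exceed the cylinder radius.",
          class = "layerfluence_domain_error")
  if (any(rho == medium$radius))
    warn("Some `rho` equal the cylinder radius; lateral-boundary effects dominate there.")
  invisible(rho)
}

#' Steady-state fluence on the surface of a layered cylinder
#'
#' Evaluates the inverse finite Hankel transform for surface queries:
#' `z = 0` (top of layer 1, the reflectance side) or `z = L` (bottom of
#' layer N, the transmittance side). Interior depths are not part of the
#' public surface; use [reflectance_ss()] / [transmittance_ss()] for the
#' usual measurement geometries.
#'
#' @param medium A [layered_medium()].
#' @param rho Radial distances in cm (`0 <= rho <= radius`).
#' @param z Either `0` or the total thickness `L`.
#' @param control A [hankel_control()].
#' @return A tibble of class `fluence_curve` with columns `rho`, `z`,
#'   `fluence` (1/cm^2), `terms_used`, `converged`, `clamped`,
#'   `at_lateral_boundary`.
#' @export
#' @examples
#' m <- layered_medium(mu_a = c(0.1, 0.1), mu_sp = c(10, 10),
#'                     thickness = c(5, 5), radius = 20)
#' fluence_ss(m, rho = c(1, 2), control = hankel_control(n_terms = 1000))
fluence_ss <- function(medium, rho, z = 0, control = hankel_control()) {
  assert_medium(medium)
  check_rho(rho, medium)
  if (length(z) != 1 || !(z == 0 || z == medium$L))
    abort("`z` must be 0 (reflectance) or L (transmittance); interior depths are unsupported.",
          class = "layerfluence_domain_error")
  gfun <- function(s) greens_sfd(medium, s, z, 0)
  hs <- hankel_sum(medium, rho, gfun, control)
  finish_curve(rho, z, hs$values, hs$terms_used, hs$converged, medium,
               "steady_state", control)
}

#' @rdname fluence_ss
#' @export
reflectance_ss <- function(medium, rho, control = hankel_control()) {
  fluence_ss(medium, rho, z = 0, control = control)
}

#' @rdname fluence_ss
#' @export
transmittance_ss <- function(medium, rho, control = hankel_control()) {
  assert_medium(medium)
  fluence_ss(medium, rho, z = medium$L, control = control)
}

# Internal: steady-state fluence at an arbitrary depth inside layer 1 or
# layer N. Used for bin-centre registration against Monte Carlo histograms;
# deliberately not exported as part of the public query surface.
fluence_ss_depth <- function(medium, rho, z, control = hankel_control()) {
  assert_medium(medium)
  check_rho(rho, medium)
  gfun <- function(s) greens_sfd(medium, s, z, 0)
  hs <- hankel_sum(medium, rho, gfun, control)
  finish_curve(rho, z, hs$values, hs$terms_used, hs$converged, medium,
               "steady_state", control)
}

#' Fast approximate steady-state reflectance (source term resummed)
#'
#' The slowly converging part of the surface Hankel sum is the particular
#' (source) solution of the layer-1 Green's function: at `z = 0` its terms
#' decay only like `exp(-s z0)` with `z0 = 1/mu_sp[1]` small. Together with
#' its extrapolated-boundary image it can be summed exactly in real space as
#' the semi-infinite dipole
#' `[exp(-mu_eff r1)/r1 - exp(-mu_eff r2)/r2] / (4 pi D1)`,
#' `r1 = sqrt(rho^2 + z0^2)`, `r2 = sqrt(rho^2 + (z0 + 2 zb)^2)`.
#' What remains in the Hankel sum is the deeper-layer/boundary residual,
#' whose terms decay like `exp(-s (2 l1 - z0))` - vastly faster whenever the
#' top layer is thicker than the transport mean free path. The approximation
#' is valid for `mu_sp[1] > 2` 1/cm at `z = 0`; outside that domain a
#' warning is issued and the exact sum is returned instead.
#'
#' @inheritParams fluence_ss
#' @return A `fluence_curve` tibble (as [fluence_ss()]); `terms_used` counts
#'   residual terms only.
#' @export
approx_reflectance_ss <- function(medium, rho, control = hankel_control()) {
  assert_medium(medium)
  check_rho(rho, medium)
  lay <- medium$layers
  if (lay$mu_sp[[1]] <= 2) {
    warn("approx_reflectance_ss() is valid for mu_sp[1] > 2 /cm; falling back to the exact sum.")
    return(reflectance_ss(medium, rho, control))
  }
  D1 <- lay$D[[1]]
  z0 <- medium$z0
  zb <- medium$zb_top
  mu_eff <- sqrt(lay$mu_a[[1]] / D1)
  r1 <- sqrt(rho^2 + z0^2)
  r2 <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  closed <- (exp(-mu_eff * r1) / r1 - exp(-mu_eff * r2) / r2) / (4 * pi * D1)

  gfun <- function(s) {
    a1 <- sqrt((lay$mu_a[[1]]) / D1 + s^2)
    particular <- (exp_decay(-a1 * z0) - exp_decay(-a1 * (z0 + 2 * zb))) / (2 * D1 * a1)
    greens_sfd(medium, s, 0, 0) - particular
  }
  hs <- hankel_sum(medium, rho, gfun, control, ref_offset = abs(closed))
  vals <- Re(hs$values) + closed
  finish_curve(rho, 0, vals, hs$terms_used, hs$converged, medium,
               "steady_state_approx", control)
}
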