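# Spatial-frequency-domain Green's functions for the layered cylinder.
#
# In the transform domain the fluence in each layer solves
#   G'' - alpha_k^2 G = -delta(z - z0) / D_1,
# with alpha_k^2 = (mu_a_k + s_bar / c) / D_k + s^2, extrapolated-boundary
# conditions G = 0 at z = -zb_top and z = L + zb_bottom, and continuity of G
# and D_k dG/dz at interfaces. The solution is assembled from a
# reflection-coefficient sweep that starts at the bottom boundary and moves
# up: in layer k the bottom-satisfying solution is
#   w_k(zeta) = A_k [ exp(-alpha_k zeta) - R_k exp(-alpha_k (2 l_k - zeta)) ],
# where every stored exponential has non-positive real exponent, so nothing
# overflows no matter how large alpha_k l_k gets, and R_k follows a bounded
# Moebius recursion in beta_k = D_k alpha_k. This is algebraically identical
# to the explicit hyperbolic-function expressions for the top and bottom
# layers, but evaluates stably for arbitrarily thick, highly scattering
# layers and for complex absorption shifts on the Laplace contour.

#' Per-layer axial wavenumbers
#'
#' `alpha_k = sqrt((mu_a_k + s_bar / c) / D_k + s^2)` with the principal
#' square root, sign-flipped if needed so that `Re(alpha_k) > 0` (decaying
#' solutions away from the source).
#'
#' @param medium A [layered_medium()].
#' @param s Transverse spatial frequency (1/cm), vectorised.
#' @param s_bar Complex Laplace variable (1/ns); `0` for steady state.
#' @return A matrix (layers x length(s)); numeric when `s_bar = 0`,
#'   complex otherwise.
#' @export
layer_wavenumbers <- function(medium, s, s_bar = 0) {
  assert_medium(medium)
  lay <- medium$layers
  q <- (lay$mu_a + s_bar / medium$c_medium) / lay$D  # per-layer, scalar s_bar
  s2 <- s * s
  cplx <- is.complex(q) || is.complex(s)
  alpha <- matrix(if (cplx) complex(1) else numeric(1), nrow = length(q), ncol = length(s))
  for (k in seq_along(q)) {
    a <- sqrt(q[[k]] + s2)
    if (is.complex(a)) {
      flip <- Re(a) < 0
      a[flip] <- -a[flip]
    }
    alpha[k, ] <- a
  }
  alpha
}

# exp() with an explicit zero for deeply negative real exponents: exact 0
# instead of subnormal noise or NaN from -Inf.
exp_decay <- function(x) {
  rx <- Re(x)
  out <- exp(x)
  out[rx < -745] <- 0
  out
}

# Full transform-domain Green's function at depth z (scalar) for a vector of
# transverse frequencies s and one (possibly complex) Laplace variable s_bar.
greens_sfd <- function(medium, s, z, s_bar = 0) {
  lay <- medium$layers
  nl <- nrow(lay)
  z0 <- medium$z0
  zb_t <- medium$zb_top
  zb_b <- medium$zb_bottom
  l <- lay$thickness
  D <- lay$D

  alpha <- layer_wavenumbers(medium, s, s_bar)
  a1 <- alpha[1, ]

  # Upward reflection-coefficient sweep; R_list[[k]] is R_k.
  R_list <- vector("list", nl)
  E_list <- lapply(seq_len(nl), function(k) exp_decay(-2 * alpha[k, ] * l[[k]]))
  R_list[[nl]] <- exp_decay(-2 * alpha[nl, ] * zb_b)
  if (nl > 1) {
    for (k in (nl - 1):1) {
      x <- R_list[[k + 1]] * E_list[[k + 1]]
      bk <- D[[k]] * alpha[k, ]
      bk1 <- D[[k + 1]] * alpha[k + 1, ]
      R_list[[k]] <- ((bk1 - bk) + (bk1 + bk) * x) / ((bk1 + bk) + (bk1 - bk) * x)
    }
  }
  R1E1 <- R_list[[1]] * E_list[[1]]
  e_zb <- exp_decay(-2 * a1 * zb_t)
  S0 <- 1 - e_zb
  C0 <- 1 + e_zb
  Wv <- 1 - R1E1
  Wd <- 1 + R1E1
  inv <- 1 / (D[[1]] * a1 * (S0 * Wd + C0 * Wv))

  if (z <= z0) {
    # z between the extrapolated top boundary and the source depth.
    R1 <- R_list[[1]]
    num <- exp_decay(-a1 * (z0 - z)) -
      R1 * exp_decay(-a1 * (2 * l[[1]] - z0 - z)) -
      exp_decay(-a1 * (z0 + z + 2 * zb_t)) +
      R1 * exp_decay(-a1 * (2 * l[[1]] - z0 + z + 2 * zb_t))
    return(num * inv)
  }

  # z at or below the source: propagate the bottom-satisfying solution to the
  # layer containing z, keeping amplitudes as a bounded prefactor P times a
  # non-positive accumulated exponent X.
  k <- findInterval(z, lay$z_top)
  k <- min(max(k, 1L), nl)
  zeta <- z - lay$z_top[[k]]

  S_z0 <- 1 - exp_decay(-2 * a1 * (z0 + zb_t))
  X <- a1 * z0
  P <- 1
  if (k > 1) {
    for (j in seq_len(k - 1)) {
      X <- X - alpha[j, ] * l[[j]]
      P <- P * (1 - R_list[[j]]) / (1 - R_list[[j + 1]] * E_list[[j + 1]])
    }
  }
  ak <- alpha[k, ]
  num <- exp_decay(X - ak * zeta) - R_list[[k]] * exp_decay(X - ak * (2 * l[[k]] - zeta))
  S_z0 * P * num * inv
}

#' Green's function in the topmost layer
#'
#' Transform-domain Green's function `G_1(s, z, s_bar)` for depths inside
#' layer 1 (the reflectance side; `z = 0` for surface fluence). Depths down
#' to the extrapolated boundary `z = -zb_top` are admitted, where `G` is
#' exactly 0. The evaluation is overflow-free: every stored exponential has
#' a non-positive real exponent, and exponentials below the double-precision
#' range return exactly 0.
#'
#' @inheritParams layer_wavenumbers
#' @param z Depth in cm; must satisfy `-zb_top <= z <= thickness[1]`.
#' @return Vector of Green's-function values over `s` (numeric for
#'   `s_bar = 0`, complex otherwise).
#' @export
greens_top <- function(medium, s, z = 0, s_bar = 0) {
  assert_medium(medium)
  l1 <- medium$layers$thickness[[1]]
  if (length(z) != 1 || !is.finite(z) || z < -medium$zb_top || z > l1)
    abort(sprintf("`z` must lie in layer 1: [%.4g, %.4g] cm.", -medium$zb_top, l1),
          class = "layerfluence_domain_error")
  greens_sfd(medium, s, z, s_bar)
}

#' Green's function in the bottommost layer
#'
#' Transform-domain Green's function `G_N(s, z, s_bar)` for depths inside
#' layer N (the transmittance side; `z = L` for the exit surface).
#'
#' @inheritParams greens_top
#' @param z Depth in cm inside the bottom layer.
#' @export
greens_bottom <- function(medium, s, z = NULL, s_bar = 0) {
  assert_medium(medium)
  nl <- nrow(medium$layers)
  z <- z %||% medium$L
  z_top_N <- medium$layers$z_top[[nl]]
  if (length(z) != 1 || !is.finite(z) || z < z_top_N || z > medium$L)
    abort(sprintf("`z` must lie in layer %d: [%.4g, %.4g] cm.", nl, z_top_N, medium$L),
          class = "layerfluence_domain_error")
  greens_sfd(medium, s, z, s_bar)
}
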