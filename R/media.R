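#' Internal-reflection coefficient A for a refractive-index mismatched boundary
#'
#' Computes the coefficient `A` entering the extrapolation length
#' `z_b = 2 A D` of the extrapolated boundary condition. `A` accounts for the
#' fraction of diffuse photons internally reflected at the tissue-air
#' interface. It is obtained by numerical integration of the unpolarised
#' Fresnel reflection coefficient over the hemisphere: with
#' `R_Phi = int 2 sin(t) cos(t) R_F(t) dt` and
#' `R_j = int 3 sin(t) cos(t)^2 R_F(t) dt` (both over incidence angles
#' `t` in `[0, pi/2]`, measured inside the medium),
#' `R_eff = (R_Phi + R_j) / (2 - R_Phi + R_j)` and
#' `A = (1 + R_eff) / (1 - R_eff)`.
#'
#' Results are cached per `n_rel` within a session, so repeated calls are
#' cheap and bit-identical. Pass `override` to pin `A` to a literature value
#' instead of the integral (the rest of the package then uses that value
#' consistently).
#'
#' @param n_rel Ratio of internal to external refractive index (> 0).
#'   `n_rel = 1` gives `A = 1` (matched boundary).
#' @param override Optional fixed value returned instead of the Fresnel
#'   integral.
#' @return The dimensionless coefficient `A >= 1`.
#' @export
#' @examples
#' a_coefficient(1.0)  # matched boundary: exactly 1
#' a_coefficient(1.4)  # tissue-air: approximately 2.95
a_coefficient <- function(n_rel, override = NULL) {
  if (!is.null(override)) {
    stopifnot(is.numeric(override), length(override) == 1, override >= 1)
    return(as.numeric(override))
  }
  if (!is.numeric(n_rel) || length(n_rel) != 1 || !is.finite(n_rel) || n_rel <= 0)
    abort("`n_rel` must be a single positive number.", class = "layerfluence_invalid_medium")
  key <- format(n_rel, digits = 17)
  hit <- .lf_cache$A[[key]]
  if (!is.null(hit)) return(hit)
  val <- if (n_rel == 1) 1 else {
    rf <- fresnel_unpolarised(n_rel)
    r_phi <- integrate(function(th) 2 * sin(th) * cos(th) * rf(th),
                       0, pi / 2, rel.tol = 1e-13, abs.tol = 0)$value
    r_j <- integrate(function(th) 3 * sin(th) * cos(th)^2 * rf(th),
                     0, pi / 2, rel.tol = 1e-13, abs.tol = 0)$value
    r_eff <- (r_phi + r_j) / (2 - r_phi + r_j)
    (1 + r_eff) / (1 - r_eff)
  }
  .lf_cache$A[[key]] <- val
  val
}

# Unpolarised Fresnel reflectance for internal incidence angle th,
# medium (index n_rel) -> outside (index 1). Total internal reflection
# beyond the critical angle.
fresnel_unpolarised <- function(n_rel) {
  force(n_rel)
  function(th) {
    st <- sin(th)
    out <- rep(1, length(th))
    ok <- n_rel * st < 1
    if (any(ok)) {
      tht <- asin(n_rel * st[ok])
      ci <- cos(th[ok])
      ct <- cos(tht)
      rs <- ((n_rel * ci - ct) / (n_rel * ci + ct))^2
      rp <- ((n_rel * ct - ci) / (n_rel * ct + ci))^2
      out[ok] <- 0.5 * (rs + rp)
    }
    out
  }
}

.lf_cache <- new.env(parent = emptyenv())
.lf_cache$A <- list()
.lf_cache$roots <- list()

#' Diffusion coefficient of a layer
#'
#' `D = 1 / (3 mu_sp)` in the absorption-free convention used throughout.
#'
#' @param mu_sp Reduced scattering coefficient in 1/cm (> 0); vectorised.
#' @return Diffusion coefficient in cm.
#' @export
#' @examples
#' diffusion_coefficient(10)   # 1/30 cm
diffusion_coefficient <- function(mu_sp) {
  if (!is.numeric(mu_sp) || any(!is.finite(mu_sp)) || any(mu_sp <= 0))
    abort("`mu_sp` must be positive and finite.", class = "layerfluence_invalid_medium")
  1 / (3 * mu_sp)
}

#' Build a layered cylindrical turbid medium
#'
#' Describes a cylinder of radius `radius` made of `N` stacked layers
#' (layer 1 on top, where the source enters). Each layer has its own
#' absorption `mu_a` [1/cm], reduced scattering `mu_sp` [1/cm] and thickness
#' [cm]; all layers share one refractive index `n_r` (the Green's-function
#' continuity conditions implemented here are valid only for matched internal
#' indices, so mixed-index stacks are rejected). The collimated source is
#' modelled as an isotropic point source on the axis at depth
#' `z0 = 1 / mu_sp[1]`, which must lie strictly inside layer 1.
#'
#' Derived boundary parameters (internal-reflection coefficient `A`,
#' extrapolation lengths `z_b` at top and bottom, extrapolated radius
#' `a' = radius + z_b_top`, source depth `z0`) are computed once and stored.
#'
#' @param mu_a Absorption coefficients, one per layer, in 1/cm (>= 0).
#' @param mu_sp Reduced scattering coefficients, one per layer, in 1/cm (> 0).
#' @param thickness Layer thicknesses in cm (> 0). The bottom layer may be
#'   very thick (but finite) to emulate a semi-infinite half-space.
#' @param radius Cylinder radius `a` in cm.
#' @param n_r Refractive index shared by all layers (>= 1). Default 1.4.
#' @param n_out External refractive index. Default 1 (air).
#' @param A Optional override for the internal-reflection coefficient
#'   (see [a_coefficient()]).
#' @return An object of class `layered_medium`: a list with a `layers`
#'   tibble (`mu_a`, `mu_sp`, `n_r`, `thickness`, `D`, `z_top`, `z_bottom`)
#'   and scalars `radius`, `n_out`, `L` (total thickness), `A`, `zb_top`,
#'   `zb_bottom`, `a_prime`, `z0`, `c_medium` (speed of light in the medium,
#'   cm/ns).
#' @export
#' @examples
#' m <- layered_medium(mu_a = c(0.1, 0.1), mu_sp = c(10, 10),
#'                     thickness = c(5, 5), radius = 20)
#' m$L      # 10 cm
#' m$z0     # 0.1 cm
layered_medium <- function(mu_a, mu_sp, thickness, radius,
                           n_r = 1.4, n_out = 1.0, A = NULL) {
  n_lay <- length(mu_a)
  if (n_lay < 1)
    abort("At least one layer is required.", class = "layerfluence_invalid_medium")
  if (length(mu_sp) != n_lay || length(thickness) != n_lay)
    abort("`mu_a`, `mu_sp` and `thickness` must have one value per layer.",
          class = "layerfluence_invalid_medium")
  if (length(n_r) != 1) {
    if (length(unique(n_r)) != 1)
      abort(paste0("All internal layers must share one refractive index; ",
                   "mixed-index stacks are not supported."),
            class = "layerfluence_unsupported_medium")
    n_r <- n_r[[1]]
  }
  if (any(!is.finite(mu_a)) || any(mu_a < 0))
    abort("`mu_a` must be finite and >= 0.", class = "layerfluence_invalid_medium")
  if (any(!is.finite(mu_sp)) || any(mu_sp <= 0))
    abort("`mu_sp` must be finite and > 0.", class = "layerfluence_invalid_medium")
  if (any(!is.finite(thickness)) || any(thickness <= 0))
    abort("`thickness` must be finite and > 0.", class = "layerfluence_invalid_medium")
  if (!is.finite(radius) || radius <= 0)
    abort("`radius` must be finite and > 0.", class = "layerfluence_invalid_medium")
  if (n_r < 1)
    abort("`n_r` must be >= 1.", class = "layerfluence_invalid_medium")

  z0 <- 1 / mu_sp[[1]]
  if (z0 >= thickness[[1]])
    abort(sprintf(paste0("Source depth z0 = 1/mu_sp[1] = %.4g cm does not lie inside ",
                         "layer 1 (thickness %.4g cm)."), z0, thickness[[1]]),
          class = "layerfluence_unsupported_geometry")

  D <- diffusion_coefficient(mu_sp)
  A_val <- a_coefficient(n_r / n_out, override = A)
  zb_top <- 2 * A_val * D[[1]]
  zb_bottom <- 2 * A_val * D[[n_lay]]
  z_bottom <- cumsum(thickness)
  z_top <- c(0, z_bottom[-n_lay])

  structure(
    list(
      layers = tibble(
        mu_a = as.numeric(mu_a), mu_sp = as.numeric(mu_sp),
        n_r = n_r, thickness = as.numeric(thickness),
        D = D, z_top = z_top, z_bottom = z_bottom
      ),
      radius = as.numeric(radius),
      n_out = as.numeric(n_out),
      L = z_bottom[[n_lay]],
      A = A_val,
      zb_top = zb_top,
      zb_bottom = zb_bottom,
      a_prime = radius + zb_top,
      z0 = z0,
      c_medium = C0_CM_NS / n_r
    ),
    class = "layered_medium"
  )
}

#' @export
print.layered_medium <- function(x, ...) {
  cat(sprintf("<layered_medium: %d layer(s), radius %.4g cm, L = %.4g cm>\n",
              nrow(x$layers), x$radius, x$L))
  print(x$layers)
  cat(sprintf("n_r = %.4g (outside %.4g), A = %.6g, z0 = %.4g cm, zb = %.4g cm, a' = %.6g cm\n",
              x$layers$n_r[[1]], x$n_out, x$A, x$z0, x$zb_top, x$a_prime))
  invisible(x)
}

#' @export
format.layered_medium <- function(x, ...) {
  sprintf("layered_medium(%d layers, a = %g cm, L = %g cm)", nrow(x$layers), x$radius, x$L)
}

is_layered_medium <- function(x) inherits(x, "layered_medium")

assert_medium <- function(medium) {
  if (!is_layered_medium(medium))
    abort("`medium` must be a `layered_medium` object (see layered_medium()).",
          class = "layerfluence_invalid_medium")
  invisible(medium)
}
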