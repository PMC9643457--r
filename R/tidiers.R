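# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a layered medium into a per-layer tibble
#'
#' @param x A [layered_medium()].
#' @param ... Unused.
#' @return One row per layer with optical properties and depth extents.
#' @export
tidy.layered_medium <- function(x, ...) {
  out <- x$layers
  out$layer <- seq_len(nrow(out))
  out[, c("layer", "mu_a", "mu_sp", "n_r", "thickness", "D", "z_top", "z_bottom")]
}

#' @rdname tidy.layered_medium
#' @export
glance.layered_medium <- function(x, ...) {
  tibble(n_layers = nrow(x$layers), radius = x$radius, L = x$L,
         n_r = x$layers$n_r[[1]], n_out = x$n_out, A = x$A,
         z0 = x$z0, zb_top = x$zb_top, zb_bottom = x$zb_bottom,
         a_prime = x$a_prime, c_medium = x$c_medium)
}

#' @export
tidy.fluence_curve <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.fluence_curve <- function(x, ...) {
  tibble(mode = attr(x, "mode"), n_queries = nrow(x),
         max_terms = max(x$terms_used), all_converged = all(x$converged),
         any_clamped = any(x$clamped))
}

#' @export
tidy.td_fluence_curve <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.td_fluence_curve <- function(x, ...) {
  ct <- attr(x, "contour")
  tibble(mode = "time_domain", n_queries = nrow(x),
         n_laplace = attr(ct, "n_evals"), t1 = attr(ct, "t1"),
         t2 = attr(ct, "t2"), Lambda = attr(ct, "Lambda"),
         max_terms = max(attr(x, "terms_used")), any_clamped = any(x$clamped))
}

#' @export
tidy.mc_result <- function(x, ...) x$steady

#' @export
glance.mc_result <- function(x, ...) {
  tt <- x$totals
  tibble(n_photons = tt$launched, g = x$config$g,
         deposited = tt$deposited / tt$launched,
         escaped_top = tt$escaped_top / tt$launched,
         escaped_bottom = tt$escaped_bottom / tt$launched,
         balance_defect = abs(tt$launched + tt$gained -
           (tt$deposited + tt$escaped_top + tt$escaped_bottom + tt$killed)) /
           tt$launched)
}

#' Plot a steady-state fluence curve
#'
#' @param object A `fluence_curve` from [fluence_ss()] and friends.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fluence_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rho, y = .data$fluence)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(rho ~ "[cm]"),
                  y = expression(Phi ~ "[" * cm^-2 * "]"),
                  title = "Steady-state fluence")
}

#' Plot a time-resolved fluence curve
#'
#' @param object A `td_fluence_curve` from [fluence_td()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.td_fluence_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$fluence,
                                       colour = factor(.data$rho))) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "t [ns]", y = expression(Phi ~ "[" * cm^-2 ~ ns^-1 * "]"),
                  colour = expression(rho ~ "[cm]"),
                  title = "Time-resolved fluence")
}

#' Plot a diffusion-vs-Monte-Carlo comparison
#'
#' @param object A tibble from [mc_compare_ss()] or [mc_compare_td()].
#' @param ... Unused.
#' @return A ggplot of per-bin relative error with the MC standard-error band.
#' @export
plot_mc_comparison <- function(object, ...) {
  xvar <- if ("t" %in% names(object)) "t" else "rho"
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[xvar]], y = .data$rel_err)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = 0, ymax = .data$rel_se),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (xvar == "t") "t [ns]" else expression(rho ~ "[cm]"),
                  y = expression("|1 - " * Phi[DT] / Phi[MC] * "|"))
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
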