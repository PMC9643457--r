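# Named tissue models and validation scenarios, ready to run.

SCENARIO_NAMES <- c("semiinf_2layer", "semiinf_8layer", "fig3_baseline",
                    "fig4_contour", "fig5a_high_scatter", "fig5b_high_abs",
                    "two_layer", "skin_fat_muscle", "brain_5layer")

#' Named validation scenarios
#'
#' Ready-made media and query grids for the scenarios used throughout the
#' package's validation suite: equal-property stacks that emulate a
#' semi-infinite medium (`semiinf_2layer`, `semiinf_8layer`), the 2-layer
#' convergence baseline (`fig3_baseline`), the 4-layer contour benchmark
#' (`fig4_contour`), high-scattering and high-absorption stress cases
#' (`fig5a_high_scatter`, `fig5b_high_abs`), and three tissue models of
#' clinical interest: a generic 2-layer model (`two_layer`), a 3-layer
#' skin/fat/muscle model and a 5-layer scalp/skull/CSF/gray/white brain
#' model. All use internal refractive index 1.4 with air outside and
#' anisotropy `g = 0.8` on the Monte Carlo side.
#'
#' For `brain_5layer` the diffusion-side medium replaces the very low CSF
#' scattering (0.25 /cm) by an effective 3.5 /cm - diffusion theory breaks
#' down in a non-scattering gap, and this effective value is the standard
#' workaround; the Monte Carlo medium keeps the true value (`mc_medium`).
#'
#' @param name One of `scenario_names()`.
#' @return A list of class `lf_scenario` with elements `name`, `medium`
#'   (diffusion side), `mc_medium` (Monte Carlo side; identical except for
#'   the CSF override), `g`, `rho` (suggested radial queries, cm), `times`
#'   (suggested time queries, ns) and `notes`.
#' @export
#' @examples
#' sc <- scenario("skin_fat_muscle")
#' sc$medium$layers
scenario <- function(name) {
  if (!is.character(name) || length(name) != 1 || !(name %in% SCENARIO_NAMES))
    abort(paste0("Unknown scenario. Valid names: ",
                 paste(SCENARIO_NAMES, collapse = ", ")),
          class = "layerfluence_unknown_scenario")
  build <- function(mu_a, mu_sp, l, a) layered_medium(mu_a, mu_sp, l, radius = a)
  sc <- switch(
    name,
    semiinf_2layer = list(
      medium = build(rep(0.1, 2), rep(10, 2), rep(5, 2), 20),
      rho = seq(0.5, 8, by = 0.5), times = seq(0.05, 5, by = 0.05),
      notes = "Equal-property 2-layer stack (L = 10 cm) emulating a semi-infinite medium."
    ),
    semiinf_8layer = list(
      medium = build(rep(0.1, 8), rep(10, 8), rep(1.25, 8), 20),
      rho = seq(0.5, 8, by = 0.5), times = seq(0.05, 5, by = 0.05),
      notes = "Equal-property 8-layer stack; must agree with the 2-layer stack to roundoff."
    ),
    fig3_baseline = list(
      medium = build(c(0.1, 0.1), c(10, 10), c(1, 20), 10),
      rho = 1, times = numeric(),
      notes = "2-layer convergence baseline for term-count studies (z = 0, rho = 1 cm)."
    ),
    fig4_contour = list(
      medium = build(rep(0.1, 4), rep(10, 4), c(0.5, 1.5, 3.0, 5.0), 15),
      rho = 1, times = seq(0.03, 6, length.out = 600),
      notes = "4-layer equal-property medium for Laplace-contour accuracy studies."
    ),
    fig5a_high_scatter = list(
      medium = build(rep(0.1, 4), rep(80, 4), c(0.5, 1.5, 3.5, 30.0), 15),
      rho = c(0.2, 3.5), times = seq(0.004, 6, length.out = 300),
      notes = "High scattering (mu_sp = 80 /cm) with a 30 cm bottom layer: overflow stress case."
    ),
    fig5b_high_abs = list(
      medium = build(rep(0.6, 4), rep(10, 4), c(0.5, 1.5, 3.5, 30.0), 15),
      rho = c(3, 6), times = seq(0.1, 6, length.out = 200),
      notes = "High absorption (mu_a = 0.6 /cm): extreme dynamic range, needs octuple precision."
    ),
    two_layer = list(
      medium = build(c(0.2, 0.1), c(13, 12), c(0.6, 9.0), 20),
      rho = seq(0.5, 8, by = 0.5), times = seq(0.05, 5, by = 0.05),
      notes = "Generic 2-layer tissue model."
    ),
    skin_fat_muscle = list(
      medium = build(c(0.15, 0.02, 0.2), c(15, 12, 5), c(0.12, 0.38, 10.0), 20),
      rho = seq(0.5, 8, by = 0.5), times = seq(0.05, 5, by = 0.05),
      notes = "3-layer skin/fat/muscle model."
    ),
    brain_5layer = list(
      medium = build(c(0.18, 0.16, 0.04, 0.36, 0.14),
                     c(19, 16, 3.5, 22, 9.1),
                     c(0.5, 0.8, 0.2, 0.5, 4.0), 20),
      mc_medium = build(c(0.18, 0.16, 0.04, 0.36, 0.14),
                        c(19, 16, 0.25, 22, 9.1),
                        c(0.5, 0.8, 0.2, 0.5, 4.0), 20),
      rho = seq(0.5, 8, by = 0.5), times = seq(0.05, 5, by = 0.05),
      notes = paste0("5-layer scalp/skull/CSF/gray/white brain model; the diffusion ",
                     "side uses an effective CSF mu_sp of 3.5 /cm.")
    )
  )
  sc$name <- name
  sc$g <- 0.8
  sc$mc_medium <- sc$mc_medium %||% sc$medium
  structure(sc, class = "lf_scenario")
}

#' @rdname scenario
#' @export
scenario_names <- function() SCENARIO_NAMES

#' @export
print.lf_scenario <- function(x, ...) {
  cat(sprintf("<scenario '%s'>\n%s\n", x$name, x$notes))
  print(x$medium)
  invisible(x)
}
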