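# Bridge to the arbitrary-precision kernel (inst/python/hp_kernel.py).
#
# The double-precision path lives entirely in R; quadruple (34 significant
# digits) and octuple (71 digits) computations run in an mpmath worker that
# implements the identical Green's-function sweep, Hankel sum and Laplace
# contour. The worker is exchanged with via JSON over a pipe; results come
# back as doubles (the quantities compared all fit the double exponent
# range) plus full-precision strings where needed.

precision_dps <- function(precision) {
  if (is.numeric(precision)) return(as.integer(precision))
  switch(match.arg(precision, c("double", "quad", "oct")),
         double = 16L, quad = 34L, oct = 71L)
}

#' Is the arbitrary-precision backend available?
#'
#' Checks that a `python` interpreter with `mpmath` can be found.
#'
#' @return Logical.
#' @export
hp_available <- function() {
  if (!is.null(.lf_cache$hp_ok)) return(.lf_cache$hp_ok)
  py <- Sys.which("python")
  ok <- nzchar(py) &&
    identical(
      tryCatch(system2(py, c("-c", shQuote("import mpmath; print('ok')")),
                       stdout = TRUE, stderr = FALSE)[1],
               error = function(e) ""),
      "ok")
  .lf_cache$hp_ok <- ok
  ok
}

hp_call <- function(req) {
  if (!hp_available())
    abort("The arbitrary-precision backend needs a python interpreter with mpmath.",
          class = "layerfluence_hp_unavailable")
  script <- system.file("python", "hp_kernel.py", package = "layerfluence")
  infile <- tempfile(fileext = ".json")
  on.exit(unlink(infile), add = TRUE)
  jsonlite::write_json(req, infile, auto_unbox = TRUE, digits = NA)
  out <- system2(Sys.which("python"), shQuote(script),
                 stdout = TRUE, stderr = "", stdin = infile)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    abort(paste("hp kernel failed:", paste(out, collapse = "\n")))
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = TRUE)
}

hp_medium_spec <- function(medium) {
  lay <- medium$layers
  list(mu_a = lay$mu_a, mu_sp = lay$mu_sp, thickness = lay$thickness,
       n_r = lay$n_r[[1]], radius = medium$radius, A = medium$A)
}

# Refine J0 roots at high working precision (used by j0_zeros()).
hp_refine_roots <- function(n_max, precision_bits) {
  dps <- max(17L, as.integer(ceiling(precision_bits * 0.30103)))
  res <- hp_call(list(op = "roots", n_max = n_max, dps = dps))
  list(root = res$root, root_str = res$root_str)
}

#' Steady-state surface fluence at elevated working precision
#'
#' Same computation as [fluence_ss()] at `z = 0`, carried out end-to-end
#' (roots, Bessel evaluations, Green's functions, summation) in the
#' arbitrary-precision backend with a fixed number of terms. Used as the
#' brute-force reference when quantifying double-precision convergence.
#'
#' @inheritParams fluence_ss
#' @param n_terms Fixed number of Hankel terms.
#' @param precision `"quad"`, `"oct"`, or a number of decimal digits.
#' @return Tibble with `rho`, `fluence` (double) and `fluence_str`
#'   (full-precision decimal strings).
#' @export
fluence_ss_hp <- function(medium, rho, n_terms, precision = "quad", z = 0) {
  assert_medium(medium)
  res <- hp_call(list(op = "fluence_ss", medium = hp_medium_spec(medium),
                      rho = rho, n_terms = n_terms, z = z,
                      dps = precision_dps(precision)))
  tibble(rho = rho, fluence = res$fluence, fluence_str = res$fluence_str)
}

#' Batched steady-state references at elevated precision
#'
#' Evaluates several `(medium, rho, z)` steady-state queries with a fixed
#' term count in one worker call, sharing the root table and Bessel rows:
#' this is what makes brute-force convergence references (tens of thousands
#' of quadruple-precision terms per configuration) affordable.
#'
#' @param configs A list of lists, each with elements `medium`
#'   (a [layered_medium()]), `rho` (numeric) and optional `z` (depth in
#'   layer 1, default 0).
#' @param n_terms Fixed term count shared by all configurations.
#' @param precision `"quad"`, `"oct"`, or decimal digits.
#' @return A list of numeric vectors, one per configuration.
#' @export
fluence_ss_hp_batch <- function(configs, n_terms, precision = "quad") {
  cfgs <- lapply(configs, function(cf) {
    assert_medium(cf$medium)
    list(medium = hp_medium_spec(cf$medium), rho = cf$rho, z = cf$z %||% 0)
  })
  res <- hp_call(list(op = "fluence_ss_batch", configs = cfgs,
                      n_terms = n_terms, dps = precision_dps(precision)))
  flu <- res$fluence
  if (is.matrix(flu)) flu <- lapply(seq_len(nrow(flu)), function(i) flu[i, ])
  if (!is.list(flu)) flu <- list(flu)
  flu
}

#' Time-resolved surface fluence at elevated working precision
#'
#' Same computation as [fluence_td()] at `z = 0` in the arbitrary-precision
#' backend: `n_laplace` contour nodes, `n_terms` Hankel roots, everything at
#' the requested precision (including the Bessel roots, which must be
#' computed at matching precision for the smallest fluence values to be
#' meaningful).
#'
#' @inheritParams fluence_td
#' @param n_terms Fixed number of Hankel terms per node.
#' @param precision `"quad"`, `"oct"`, or decimal digits.
#' @return Tibble with `rho`, `t`, `fluence`.
#' @export
fluence_td_hp <- function(medium, rho, times, n_laplace, t1, t2,
                          n_terms = 600, phi = NULL, precision = "oct") {
  assert_medium(medium)
  phi <- phi %||% contour_phi_optimal(t2 / t1)
  res <- hp_call(list(op = "fluence_td", medium = hp_medium_spec(medium),
                      rho = rho, times = times, n_laplace = n_laplace,
                      t1 = t1, t2 = t2, phi = phi, n_terms = n_terms,
                      dps = precision_dps(precision)))
  flu <- res$fluence
  if (is.null(dim(flu))) flu <- matrix(flu, nrow = length(rho), byrow = TRUE)
  rho_col <- rep(rho, each = length(times))
  t_col <- rep(times, times = length(rho))
  tibble(rho = rho_col, t = t_col, fluence = as.vector(t(flu)))
}

#' Semi-infinite closed forms at elevated working precision
#'
#' High-precision counterparts of [fluence_ss_semiinf()] and
#' [fluence_td_semiinf()], sharing the medium's boundary coefficient `A`.
#'
#' @param model A [semiinf_medium()].
#' @param rho Radial distances (cm).
#' @param precision `"quad"`, `"oct"`, or decimal digits.
#' @return A tibble.
#' @export
fluence_ss_semiinf_hp <- function(model, rho, precision = "quad") {
  stopifnot(inherits(model, "semiinf_medium"))
  res <- hp_call(list(op = "ss_semiinf", mu_a = model$mu_a, mu_sp = model$mu_sp,
                      A = model$A, rho = rho, dps = precision_dps(precision)))
  tibble(rho = rho, fluence = res$fluence, fluence_str = res$fluence_str)
}

#' @rdname fluence_ss_semiinf_hp
#' @param t Times (ns).
#' @export
fluence_td_semiinf_hp <- function(model, rho, t, precision = "oct") {
  stopifnot(inherits(model, "semiinf_medium"))
  res <- hp_call(list(op = "td_semiinf", mu_a = model$mu_a, mu_sp = model$mu_sp,
                      n_rel = model$n_rel, A = model$A, rho = rho, times = t,
                      dps = precision_dps(precision)))
  flu <- res$fluence
  if (is.null(dim(flu))) flu <- matrix(flu, nrow = length(rho), byrow = TRUE)
  rho_col <- rep(rho, each = length(t))
  t_col <- rep(t, times = length(rho))
  tibble(rho = rho_col, t = t_col, fluence = as.vector(t(flu)))
}

#' Evaluate |J0| at given abscissae in the backend
#'
#' Used to verify that roots refined at higher working precision drive the
#' residual `|J0(root)|` down accordingly.
#'
#' @param x Character vector of decimal abscissae (full precision).
#' @param precision `"quad"`, `"oct"`, or decimal digits.
#' @return Numeric vector of `|J0(x)|`.
#' @export
hp_abs_j0 <- function(x, precision = "oct") {
  res <- hp_call(list(op = "j0_at", x = as.character(x),
                      dps = precision_dps(precision)))
  res$abs_j0
}
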