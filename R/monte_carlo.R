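# R-side interface to the layered Monte Carlo validator.

#' Monte Carlo configuration
#'
#' Binning and transport options for [run_mc()]. Bin widths default to the
#' histogram registration used throughout the validation comparisons:
#' `dr = 0.099` cm, `dz = 0.027` cm, `dt = 0.02` ns. The full scattering
#' coefficient of each layer is derived from the medium's reduced value as
#' `mu_s = mu_sp / (1 - g)`.
#'
#' @param n_photons Number of photon packets.
#' @param g Henyey-Greenstein anisotropy factor, `0 <= g < 1`. Default 0.8.
#' @param dr,dz,dt Bin widths (cm, cm, ns).
#' @param n_r_bins,n_z_bins,n_t_bins Histogram extents.
#' @param dz_td Depth of the surface slab scored for the time-domain
#'   histogram, cm. Default 0.3: the per-(rho, t) bins are far smaller than
#'   the steady-state bins, and a 3 mm slab keeps their variance usable at
#'   desk-scale photon counts; diffusion comparisons integrate over the
#'   slab (Simpson), so the registration stays exact.
#' @param roulette_threshold,roulette_factor Russian-roulette parameters.
#' @param n_batches Number of photon batches used for standard-error
#'   estimation.
#' @param collimated Launch a normally incident collimated beam at the
#'   surface instead of the isotropic source at `z0` (used for analytic
#'   attenuation checks). Default `FALSE`.
#' @return A list of class `mc_config`.
#' @export
mc_config <- function(n_photons = 1e6, g = 0.8,
                      dr = 0.099, dz = 0.027, dt = 0.02,
                      n_r_bins = 70L, n_z_bins = 40L, n_t_bins = 250L,
                      dz_td = 0.3,
                      roulette_threshold = 1e-3, roulette_factor = 10,
                      n_batches = 32L, collimated = FALSE) {
  stopifnot(n_photons >= 1, g >= 0, g < 1, dr > 0, dz > 0, dt > 0,
            n_batches >= 2, roulette_factor > 1)
  structure(list(
    n_photons = as.integer(n_photons), g = g, dr = dr, dz = dz, dt = dt,
    n_r_bins = as.integer(n_r_bins), n_z_bins = as.integer(n_z_bins),
    n_t_bins = as.integer(n_t_bins), dz_td = dz_td,
    roulette_threshold = roulette_threshold, roulette_factor = roulette_factor,
    n_batches = as.integer(n_batches), collimated = isTRUE(collimated)
  ), class = "mc_config")
}

#' Run the layered Monte Carlo simulation
#'
#' Simulates photon packets launched from an isotropic source at depth
#' `z0 = 1/mu_sp[1]` in an index-matched layered slab, with Fresnel
#' reflection at the external top and bottom boundaries. Fluence is scored
#' with a collision estimator into `(rho, z)` and `(rho, z, t)` histograms.
#' Results are reproducible for a fixed R random seed (`set.seed()`).
#'
#' @param medium A [layered_medium()]; the lateral boundary is ignored
#'   (infinite-slab geometry), so use media whose radius is large compared
#'   with the largest `rho` of interest.
#' @param config An [mc_config()].
#' @return An object of class `mc_result`: list with tibbles `steady`
#'   (`rho`, `z`, `fluence`, `se`, `n_bin`) and `time` (`rho`, `z`, `t`,
#'   `fluence`, `se`), a `totals` list (energy bookkeeping), and the
#'   `config`/`medium` used. Fluence units are 1/cm^2 (steady state) and
#'   1/cm^2/ns (time domain), per launched photon.
#' @export
run_mc <- function(medium, config = mc_config()) {
  assert_medium(medium)
  stopifnot(inherits(config, "mc_config"))
  lay <- medium$layers
  mu_s <- lay$mu_sp / (1 - config$g)
  raw <- .mc_run_cpp(
    config$n_photons, lay$mu_a, mu_s, lay$z_bottom,
    lay$n_r[[1]], medium$n_out, config$g, medium$z0,
    config$dr, config$dz, config$dt,
    config$n_r_bins, config$n_z_bins, config$n_t_bins, config$dz_td,
    config$roulette_threshold, config$roulette_factor, config$n_batches,
    config$collimated
  )
  nb <- config$n_batches
  nr <- config$n_r_bins; nz <- config$n_z_bins; nt <- config$n_t_bins
  per_batch <- config$n_photons / nb

  r_edges <- (0:nr) * config$dr
  shell_area <- pi * diff(r_edges^2)            # cm^2
  vol_ss <- outer(shell_area, rep(config$dz, nz))  # nr x nz

  ss <- array(raw$ss, dim = c(nr, nz, nb))
  ss_flu <- sweep(ss, c(1, 2), vol_ss, "/") / per_batch
  ss_mean <- apply(ss_flu, c(1, 2), mean)
  ss_se <- apply(ss_flu, c(1, 2), stats::sd) / sqrt(nb)

  td <- array(raw$td, dim = c(nr, nt, nb))
  td_flu <- td / per_batch / (shell_area * config$dz_td * config$dt)
  td_mean <- apply(td_flu, c(1, 2), mean)
  td_se <- apply(td_flu, c(1, 2), stats::sd) / sqrt(nb)

  rho_centers <- (seq_len(nr) - 0.5) * config$dr
  z_centers <- (seq_len(nz) - 0.5) * config$dz
  t_centers <- (seq_len(nt) - 0.5) * config$dt

  steady <- tibble(
    rho = rep(rho_centers, times = nz),
    z = rep(z_centers, each = nr),
    fluence = as.vector(ss_mean),
    se = as.vector(ss_se)
  )
  time_tb <- tibble(
    rho = rep(rho_centers, times = nt),
    t = rep(t_centers, each = nr),
    z = config$dz_td / 2,
    fluence = as.vector(td_mean),
    se = as.vector(td_se)
  )
  totals <- list(
    launched = config$n_photons,
    deposited = raw$deposited, escaped_top = raw$escaped_top,
    escaped_bottom = raw$escaped_bottom, killed = raw$killed,
    gained = raw$gained
  )
  structure(list(steady = steady, time = time_tb, totals = totals,
                 config = config, medium = medium),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result: %g photons, g = %.3g, %d rho-bins>\n",
              x$config$n_photons, x$config$g, x$config$n_r_bins))
  invisible(x)
}

#' Sample Henyey-Greenstein deflection cosines
#'
#' Exposes the scattering-angle sampler of the Monte Carlo engine so its
#' first moment (`mean cosine = g`) can be checked empirically.
#'
#' @param n Number of samples.
#' @param g Anisotropy factor.
#' @return Numeric vector of sampled deflection cosines.
#' @export
sample_hg <- function(n, g) .mc_sample_hg_cpp(as.integer(n), g)

#' Per-bin relative error between diffusion theory and Monte Carlo
#'
#' Evaluates the layered diffusion solution at the Monte Carlo bin centres
#' (including the depth of the scored surface bin, `z = dz/2`) and returns
#' `|1 - Phi_DT / Phi_MC|` per bin with the Monte Carlo standard-error band.
#' Empty bins are dropped with a flag; bins with `rho < rho_min` (default
#' 0.5 cm, where diffusion theory is known to fail) are excluded from the
#' returned comparison but kept when `keep_all = TRUE`.
#'
#' @param mc An [run_mc()] result.
#' @param medium The diffusion-side [layered_medium()] (may differ from the
#'   Monte Carlo medium, e.g. a CSF scattering override).
#' @param rho_max Largest bin centre compared (cm).
#' @param rho_min Smallest bin centre compared. Default 0.5 cm.
#' @param se_frac Keep only bins whose MC standard error is below this
#'   fraction of the bin value. Default 0.01 (1 percent).
#' @param control Hankel control for the diffusion evaluations.
#' @param keep_all Return all bins, flagged, instead of filtering.
#' @return A tibble with `rho`, `mc`, `se`, `dt` (diffusion value),
#'   `rel_err`, `rel_se`.
#' @export
mc_compare_ss <- function(mc, medium = mc$medium, rho_max = Inf, rho_min = 0.5,
                          se_frac = 0.01, control = hankel_control(),
                          keep_all = FALSE) {
  stopifnot(inherits(mc, "mc_result"))
  cfg <- mc$config
  surf <- mc$steady[mc$steady$z == cfg$dz / 2, ]
  keep <- surf$fluence > 0 & surf$rho >= rho_min & surf$rho <= rho_max &
    surf$se < se_frac * surf$fluence
  rows <- if (keep_all) surf else surf[keep, ]
  dt_vals <- fluence_ss_depth(medium, rows$rho, z = cfg$dz / 2, control = control)$fluence
  out <- tibble(
    rho = rows$rho, mc = rows$fluence, se = rows$se, dt = dt_vals,
    rel_err = abs(1 - dt_vals / rows$fluence),
    rel_se = rows$se / rows$fluence
  )
  if (keep_all) out$included <- keep
  out
}

#' @rdname mc_compare_ss
#' @param rho Radial bin centres (matched to the MC grid) at which to
#'   compare the time-resolved curves.
#' @param t_min Earliest time compared, ns.
#' @param n_laplace,t2 Passed to [fluence_td()] (window `t1` is `t_min`).
#' @export
mc_compare_td <- function(mc, medium = mc$medium, rho, t_min = 0.1,
                          se_frac = 0.01, n_laplace = 24, t2 = NULL,
                          control = hankel_control()) {
  stopifnot(inherits(mc, "mc_result"))
  cfg <- mc$config
  # snap requested rho to bin centres
  ir <- pmax(1, pmin(cfg$n_r_bins, round(rho / cfg$dr + 0.5)))
  rho_c <- (ir - 0.5) * cfg$dr
  surf <- mc$time
  rows <- surf[surf$rho %in% rho_c & surf$t >= t_min, ]
  rows <- rows[rows$fluence > 0 & rows$se < se_frac * rows$fluence, ]
  if (nrow(rows) == 0)
    return(tibble(rho = numeric(), t = numeric(), mc = numeric(), se = numeric(),
                  dt = numeric(), rel_err = numeric(), rel_se = numeric()))
  t2 <- t2 %||% (max(rows$t) * 1.05)
  # slab-average registration in depth: the MC histogram is an average over
  # the scored surface slab, so integrate the diffusion value over it
  # (Simpson on [0, dz_td]) rather than evaluating at a single depth
  rho_u <- unique(rows$rho)
  t_u <- sort(unique(rows$t))
  z_nodes <- c(1e-6, cfg$dz_td / 2, cfg$dz_td)
  wts <- c(1, 4, 1) / 6
  acc <- 0
  for (i in seq_along(z_nodes)) {
    d_i <- fluence_td_depth(medium, rho_u, t_u, z = z_nodes[[i]],
                            n_laplace = n_laplace, t1 = min(rows$t) * 0.95,
                            t2 = t2, control = control)
    acc <- acc + wts[[i]] * d_i$fluence
  }
  lut <- setNames(acc, paste(d_i$rho, d_i$t))
  key <- paste(rows$rho, rows$t)
  dt_vals <- unname(lut[key])
  tibble(
    rho = rows$rho, t = rows$t, mc = rows$fluence, se = rows$se, dt = dt_vals,
    rel_err = abs(1 - dt_vals / rows$fluence),
    rel_se = rows$se / rows$fluence
  )
}

# Internal: time-domain fluence at a shallow depth inside layer 1 (bin-centre
# registration for MC comparisons).
fluence_td_depth <- function(medium, rho, times, z, n_laplace = 24,
                             t1 = NULL, t2 = NULL, phi = 1.09,
                             control = hankel_control()) {
  assert_medium(medium)
  t1 <- t1 %||% min(times)
  t2 <- t2 %||% max(times)
  contour <- laplace_contour(n_laplace, t1, t2, phi)
  n_nodes <- nrow(contour)
  H <- matrix(0 + 0i, nrow = n_nodes, ncol = length(rho))
  for (k in seq_len(n_nodes)) {
    sbar <- contour$node[[k]]
    hs <- hankel_sum(medium, rho, function(s) greens_sfd(medium, s, z, sbar), control)
    H[k, ] <- hs$values
  }
  h <- attr(contour, "h")
  fw <- H * (contour$dnode / 1i)
  grid <- expand.grid(rho = rho, t = times, KEEP.OUT.ATTRS = FALSE)
  vals <- numeric(nrow(grid))
  for (ti in seq_along(times)) {
    et <- exp(contour$node * times[[ti]])
    vals[(ti - 1) * length(rho) + seq_along(rho)] <- (h / pi) * colSums(Re(et * fw))
  }
  tibble(rho = grid$rho, t = grid$t, fluence = pmax(vals, 0))
}
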