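test_that("pure absorber obeys Beer-Lambert for a collimated beam", {
  set.seed(101)
  n <- 5e4
  raw <- layerfluence:::.mc_run_cpp(
    n, mu_a = 0.5, mu_s = 0, z_bot = 2, n_rel = 1, n_out = 1, g = 0, z0 = 0.01,
    dr = 0.1, dz = 0.1, dt = 0.02, nr = 10, nz = 10, nt = 10, dz_td = 0.1,
    roulette_threshold = 0, roulette_factor = 10, n_batches = 4,
    collimated = TRUE)
  p <- exp(-0.5 * 2)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(raw$escaped_bottom / n - p), 3 * se)
})

test_that("Henyey-Greenstein sampler has mean cosine g", {
  set.seed(202)
  for (g in c(0.8, 0.5)) {
    x <- sample_hg(1e6, g)
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - g), 3 * se)
  }
  set.seed(203)
  x0 <- sample_hg(1e5, 0)
  expect_lt(abs(mean(x0)), 3 * stats::sd(x0) / sqrt(1e5))
})

test_that("energy bookkeeping is exact and runs are seed-deterministic", {
  m <- fig2_medium()
  cfg <- mc_config(n_photons = 2e4, n_batches = 4)
  set.seed(7)
  a <- run_mc(m, cfg)
  expect_lt(glance(a)$balance_defect, 1e-11)
  set.seed(7)
  b <- run_mc(m, cfg)
  expect_identical(a$steady$fluence, b$steady$fluence)
  expect_identical(a$time$fluence, b$time$fluence)
  set.seed(8)
  c_ <- run_mc(m, cfg)
  expect_false(identical(a$steady$fluence, c_$steady$fluence))
})

test_that("per-bin standard error shrinks like 1/sqrt(n_photons)", {
  m <- fig2_medium()
  set.seed(11)
  small <- run_mc(m, mc_config(n_photons = 1e4, n_batches = 8))
  set.seed(11)
  big <- run_mc(m, mc_config(n_photons = 4e4, n_batches = 8))
  surf_s <- small$steady[small$steady$z == small$config$dz / 2, ]
  surf_b <- big$steady[big$steady$z == big$config$dz / 2, ]
  keep <- surf_s$fluence > 0 & surf_b$fluence > 0 & surf_s$rho < 2 &
    surf_s$se > 0 & surf_b$se > 0
  ratio <- median(surf_s$se[keep] / surf_b$se[keep])
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.9)
})

test_that("comparison harness flags gross model mismatch (negative control)", {
  sc <- scenario("semiinf_2layer")
  set.seed(21)
  mc <- run_mc(sc$medium, mc_config(n_photons = 2e5))
  cmp_ok <- mc_compare_ss(mc, se_frac = 0.05, rho_max = 3)
  expect_gt(nrow(cmp_ok), 5)
  expect_lt(max(cmp_ok$rel_err), 0.1)

  # doubled absorption must blow the comparison up
  m_bad <- layered_medium(c(0.2, 0.2), c(10, 10), c(5, 5), radius = 20)
  cmp_bad <- mc_compare_ss(mc, medium = m_bad, se_frac = 0.05, rho_max = 3)
  expect_gt(max(cmp_bad$rel_err), 0.2)
})
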