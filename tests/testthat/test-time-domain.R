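test_that("contour nodes form a left-opening hyperbola with conjugate pairing", {
  ct <- laplace_contour(24, t1 = 0.5, t2 = 5)
  expect_equal(attr(ct, "Lambda"), 10)
  expect_equal(nrow(ct), 24)
  # real part decreases toward the tails; only the upper half is stored
  expect_true(all(Im(ct$node) > 0))
  expect_true(all(diff(Re(ct$node)) < 0))
  expect_lt(Re(ct$node[[24]]), -20)
  # reducing to the classical single-time parameters at Lambda = 1
  expect_equal(contour_phi_optimal(1), 1.1721)
  expect_error(laplace_contour(24, t1 = 0, t2 = 1),
               class = "layerfluence_domain_error")
})

test_that("known transforms invert to stated accuracy", {
  ct <- laplace_contour(24, t1 = 0.5, t2 = 5)
  # unit step: F = 1/s
  expect_lt(abs(invert_laplace(function(s) 1 / s, 1, ct) - 1), 1e-10)
  tt <- seq(0.5, 5, length.out = 9)
  expect_lt(max(abs(invert_laplace(function(s) 1 / s, tt, ct) - 1)), 1e-9)
  # F = 1/(s+a)^2 -> t exp(-a t)
  a <- 1
  rec <- invert_laplace(function(s) 1 / (s + a)^2, tt, ct)
  expect_lt(max(abs(rec - tt * exp(-a * tt)) / (tt * exp(-a * tt))), 1e-8)
  # refusal outside the window
  expect_error(invert_laplace(function(s) 1 / s, 6, ct),
               class = "layerfluence_domain_error")
})

test_that("choose_n_laplace reproduces the calibrated dynamic-range table", {
  expect_identical(choose_n_laplace(3), 12L)
  expect_identical(choose_n_laplace(6), 24L)
  expect_gte(choose_n_laplace(50), 168L)
  expect_identical(choose_n_laplace(3.2, multiple_of = 8), 16L)
})

test_that("time-domain fluence matches the semi-infinite solution", {
  m <- scenario("fig4_contour")$medium
  si <- fig2_semiinf()
  ref <- fluence_td_semiinf(si, 1, 1)
  td <- fluence_td(m, 1, times = 1, n_laplace = 20, t1 = 1, t2 = 5,
                   control = hankel_control(n_terms = 1200))
  expect_lt(abs(td$fluence - ref), 1e-8)

  # error decreases with N up to the roundoff floor
  errs <- vapply(c(8, 16, 24, 32), function(N) {
    v <- fluence_td(m, 1, times = 1, n_laplace = N, t1 = 0.5, t2 = 5,
                    control = hankel_control(n_terms = 1000))$fluence
    abs(v - ref)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))

  # wider windows at fixed N are equal-or-worse
  e_wide <- abs(fluence_td(m, 1, 1, n_laplace = 16, t1 = 0.05, t2 = 5,
                           control = hankel_control(n_terms = 1000))$fluence - ref)
  expect_gt(e_wide, errs[[2]] / 10)  # no free lunch from widening
})

test_that("causality: fluence vanishes before photons can arrive", {
  m <- scenario("fig4_contour")$medium
  td <- fluence_td(m, rho = 3, times = 0.01, n_laplace = 24,
                   t1 = 0.005, t2 = 5, control = hankel_control(n_terms = 800))
  expect_lt(td$fluence, 1e-10)
})

test_that("time integral of the TPSF equals the steady-state fluence", {
  m <- fig2_medium()
  tt <- exp(seq(log(0.012), log(60), length.out = 400))
  td <- fluence_td(m, rho = 1, times = tt, n_laplace = 48, t1 = 0.01, t2 = 65,
                   control = hankel_control(n_terms = 1500))
  ss <- fluence_ss(m, rho = 1, control = hankel_control(n_terms = 1500))$fluence
  expect_equal(trapz(tt, td$fluence), ss, tolerance = 1e-3)
})

test_that("reconstruction is deterministic and refuses out-of-window times", {
  m <- fig2_medium()
  a <- fluence_td(m, 1, c(0.5, 1), n_laplace = 12, t1 = 0.4, t2 = 2,
                  control = hankel_control(n_terms = 400))
  b <- fluence_td(m, 1, c(0.5, 1), n_laplace = 12, t1 = 0.4, t2 = 2,
                  control = hankel_control(n_terms = 400))
  expect_identical(a$fluence, b$fluence)
  expect_error(fluence_td(m, 1, c(0.1, 3), n_laplace = 12, t1 = 0.4, t2 = 2),
               class = "layerfluence_domain_error")
})

test_that("modulated-source output reduces to steady state at zero frequency", {
  m <- fig2_medium()
  fd0 <- fluence_fd(m, rho = c(1, 2), omega = 0,
                    control = hankel_control(n_terms = 800))
  ss <- fluence_ss(m, rho = c(1, 2), control = hankel_control(n_terms = 800))
  expect_equal(Re(fd0$fluence), ss$fluence, tolerance = 1e-14)
  # finite modulation attenuates the AC amplitude and retards the phase
  fd <- fluence_fd(m, rho = c(1, 2), omega = 2 * pi * 0.1,
                   control = hankel_control(n_terms = 800))
  expect_true(all(fd$amplitude < ss$fluence))
  expect_true(all(fd$phase_rad < 0))
  expect_lt(fd$phase_rad[2], fd$phase_rad[1])  # more delay farther away
})
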