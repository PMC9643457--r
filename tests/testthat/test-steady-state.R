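test_that("layered Hankel sum matches the semi-infinite closed form", {
  m <- fig2_medium()
  si <- fig2_semiinf()
  v <- fluence_ss(m, rho = 1, control = hankel_control(n_terms = 1500))
  expect_lt(abs(v$fluence - fluence_ss_semiinf(si, 1)), 1e-12)

  # layering invariance: 2-layer vs 8-layer equal-property stacks
  v8 <- fluence_ss(equal_stack(8), rho = c(0.5, 1, 3),
                   control = hankel_control(n_terms = 1500))
  v2 <- fluence_ss(equal_stack(2), rho = c(0.5, 1, 3),
                   control = hankel_control(n_terms = 1500))
  expect_equal(v8$fluence, v2$fluence, tolerance = 1e-13)
})

test_that("dynamic stopping terminates and terms grow with rho and radius", {
  m <- fig2_medium()
  v <- fluence_ss(m, rho = c(0.5, 1, 2, 4, 8))
  expect_true(all(v$converged))
  expect_true(all(diff(v$terms_used) >= 0))   # more terms at larger rho
  expect_true(all(v$fluence > 0))

  # radius monotonicity at matched tolerance
  m_small <- equal_stack(2, radius = 10)
  v_small <- fluence_ss(m_small, rho = 1)
  expect_gte(v$terms_used[[2]], v_small$terms_used[[1]])
})

test_that("surface-only contract and domain errors are enforced", {
  m <- fig2_medium()
  expect_error(fluence_ss(m, rho = 25), class = "layerfluence_domain_error")
  expect_error(fluence_ss(m, rho = 1, z = 3), class = "layerfluence_domain_error")
  expect_warning(fluence_ss(m, rho = m$radius,
                            control = hankel_control(n_terms = 200)),
                 "lateral")
  # rho = 0 takes the J0(0) = 1 path
  v0 <- fluence_ss(m, rho = 0, control = hankel_control(n_terms = 800))
  expect_true(is.finite(v0$fluence) && v0$fluence > 0)
})

test_that("transmittance is positive, decreasing, and absorption-monotone", {
  m <- fig2_medium()
  tr <- transmittance_ss(m, rho = c(0.5, 1, 2, 4))
  expect_true(all(tr$fluence > 0))
  expect_true(all(diff(tr$fluence) < 0))

  # increasing absorption in any single layer never increases transmittance
  base <- transmittance_ss(m, rho = 1)$fluence
  for (k in 1:2) {
    mu_a <- c(0.1, 0.1)
    mu_a[k] <- 0.3
    m_k <- layered_medium(mu_a, c(10, 10), c(5, 5), radius = 20)
    expect_lt(transmittance_ss(m_k, rho = 1)$fluence, base)
  }
})

test_that("source-resummed reflectance matches the exact sum far faster", {
  m <- fig2_medium()
  exact <- fluence_ss(m, rho = c(0.5, 1, 2))
  appr <- approx_reflectance_ss(m, rho = c(0.5, 1, 2))
  expect_equal(appr$fluence, exact$fluence, tolerance = 1e-10)

  # high scattering: >= 10x fewer residual terms at matched tolerance
  mh <- layered_medium(rep(0.1, 4), rep(80, 4), c(0.5, 1.5, 3.5, 30), radius = 15)
  e_h <- fluence_ss(mh, rho = 1)
  a_h <- approx_reflectance_ss(mh, rho = 1)
  expect_equal(a_h$fluence, e_h$fluence, tolerance = 1e-10)
  expect_gt(e_h$terms_used / a_h$terms_used, 10)

  # approximate result stays finite/converged where a short exact sum is not
  short <- fluence_ss(mh, rho = 1, control = hankel_control(n_terms = 100))
  expect_gt(abs(short$fluence - e_h$fluence) / e_h$fluence, 0.01)
  expect_lt(abs(a_h$fluence - e_h$fluence) / e_h$fluence, 1e-9)
})

test_that("approximation outside its validity domain falls back with a warning", {
  m_low <- layered_medium(c(0.05, 0.05), c(1.5, 1.5), c(5, 5), radius = 20)
  expect_warning(v <- approx_reflectance_ss(m_low, rho = 2,
                                            control = hankel_control(n_terms = 500)),
                 "valid")
  ref <- fluence_ss(m_low, rho = 2, control = hankel_control(n_terms = 500))
  expect_equal(v$fluence, ref$fluence)
})

test_that("partial sums converge under the run-length rule", {
  m <- fig2_medium()
  full <- fluence_ss(m, rho = 2, control = hankel_control(n_terms = 3000))$fluence
  half <- fluence_ss(m, rho = 2, control = hankel_control(n_terms = 1500))$fluence
  expect_lt(abs(full - half) / full, 1e-8)
})
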