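test_that("wavenumbers take the principal branch with positive real part", {
  m <- fig2_medium()
  # mu_eff limit at s = 0
  al <- layer_wavenumbers(m, 0)
  expect_equal(al[1, 1], sqrt(3 * 0.1 * 10), tolerance = 1e-14)
  # alpha -> s asymptote
  al2 <- layer_wavenumbers(m, 1e6)
  expect_equal(al2[1, 1] / 1e6, 1, tolerance = 1e-9)
  # complex shift increases Re(alpha); principal branch enforced
  alc <- layer_wavenumbers(m, c(1, 5), s_bar = complex(real = 3, imaginary = 2))
  expect_true(all(Re(alc) > 0))
  expect_gt(Re(alc[1, 1]), al[1, 1])
})

test_that("layered sweep reproduces the single-slab closed form", {
  A <- a_coefficient(1.4)
  s <- c(0.2, 1, 3, 7, 15)   # moderate alpha: hyperbolic oracle still finite
  for (nl in c(1, 3, 5)) {
    m <- equal_stack(nl, L = 6)
    g_top <- greens_top(m, s, z = 0)
    g_bot <- greens_bottom(m, s)
    oracle_top <- slab_greens_oracle(0.1, 10, 6, A, s, z = 0)
    oracle_bot <- slab_greens_oracle(0.1, 10, 6, A, s, z = 6)
    expect_equal(g_top, oracle_top, tolerance = 1e-13)
    expect_equal(g_bot, oracle_bot, tolerance = 1e-13)
  }
  # interior depths in layer 1, both sides of the source
  m <- equal_stack(4, L = 6)
  for (z in c(0.05, 0.1, 0.9, 1.4)) {
    g <- layerfluence:::greens_sfd(m, s, z, 0)
    expect_equal(g, slab_greens_oracle(0.1, 10, 6, A, s, z = z), tolerance = 1e-13)
  }
})

test_that("Green's function vanishes at the extrapolated boundary", {
  m <- fig2_medium()
  g <- greens_top(m, s = c(0.5, 2, 10), z = -m$zb_top)
  expect_true(all(abs(g) < 1e-14))
})

test_that("underflow regime returns exact zeros, never overflows", {
  m <- layered_medium(rep(0.1, 4), rep(80, 4), c(0.5, 1.5, 3.5, 30), radius = 15)
  rt <- j0_zeros(50000)
  s <- rt$root / m$a_prime
  g <- greens_top(m, s, z = 0)
  expect_true(all(is.finite(g)))
  gb <- greens_bottom(m, s)
  expect_true(all(is.finite(gb)))
  # deep underflow (total optical depth beyond the double range) is exact 0
  expect_true(all(gb[s > 25] == 0))
  expect_true(any(gb > 0))
})

test_that("semi-infinite-bottom limit is reached by thickness 100 cm", {
  s <- c(0.5, 1, 3)
  m100 <- layered_medium(c(0.2, 0.1), c(13, 12), c(0.6, 100), radius = 20)
  m1e3 <- layered_medium(c(0.2, 0.1), c(13, 12), c(0.6, 1000), radius = 20)
  expect_equal(greens_top(m100, s, 0), greens_top(m1e3, s, 0), tolerance = 1e-15)
})

test_that("flux D dG/dz is continuous across interfaces", {
  m <- layered_medium(c(0.15, 0.02, 0.2), c(15, 12, 5), c(0.5, 0.8, 6), radius = 20)
  s <- c(0.5, 2)
  h <- 1e-6
  lay <- m$layers
  for (k in 1:2) {
    zi <- lay$z_bottom[[k]]
    g_up <- layerfluence:::greens_sfd(m, s, zi - 2 * h, 0)
    g_mid_u <- layerfluence:::greens_sfd(m, s, zi - h, 0)
    g_mid_l <- layerfluence:::greens_sfd(m, s, zi + h, 0)
    g_lo <- layerfluence:::greens_sfd(m, s, zi + 2 * h, 0)
    flux_up <- lay$D[[k]] * (g_mid_u - g_up) / h
    flux_lo <- lay$D[[k + 1]] * (g_lo - g_mid_l) / h
    expect_equal(flux_up, flux_lo, tolerance = 1e-4)
    # value continuity is much tighter
    expect_equal(g_mid_u, g_mid_l, tolerance = 1e-4)
  }
})

test_that("reciprocity and conjugate symmetry hold", {
  m <- equal_stack(3, L = 6)
  A <- a_coefficient(1.4)
  s <- c(0.5, 2, 8)
  # reciprocity via the slab form: G(z; z0) with z, z0 exchanged
  g_a <- slab_greens_oracle(0.1, 10, 6, A, s, z = 0.4, z0 = 0.1)
  g_b <- slab_greens_oracle(0.1, 10, 6, A, s, z = 0.1, z0 = 0.4)
  expect_equal(g_a, g_b, tolerance = 1e-13)
  expect_equal(layerfluence:::greens_sfd(m, s, 0.4, 0), g_a, tolerance = 1e-13)

  sb <- complex(real = 0.3, imaginary = 4)
  g1 <- greens_top(m, s, 0, s_bar = sb)
  g2 <- greens_top(m, s, 0, s_bar = Conj(sb))
  expect_equal(g2, Conj(g1), tolerance = 1e-15)
})

test_that("depth queries outside the named layer are rejected", {
  m <- fig2_medium()
  expect_error(greens_top(m, 1, z = 6), class = "layerfluence_domain_error")
  expect_error(greens_bottom(m, 1, z = 1), class = "layerfluence_domain_error")
})
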