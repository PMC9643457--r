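test_that("diffusion coefficient follows D = 1/(3 mu_sp)", {
  expect_equal(diffusion_coefficient(10), 1 / 30)
  expect_equal(diffusion_coefficient(1 / 3), 1)
  expect_equal(diffusion_coefficient(80), 1 / 240)
  expect_error(diffusion_coefficient(0), class = "layerfluence_invalid_medium")
  expect_error(diffusion_coefficient(-2), class = "layerfluence_invalid_medium")
})

test_that("A coefficient matches an independent Fresnel-integral quadrature", {
  expect_identical(a_coefficient(1.0), 1.0)

  # oracle: same hemispheric moments by Gauss-Kronrod quadrature (pracma)
  n_rel <- 1.4
  rf <- function(th) {
    st <- sin(th)
    if (n_rel * st >= 1) return(1)
    tht <- asin(n_rel * st)
    rs <- ((n_rel * cos(th) - cos(tht)) / (n_rel * cos(th) + cos(tht)))^2
    rp <- ((n_rel * cos(tht) - cos(th)) / (n_rel * cos(tht) + cos(th)))^2
    0.5 * (rs + rp)
  }
  th_c <- asin(1 / n_rel)
  q <- function(f) pracma::quadgk(Vectorize(f), 0, th_c, tol = 1e-13) +
    pracma::quadgk(Vectorize(f), th_c, pi / 2, tol = 1e-13)
  r_phi <- q(function(th) 2 * sin(th) * cos(th) * rf(th))
  r_j <- q(function(th) 3 * sin(th) * cos(th)^2 * rf(th))
  r_eff <- (r_phi + r_j) / (2 - r_phi + r_j)
  A_oracle <- (1 + r_eff) / (1 - r_eff)
  expect_equal(a_coefficient(1.4), A_oracle, tolerance = 1e-10)
  expect_gt(a_coefficient(1.4), 2.9)
  expect_lt(a_coefficient(1.4), 3.0)

  # caching determinism
  expect_identical(a_coefficient(1.4), a_coefficient(1.4))
  # override is honoured
  expect_identical(a_coefficient(1.4, override = 2.95), 2.95)
})

test_that("layered_medium populates derived geometry correctly", {
  m <- layered_medium(c(0.1, 0.1), c(10, 10), c(5, 5), radius = 20)
  expect_equal(m$L, 10)
  expect_equal(m$z0, 0.1)
  expect_equal(m$zb_top, 2 * m$A / 30)
  expect_equal(m$a_prime, 20 + m$zb_top)
  expect_gt(m$zb_top, 0)
  expect_gt(m$a_prime, m$radius)

  m4 <- layered_medium(rep(0.1, 4), rep(10, 4), c(0.5, 1.5, 3.0, 5.0), radius = 15)
  expect_equal(m4$layers$z_bottom, c(0.5, 2.0, 5.0, 10.0))
  expect_equal(m4$L, sum(m4$layers$thickness))

  # single layer degenerates to a homogeneous slab description
  m1 <- layered_medium(0.1, 10, 5, radius = 10)
  expect_equal(nrow(m1$layers), 1)
  expect_equal(m1$zb_top, m1$zb_bottom)

  # rebuilding yields bit-identical derived parameters
  m_b <- layered_medium(c(0.1, 0.1), c(10, 10), c(5, 5), radius = 20)
  expect_identical(glance(m), glance(m_b))
})

test_that("invalid media are rejected with informative classes", {
  expect_error(layered_medium(0.1, 10, 0.05, radius = 10),
               class = "layerfluence_unsupported_geometry")  # z0 >= l1
  expect_error(layered_medium(c(0.1, 0.1), c(10, 10), c(5, 5), radius = 10,
                              n_r = c(1.4, 1.5)),
               class = "layerfluence_unsupported_medium")
  expect_error(layered_medium(0.1, -1, 5, radius = 10),
               class = "layerfluence_invalid_medium")
  expect_error(layered_medium(0.1, 10, 5, radius = -1),
               class = "layerfluence_invalid_medium")
})

test_that("tidiers expose per-layer and derived views", {
  m <- layered_medium(c(0.2, 0.1), c(13, 12), c(0.6, 9), radius = 20)
  td <- tidy(m)
  expect_equal(nrow(td), 2)
  expect_equal(td$mu_a, c(0.2, 0.1))
  g <- glance(m)
  expect_equal(g$n_layers, 2)
  expect_equal(g$c_medium, c0_cm_ns() / 1.4)
})
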