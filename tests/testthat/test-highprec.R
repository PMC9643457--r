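test_that("the arbitrary-precision backend is present and consistent", {
  expect_true(hp_available())
  m <- fig2_medium()
  hp <- fluence_ss_hp(m, rho = 1, n_terms = 1000, precision = "quad")
  dd <- fluence_ss(m, rho = 1, control = hankel_control(n_terms = 1000))
  expect_lt(abs(hp$fluence - dd$fluence), 1e-14)
  # full-precision string carries more digits than a double
  expect_gt(nchar(gsub("[^0-9]", "", hp$fluence_str)), 20)
})

test_that("root refinement at higher precision drives |J0| down accordingly", {
  rt_d <- j0_zeros(10)
  rt_q <- j0_zeros(10, precision_bits = 113)
  expect_equal(rt_q$root, rt_d$root, tolerance = 1e-14)
  resid_d <- hp_abs_j0(format(rt_d$root, digits = 17), precision = "quad")
  resid_q <- hp_abs_j0(rt_q$root_str, precision = "quad")
  expect_lt(max(resid_d), 1e-14)        # double roots: double-level residual
  expect_lt(max(resid_q), 1e-30)        # refined roots: quad-level residual
  # and the refined table round-trips through the text cache
  path <- tempfile()
  write_root_table(rt_q, path)
  back <- read_root_table(path)
  expect_identical(back$root_str, rt_q$root_str)
  expect_equal(attr(back, "precision_bits"), 113)
})

test_that("batched references agree with the single-call path", {
  m <- fig2_medium()
  single <- fluence_ss_hp(m, rho = c(1, 2), n_terms = 600, precision = "quad")
  batch <- fluence_ss_hp_batch(list(list(medium = m, rho = c(1, 2))),
                               n_terms = 600, precision = "quad")
  expect_equal(batch[[1]], single$fluence, tolerance = 1e-15)
})
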