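test_that("J0/J1 evaluators agree with arbitrary-precision references", {
  expect_identical(bessel_j0(0), 1)
  expect_identical(bessel_j1(0), 0)

  # frozen mpmath (30-digit) references, including the asymptotic regime
  # where base besselJ() runs out of range
  expect_lt(abs(bessel_j0(1000) - 0.02478668615242017456133), 1e-14)
  expect_lt(abs(bessel_j1(1000) - 0.004728311907089523917576), 1e-14)
  expect_lt(abs(bessel_j0(100000) - (-0.001719201116235972192571)), 1e-14)
  expect_lt(abs(bessel_j1(100000) - 0.001846757562882567716362), 1e-14)
  expect_lt(abs(bessel_j0(157000.5) - (-0.0003853106115904992188848)), 1e-14)
  expect_lt(abs(bessel_j1(157000.5) - 0.001976466791275959987528), 1e-14)

  # the two evaluation paths agree where both are valid
  xs <- seq(50, 80, by = 3.7)
  expect_lt(max(abs(layerfluence:::bessel_asym(xs, 0, layerfluence:::.J0_ASYM) -
                      besselJ(xs, 0))), 1e-14)
  expect_lt(max(abs(layerfluence:::bessel_asym(xs, 1, layerfluence:::.J1_ASYM) -
                      besselJ(xs, 1))), 1e-14)

  expect_error(bessel_j0(-1), class = "layerfluence_domain_error")
  expect_error(bessel_j1(NaN), class = "layerfluence_domain_error")
})

test_that("J0 zeros are correct, monotone, and McMahon-spaced", {
  rt <- j0_zeros(5)
  # first root, bisection/Newton-verified classical value
  expect_equal(rt$root[[1]], 2.404825557695773, tolerance = 1e-15)
  expect_true(all(diff(rt$root) > 0))
  expect_true(all(abs(bessel_j0(rt$root)) < 1e-13))

  big <- j0_zeros(50000)
  expect_true(all(diff(big$root) > 0))
  sp <- diff(big$root)
  expect_lt(max(abs(sp[10000:49999] - pi)), 1e-9)  # asymptotic spacing
  expect_true(all(is.finite(big$weight)))

  # interlacing: J1 does not vanish at J0 zeros and alternates sign
  j1v <- bessel_j1(big$root[1:1000])
  expect_true(all(abs(j1v) > 0.01))
  expect_true(all(sign(j1v[-1]) == -sign(j1v[-1000])))
})

test_that("root tables persist as plain text and round-trip", {
  rt <- j0_zeros(20)
  path <- tempfile(fileext = ".txt")
  write_root_table(rt, path)
  lines <- readLines(path)
  expect_equal(strsplit(lines[[1]], " ")[[1]], c("20", "53"))
  back <- read_root_table(path)
  expect_equal(back$root, rt$root, tolerance = 1e-15)
  expect_equal(attr(back, "n_max"), 20)
  expect_equal(attr(back, "precision_bits"), 53)
})

test_that("repeated root computation is deterministic", {
  expect_identical(j0_zeros(100)$root, j0_zeros(100)$root)
})
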