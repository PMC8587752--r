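test_that("cut_region selects the closed interval and is idempotent", {
  x <- seq(900, 4000, by = 2)
  s <- ftir_spectrum(x, rep(1, length(x)), meta_n(1))
  set <- spectra_set(list(s))
  cutd <- cut_region(set, "fingerprint")
  expect_equal(length(cutd$grid), 151)
  expect_true(all(cutd$grid >= 900 & cutd$grid <= 1200))
  expect_equal(cut_region(cutd, "fingerprint"), cutd)
  expect_error(cut_region(set, list(lo = 4500, hi = 5000)), "intersect")
})

test_that("baseline correction recovers a band from a tilted baseline", {
  # straight line -> all zeros under both methods
  x <- seq(1000, 1200, 4)
  line <- ftir_spectrum(x, 0.2 + 0.003 * x, meta_n(1))
  expect_lt(max(abs(baseline_correct(line, "rubberband")$absorbance)), 1e-12)
  expect_lt(max(abs(baseline_correct(line,
                                     "linear_endpoints")$absorbance)), 1e-12)

  # single Gaussian on zero baseline: rubberband leaves the peak intact
  g <- gaussian_spectrum(a = 0.8, center = 1650, sigma = 20)
  rb <- baseline_correct(g, "rubberband")
  # oracle: the hull of a single positive band on a flat floor is the chord
  # between the endpoints, so the interior must be (almost) untouched
  expect_equal(rb$absorbance[1], 0)
  expect_equal(rb$absorbance[length(g$wavenumbers)], 0)
  ctr <- which.min(abs(g$wavenumbers - 1650))
  expect_lt(abs(rb$absorbance[ctr] - g$absorbance[ctr]), 0.01 * 0.8)

  # Gaussian + tilted line: recovered within 1% of peak height inside peak
  tilt <- gaussian_spectrum(a = 0.8, center = 1650, sigma = 20,
                            baseline = function(x) 1 + 0.002 * x)
  rec <- baseline_correct(tilt, "rubberband")
  inside <- abs(tilt$wavenumbers - 1650) < 40
  expect_lt(max(abs(rec$absorbance[inside] - g$absorbance[inside])),
            0.01 * 0.8)
  expect_true(all(rec$absorbance >= 0))
})

test_that("area normalization yields unit integral and scale invariance", {
  x <- seq(1000, 1100, 10)
  const <- ftir_spectrum(x, rep(3, length(x)), meta_n(1))
  n1 <- area_normalize(const)
  expect_equal(n1$absorbance, rep(1 / 100, length(x)))
  g <- gaussian_spectrum()
  n2 <- area_normalize(g)
  g7 <- ftir_spectrum(g$wavenumbers, 7 * g$absorbance, g$meta)
  expect_equal(area_normalize(g7)$absorbance, n2$absorbance)
  # idempotence
  expect_equal(area_normalize(n2)$absorbance, n2$absorbance)
  neg <- ftir_spectrum(x, rep(-1, length(x)), meta_n(1))
  expect_error(area_normalize(neg), "nonpositive")
})

test_that("SG second derivative is exact on polynomials and linear", {
  x <- seq(900, 1100, 2)
  quad <- ftir_spectrum(x, x^2, meta_n(1))
  d2 <- second_derivative_sg(quad, sg_params(window_points = 5))
  interior <- 3:(length(x) - 2)
  expect_lt(max(abs(d2$absorbance[interior] - 2)), 1e-9)
  lin <- ftir_spectrum(x, 5 * x - 3, meta_n(1))
  expect_lt(max(abs(second_derivative_sg(lin)$absorbance)), 1e-9)
})

test_that("SG second derivative matches the Gaussian closed form at center", {
  g <- gaussian_spectrum(a = 0.7, center = 1650, sigma = 10, step = 2)
  d2 <- second_derivative_sg(g, sg_params())
  ctr <- which.min(abs(g$wavenumbers - 1650))
  expect_lt(abs(d2$absorbance[ctr] - (-0.7 / 100)), 0.02 * 0.7 / 100)
})

test_that("SG differentiation is linear in the input", {
  x <- seq(1000, 1200, 2)
  set.seed(5)
  f <- ftir_spectrum(x, runif(length(x)), meta_n(1))
  g <- ftir_spectrum(x, runif(length(x)), meta_n(2))
  comb <- ftir_spectrum(x, 2.5 * f$absorbance - 1.25 * g$absorbance,
                        meta_n(3))
  lhs <- second_derivative_sg(comb, sg_params(7))$absorbance
  rhs <- 2.5 * second_derivative_sg(f, sg_params(7))$absorbance -
    1.25 * second_derivative_sg(g, sg_params(7))$absorbance
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("SG rejects non-uniform grids and oversized windows", {
  x <- c(seq(1000, 1050, 5), 1061)
  s <- ftir_spectrum(x, seq_along(x), meta_n(1))
  expect_error(second_derivative_sg(s), "uniform")
  short <- ftir_spectrum(seq(1000, 1035, 5), rnorm(8), meta_n(1))
  expect_error(second_derivative_sg(short, sg_params(9)), "window")
  expect_error(sg_params(4), "odd")
  expect_error(sg_params(3, poly_order = 3), "poly_order")
})
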