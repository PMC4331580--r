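test_that("profile construction enforces the gradient invariants", {
  expect_error(gradient_profile(1:3, c(1.8, 1.79, 1.78), c(1, 2, 3)),
               "at least 4")
  expect_error(gradient_profile(1:4, c(1.8, 1.79, 1.79, 1.78), 1:4),
               "monotone")
  expect_error(gradient_profile(1:4, c(1.8, 1.79, 1.78, 1.77),
                                c(1, -2, 3, 4)), "non-negative")
})

test_that("normalisation rescales to the profile maximum", {
  p <- gradient_profile(1:4, c(1.80, 1.79, 1.78, 1.77), c(2, 8, 4, 1))
  np <- normalize_profile(p)
  expect_equal(np$copies, c(0.25, 1, 0.5, 0.125))
  expect_equal(max(np$copies), 1)
  zero <- gradient_profile(1:4, c(1.80, 1.79, 1.78, 1.77), rep(0, 4))
  expect_error(normalize_profile(zero), "degenerate")
})

test_that("normalisation is idempotent and scale-invariant", {
  set.seed(5)
  for (i in 1:10) {
    p <- gradient_profile(1:6, seq(1.81, 1.77, length.out = 6),
                          runif(6, 0, 100))
    np <- normalize_profile(p)
    expect_equal(normalize_profile(np)$copies, np$copies)
    k <- runif(1, 0.01, 50)
    ps <- p
    ps$copies <- k * p$copies
    expect_equal(normalize_profile(ps)$copies, np$copies)
  }
})

test_that("fractions classify into light, heavy and other windows", {
  w <- density_windows()
  expect_equal(classify_fraction(1.795, w), "heavy")
  expect_equal(classify_fraction(1.782, w), "light")
  expect_equal(classify_fraction(1.750, w), "other")
  expect_equal(classify_fraction(c(1.806, 1.791), w), c("heavy", "heavy"))
  expect_warning(classify_fraction(1.70, w), "plausible")
  expect_error(density_windows(heavy_lo = 1.78), "light_center")
})

test_that("identical labeled and unlabeled profiles show no shift", {
  p <- make_two_band_profile(0)
  ev <- labeling_evidence(p, p)
  expect_false(ev$shifted)
  expect_equal(ev$difference, 0)
  expect_equal(ev$diff_fraction, rep(0, nrow(p)))
})

test_that("heavy-window mass fractions partition total mass", {
  p <- normalize_profile(make_two_band_profile(0.6))
  w <- density_windows()
  cls <- classify_fraction(p$bd, w)
  heavy <- sum(p$copies[cls == "heavy"]) / sum(p$copies)
  rest <- sum(p$copies[cls != "heavy"]) / sum(p$copies)
  expect_equal(heavy + rest, 1, tolerance = 1e-12)
  ev <- labeling_evidence(p, normalize_profile(make_two_band_profile(0)))
  expect_equal(ev$heavy_mass_fraction_labeled, heavy)
  expect_true(ev$heavy_mass_fraction_labeled >= 0 &&
                ev$heavy_mass_fraction_labeled <= 1)
})

test_that("a 60% label shift is detected; light-only pairs are not", {
  lab <- make_two_band_profile(0.6)
  unl <- make_two_band_profile(0)
  ev <- labeling_evidence(lab, unl)
  expect_true(ev$shifted)
  expect_gt(ev$difference, 0.15)
  # archaeal-style pair: both light-only
  arch <- labeling_evidence(make_two_band_profile(0, domain = "Archaea"),
                            make_two_band_profile(0, domain = "Archaea"))
  expect_false(arch$shifted)
})

test_that("pairing uses nearest buoyant density and fails without overlap", {
  lab <- make_two_band_profile(0.6)
  # unlabeled grid offset by less than the tolerance still pairs
  unl <- make_two_band_profile(0, bd_hi = 1.821, bd_lo = 1.771)
  expect_s3_class(labeling_evidence(lab, unl), "labeling_evidence")
  # non-overlapping BD ranges error
  far <- gradient_profile(1:5, seq(1.90, 1.86, length.out = 5), rep(1, 5))
  expect_error(suppressWarnings(labeling_evidence(lab, far)), "pairing")
})

test_that("heavy-fraction selection matches a direct scan and ignores indexing", {
  bd <- seq(1.82, 1.77, length.out = 12)
  p <- gradient_profile(1:12, bd, rep(1, 12))
  w <- density_windows()
  sel <- select_heavy_fractions(p, w)
  expect_identical(sel, which(bd >= 1.791 & bd <= 1.801))
  # re-indexed fractions: selection depends only on BD
  p2 <- gradient_profile(101:112, bd, rep(1, 12))
  expect_identical(select_heavy_fractions(p2, w) - 100L, sel)
  # window outside the grid
  low <- gradient_profile(1:5, seq(1.789, 1.77, length.out = 5), rep(1, 5))
  expect_warning(empty <- select_heavy_fractions(low, w), "no fractions")
  expect_identical(empty, integer(0))
  # window covering the whole grid
  wide <- density_windows(select_lo = 1.791, select_hi = 1.806)
  inwin <- gradient_profile(1:4, seq(1.805, 1.792, length.out = 4), rep(1, 4))
  expect_identical(select_heavy_fractions(inwin, wide), 1:4)
})
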