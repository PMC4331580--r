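test_that("acetate electron yield follows the 8 e- stoichiometry and is linear", {
  expect_equal(acetate_electron_yield(24), 192)
  expect_equal(acetate_electron_yield(17), 136)
  expect_equal(acetate_electron_yield(0), 0)
  for (i in 1:20) {
    a <- runif(1, 0, 50)
    b <- runif(1, 0, 50)
    expect_equal(acetate_electron_yield(a + b),
                 acetate_electron_yield(a) + acetate_electron_yield(b))
  }
  expect_error(acetate_electron_yield(-1), "non-negative")
})

test_that("electron balance partitions electrons to Fe(III) at 1 e- per Fe", {
  eb <- electron_balance(142, 192)
  expect_equal(eb$e_to_fe, 142)
  expect_equal(eb$percent_reported, 74)
  expect_equal(electron_balance(6.0, 130)$percent_reported, 4.6)
  expect_equal(electron_balance(0, 192)$percent_reported, 0)
  expect_error(electron_balance(10, 0), "undefined|positive")
  expect_error(electron_balance(-1, 100), "non-negative")
})

test_that("electron flow above 100% is reported with a warning, never clamped", {
  expect_warning(eb <- electron_balance(250, 192), "exceeds")
  expect_gt(eb$percent_to_fe, 100)
  expect_true(eb$exceeds_production)
  expect_equal(eb$percent_reported, signif_away(100 * 250 / 192, 2))
})

test_that("reducible Fe(III) is the extractable difference and conserves iron", {
  expect_equal(reducible_fe3(155, 75), 80)
  expect_equal(reducible_fe3(63, 63), 0)
  expect_equal(reducible_fe3(75, 20), 55)
  for (i in 1:20) {
    tot <- runif(1, 50, 200)
    fe2 <- runif(1, 0, tot)
    expect_identical(fe2 + reducible_fe3(tot, fe2), tot)
  }
  expect_error(reducible_fe3(50, 60, time_days = 2),
               "inconsistency at day 2")
})

test_that("ferrihydrite accounting uses five Fe per formula unit", {
  expect_equal(ferrihydrite_formula_units(140), 28)
  expect_equal(ferrihydrite_formula_units(5), 1)
  expect_equal(ferrihydrite_formula_units(0), 0)
  expect_error(ferrihydrite_formula_units(-5), "non-negative")
})

test_that("labeled gas amounts scale with atom percent", {
  expect_equal(labeled_gas_amount(10, 50), 5)
  expect_equal(labeled_gas_amount(12.4, 80), 9.92)
  expect_equal(labeled_gas_amount(7, 0), 0)
  expect_error(labeled_gas_amount(10, 101), "\\[0, 100\\]")
  expect_error(labeled_gas_amount(10, -2), "\\[0, 100\\]")
})

test_that("13C recovery sums products over the added label", {
  expect_equal(c13_recovery(7.6, 4.1, 8.0, 60, rounded = TRUE), 33)
  expect_equal(c13_recovery(13, 2.7, 2.8, 60, rounded = TRUE), 31)
  expect_equal(c13_recovery(0, 0, 0, 60), 0)
  expect_error(c13_recovery(1, 1, 1, 0), "undefined")
  expect_error(c13_recovery(-1, 1, 1, 60), "non-negative")
})

test_that("suppression percentages compare treatment to control", {
  expect_equal(suppression_percent(6.5, 10), 35)
  expect_equal(suppression_percent(10, 10), 0)
  expect_lt(suppression_percent(12, 10), 0)  # stimulation reported as-is
  expect_error(suppression_percent(5, 0), "zero control")
})

test_that("table-style rounding is half away from zero", {
  expect_equal(round_away(c(0.5, 1.5, 2.5, -0.5)), c(1, 2, 3, -1))
  expect_equal(signif_away(c(73.958, 4.615, 30.93, 83.87), 2),
               c(74, 4.6, 31, 84))
  expect_equal(signif_away(0, 2), 0)
})
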