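test_that("relative abundances sum to 100 per sample", {
  tab <- rbind(s1 = c(Geobacter = 30, Other = 70),
               s2 = c(Geobacter = 1, Other = 0))
  rel <- relative_abundance(tab)
  expect_equal(unname(rel["s1", ]), c(30, 70))
  expect_equal(unname(rel["s2", "Geobacter"]), 100)
  expect_equal(unname(rowSums(rel)), rep(100, 2), tolerance = 1e-9)
  set.seed(3)
  big <- matrix(rpois(60, 20), nrow = 6,
                dimnames = list(paste0("s", 1:6), paste0("g", 1:10)))
  expect_equal(unname(rowSums(relative_abundance(big))), rep(100, 6),
               tolerance = 1e-9)
})

test_that("zero-count samples are dropped with a warning", {
  tab <- rbind(s1 = c(a = 3, b = 7), s2 = c(a = 0, b = 0))
  expect_warning(rel <- relative_abundance(tab), "zero total")
  expect_equal(rownames(rel), "s1")
})

test_that("multinomial sampling recovers generating proportions", {
  set.seed(21)
  p <- c(g1 = 0.1, g2 = 0.3, g3 = 0.6)
  depth <- 4000
  counts <- t(rmultinom(5, depth, p))
  colnames(counts) <- names(p)
  rel <- relative_abundance(counts)
  se <- sqrt(p * (1 - p) / (5 * depth)) * 100
  expect_true(all(abs(colMeans(rel) - 100 * p) < 4 * se))
})

test_that("exact permutation p-values match bitmask enumeration", {
  expect_equal(perm_test_greater(c(30, 32, 31), c(2, 3, 2)), 0.05)
  set.seed(17)
  for (i in 1:20) {
    x <- rnorm(3, 5, 2)
    y <- rnorm(3, 4, 2)
    expect_equal(perm_test_greater(x, y), perm_p_bitmask(x, y))
  }
  # unequal group sizes too
  x <- rnorm(4)
  y <- rnorm(2)
  expect_equal(perm_test_greater(x, y), perm_p_bitmask(x, y))
})

test_that("all-identical replicates give p = 1 by convention", {
  expect_equal(perm_test_greater(c(5, 5, 5), c(5, 5, 5)), 1)
})

test_that("screen flags only significantly enriched genera", {
  lab <- cbind(Geobacter = c(30, 32, 31), Bacillus = c(2, 2, 3))
  unl <- cbind(Geobacter = c(2, 3, 2), Bacillus = c(2, 3, 2))
  res <- assimilator_screen(lab, unl)
  expect_true(res$assimilator[res$genus == "Geobacter"])
  expect_false(res$assimilator[res$genus == "Bacillus"])
  # identical treatments flag nothing
  same <- assimilator_screen(unl, unl)
  expect_false(any(same$assimilator))
})

test_that("alpha bounds behave as limits of the screen", {
  set.seed(8)
  lab <- matrix(runif(15, 1, 10), nrow = 3,
                dimnames = list(NULL, paste0("g", 1:5)))
  unl <- matrix(runif(15, 1, 10), nrow = 3,
                dimnames = list(NULL, paste0("g", 1:5)))
  none <- assimilator_screen(lab, unl, alpha = 0)
  expect_false(any(none$assimilator))
  all_up <- assimilator_screen(lab, unl, alpha = 1)
  expect_identical(all_up$assimilator,
                   all_up$mean_rel_labeled > all_up$mean_rel_unlabeled)
})

test_that("net change and fold change are mutually consistent", {
  expect_equal(net_change(31, 2.4), 28.6)
  expect_equal(net_change(5, 5), 0)
  expect_equal(net_change(0, 5), -5)
  expect_equal(signif_away(fold_change(31, 2.4), 2), 13)
  expect_equal(fold_change(5, 5), 1)
  for (i in 1:20) {
    mt <- runif(1, 0, 60)
    mc <- runif(1, 0.5, 40)
    expect_equal(net_change(mt, mc), mc * (fold_change(mt, mc) - 1))
  }
  expect_error(net_change(150, 2), "\\[0, 100\\]")
})

test_that("zero-control fold change needs the flagged pseudo-count", {
  expect_error(fold_change(5, 0), "pseudo_count")
  fc <- fold_change(5, 0, pseudo_count = 0.1)
  expect_equal(as.numeric(fc), 51)
  expect_equal(attr(fc, "pseudo_count"), 0.1)
  expect_equal(half_min_nonzero(c(0, 0.4, 2)), 0.2)
})

test_that("iron-reducer filter keeps exactly the reference genera present", {
  ref <- iron_reducer_genera()
  expect_equal(nrow(ref), 11)
  expect_false(anyDuplicated(ref$genus) > 0)
  tab <- cbind(Geobacter = c(5, 8), Methanosarcina = c(3, 1))
  sub <- filter_iron_reducers(tab)
  expect_identical(colnames(sub), "Geobacter")
  expect_identical(sub[, "Geobacter"], tab[, "Geobacter"])  # counts unchanged
  # field-style table containing all reference genera plus bystanders
  field <- matrix(1, nrow = 2, ncol = 13,
                  dimnames = list(NULL, c(ref$genus, "Methanosarcina",
                                          "Anaerolinea")))
  expect_setequal(colnames(filter_iron_reducers(field)), ref$genus)
  empty <- matrix(1, 2, 1, dimnames = list(NULL, "Methanosarcina"))
  expect_warning(out <- filter_iron_reducers(empty), "no reference")
  expect_equal(ncol(out), 0)
})

test_that("top-genera rank filter orders by mean abundance", {
  rel <- rbind(c(a = 1, b = 50, c = 10), c(a = 2, b = 40, c = 20))
  expect_identical(top_genera(rel, 2), c("b", "c"))
})
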