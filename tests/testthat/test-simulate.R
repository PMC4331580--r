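fer_spec <- microcosm_spec("NF", "FER", "C13")

test_that("noiseless stoichiometric limits hold", {
  # everything to Fe: 8 Fe(II) per acetate, no methane beyond background
  p <- sim_params(f_fe = c(FER = 1, GOE = 0.22, CTR = 0.08),
                  f_meth = c(FER = 0, GOE = 0.5, CTR = 0.6),
                  background_ch4 = 0, background_co2 = 0)
  sim <- simulate_microcosm(fer_spec, p, noise = FALSE)
  s <- sim$series
  consumed_g <- sum(p$acetate_pulses$amount) - s$acetate[nrow(s)]
  expect_equal(s$fe2[nrow(s)] - s$fe2[1], 8 * consumed_g)
  expect_equal(sim$truth$fe2_formed_umol,
               8 * sim$truth$acetate_consumed_umol)
  expect_equal(s$ch4_total, rep(0, nrow(s)))
  expect_equal(s$co2_total, 2 * fer_spec$soil_dry_mass *
                 (cumsum(c(0, diff(s$time_days))) * 0 +
                    (vapply(s$time_days, function(t)
                      sum(p$acetate_pulses$amount[p$acetate_pulses$day <= t]),
                      numeric(1)) - s$acetate)))
  expect_equal(unique(s$total_fe), p$total_fe[["FER"]])
})

test_that("closed loop: the electron balance recovers the configured f_fe", {
  p <- sim_params(f_fe = c(FER = 0.74, GOE = 0.22, CTR = 0.08))
  sim <- simulate_microcosm(fer_spec, p, noise = FALSE)
  eb <- estimate_electron_partition(sim$series, sim$spec, p$acetate_pulses)
  expect_equal(eb$percent_to_fe, 74, tolerance = 1e-9)
  expect_equal(eb$percent_reported, 74)
})

test_that("gas atom percentages mix substrate label with background", {
  p <- sim_params(background_ch4 = 0, background_co2 = 0)
  lab <- simulate_microcosm(fer_spec, p, noise = FALSE)$series
  expect_equal(lab$atom13_ch4[nrow(lab)], 99)  # pure substrate carbon
  unl <- simulate_microcosm(microcosm_spec("NF", "FER", "C12"), p,
                            noise = FALSE)$series
  expect_equal(unl$atom13_ch4[nrow(unl)], 1.1)
  # with background the mixture lies strictly between
  pb <- sim_params(background_ch4 = 2)
  mid <- simulate_microcosm(fer_spec, pb, noise = FALSE)$series
  a <- mid$atom13_ch4[nrow(mid)]
  expect_true(a > 1.1 && a < 99)
})

test_that("carbon conservation: a large assimilated pool gives table-like recoveries", {
  # 70% of consumed acetate assimilated -> gas+dissolved recovery ~30%
  p <- sim_params(f_fe = c(FER = 0.12, GOE = 0.22, CTR = 0.08),
                  f_meth = c(FER = 0.18, GOE = 0.5, CTR = 0.6),
                  background_ch4 = 0, background_co2 = 0)
  sim <- simulate_microcosm(fer_spec, p, noise = FALSE)
  s <- sim$series
  n <- nrow(s)
  c13_ch4 <- labeled_gas_amount(s$ch4_total[n], s$atom13_ch4[n])
  c13_co2 <- labeled_gas_amount(s$co2_total[n], s$atom13_co2[n])
  added13 <- 2 * sim$truth$acetate_added_umol * 99 / 100  # 2 C per acetate
  rec <- c13_recovery(c13_ch4, c13_co2, 0, added13)
  expect_gt(rec, 27)
  expect_lt(rec, 36)
  expect_equal(sim$truth$f_assimilated, 0.7)
})

test_that("identical seeds give byte-identical series, different seeds differ", {
  a <- simulate_microcosm(fer_spec, sim_params(seed = 42))
  b <- simulate_microcosm(fer_spec, sim_params(seed = 42))
  expect_identical(a$series, b$series)
  c <- simulate_microcosm(fer_spec, sim_params(seed = 43))
  expect_false(identical(a$series, c$series))
})

test_that("different seeds are statistically indistinguishable", {
  est <- function(s) {
    sim <- simulate_microcosm(fer_spec, sim_params(seed = s))
    estimate_electron_partition(sim$series, sim$spec)$percent_to_fe
  }
  batch1 <- vapply(1:50, est, numeric(1))
  batch2 <- vapply(51:100, est, numeric(1))
  expect_gt(suppressWarnings(ks.test(batch1, batch2)$p.value), 0.01)
})

test_that("pulse schedules outside the horizon are rejected", {
  p <- sim_params(acetate_pulses = data.frame(day = c(0, 6), amount = 3.3))
  expect_error(simulate_microcosm(fer_spec, p), "horizon")
})

test_that("gradient simulation places mass per the Gaussian band integrals", {
  p <- sim_params()
  g0 <- simulate_gradient(p, "C12", noise = FALSE)
  g1 <- simulate_gradient(p, "C13", noise = FALSE)
  # no shift without label: C12 bacterial profile equals the archaeal one
  expect_equal(g0$Bacteria$copies, g0$Archaea$copies)
  expect_equal(g0$truth$label_shift_bacteria, 0)
  # argmax of the unlabeled profile sits at the configured light band
  nb <- normalize_profile(g0$Bacteria)
  expect_equal(nb$bd[which.max(nb$copies)], 1.7815385, tolerance = 1e-4)
  # heavy-window mass of the shifted profile matches the pnorm oracle
  w <- density_windows()
  cls <- classify_fraction(g1$Bacteria$bd, w)
  heavy <- sum(g1$Bacteria$copies[cls == "heavy"]) /
    sum(g1$Bacteria$copies)
  oracle <- g1$truth$expected_heavy_mass_bacteria
  expect_equal(heavy, oracle, tolerance = 0.06)  # grid discretisation
  # archaeal profile never shifts under 13C
  expect_equal(g1$Archaea$copies, g0$Archaea$copies)
})

test_that("labeling evidence closes the loop on the configured shift", {
  g1 <- simulate_gradient(sim_params(seed = 5), "C13")
  g0 <- simulate_gradient(sim_params(seed = 6), "C12")
  ev <- labeling_evidence(g1$Bacteria, g0$Bacteria)
  expect_true(ev$shifted)
  expect_equal(ev$difference, g1$truth$expected_heavy_mass_bacteria -
                 g0$truth$expected_heavy_mass_bacteria, tolerance = 0.15)
  expect_false(labeling_evidence(g1$Archaea, g0$Archaea)$shifted)
})

test_that("taxon tables hit the configured depth and proportions", {
  tt <- simulate_taxon_table(sim_params(seed = 7))
  expect_true(all(rowSums(tt$counts) == 3990))
  expect_equal(nrow(tt$counts), 18)  # 3 amendments x 2 isotopes x 3 fractions
  expect_true(all(tt$counts >= 0))
  # neutral enrichment: labeled and unlabeled expected proportions equal
  p <- sim_params(seed = 8)
  p$taxa$enrichment <- list()
  tn <- simulate_taxon_table(p)
  expect_equal(tn$truth$proportions[["FER_C13"]],
               tn$truth$proportions[["FER_C12"]])
  expect_error(simulate_taxon_table({
    q <- sim_params()
    q$taxa$depth <- 0
    q
  }), "positive")
})

test_that("configured enrichment is recovered as an observed fold change", {
  p <- sim_params(seed = 9)
  p$taxa$enrichment$FER["Geobacter"] <- 8.2
  tt <- simulate_taxon_table(p)
  rel <- relative_abundance(tt$counts)
  md <- tt$metadata
  fer <- mean(rel[md$amendment == "FER" & md$isotope == "C13", "Geobacter"])
  ctr <- mean(rel[md$amendment == "CTR" & md$isotope == "C13", "Geobacter"])
  # binomial SE bound at depth 3990 x 3 fractions
  expect_equal(fold_change(fer, ctr), 8.2, tolerance = 0.2)
})
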