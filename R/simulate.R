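#' Simulation parameters with study-like defaults
#'
#' All knobs of the synthetic-data generator, set to emulate a 4-day
#' anoxic paddy-soil slurry incubation with 13C-acetate: three acetate
#' pulses of 3.3 umol g-1 (days 0, 1.5 and 3), first-order acetate
#' consumption (fast under ferrihydrite, where the substrate is nearly
#' exhausted between pulses), a fixed partition of consumed acetate
#' between dissimilatory Fe(III) reduction (`f_fe`, 8 Fe(II) + 2 CO2 per
#' acetate) and acetoclastic methanogenesis (`f_meth`, 1 CH4 + 1 CO2 per
#' acetate), with the remainder assimilated into biomass.  Substrate is
#' 99 atom% 13C against a 1.1 atom% natural-abundance background.
#'
#' Gradient defaults place the unlabeled rRNA band at 1.782 g ml-1 and
#' the labeled band near 1.7965 g ml-1 on a 14-fraction grid spanning
#' 1.77-1.82 g ml-1, with multiplicative lognormal qPCR noise.  Taxon
#' defaults give Geobacter a 2.4% baseline with a 13-fold ferrihydrite
#' enrichment, sampled multinomially at a depth of 3990 reads per sample
#' (the rarefaction depth convention for these libraries).
#'
#' Enrichment factors scale a genus's relative abundance directly; the
#' unassigned "Other" pool absorbs the compensating change, so a
#' configured 13-fold enrichment is recovered as a 13-fold observed
#' fold change (up to sampling error).
#'
#' @param acetate_pulses data.frame with columns `day` and `amount`
#'   (umol g-1 dry soil).
#' @param rate First-order acetate consumption rate per amendment, day-1.
#' @param f_fe,f_meth Named per-amendment proportions of consumed acetate
#'   routed to Fe(III) reduction and to acetoclastic methanogenesis;
#'   `f_fe + f_meth <= 1` elementwise.
#' @param fe2_initial,total_fe Initial Fe(II) and (constant) total
#'   extractable Fe per amendment, umol g-1.
#' @param ph Slurry pH per amendment.
#' @param atom13_substrate,atom13_natural 13C atom percent of the labeled
#'   substrate and of natural-abundance carbon.
#' @param background_ch4,background_co2 Background gas production from
#'   soil organic matter, umol per vial per day, at natural abundance.
#' @param noise Named list of Gaussian measurement s.d. per analyte
#'   (`fe2`, `total_fe`, `acetate` in umol g-1; `gas` in umol; `atom13`
#'   in atom %; `ph` in pH units).
#' @param gradient Named list: `n_fractions`, `bd_range`, `light_center`,
#'   `light_sd`, `heavy_center`, `heavy_sd`, `label_shift` (proportion of
#'   bacterial signal moved to the heavy band under 13C), `total_copies`,
#'   `qpcr_sdlog` (lognormal s.d. per fraction).
#' @param taxa Named list: `baseline` (named genus proportions summing to
#'   <= 1; remainder becomes "Other"), `enrichment` (per-amendment named
#'   fold factors applied under the 13C isotope), `depth` (reads per
#'   sample).
#' @param seed Optional integer seed; when given, recorded in every
#'   ground-truth record and used for all randomness.
#' @return An object of class `sim_params`.
#' @examples
#' p <- sim_params(seed = 1)
#' p$taxa$depth
#' @export
sim_params <- function(acetate_pulses = data.frame(day = c(0, 1.5, 3),
                                                   amount = 3.3),
                       rate = c(FER = 2.0, GOE = 1.0, CTR = 1.0),
                       f_fe = c(FER = 0.75, GOE = 0.22, CTR = 0.08),
                       f_meth = c(FER = 0.20, GOE = 0.50, CTR = 0.60),
                       fe2_initial = c(FER = 75, GOE = 52, CTR = 55),
                       total_fe = c(FER = 155, GOE = 75, CTR = 63),
                       ph = c(FER = 7.7, GOE = 7.7, CTR = 7.6),
                       atom13_substrate = 99, atom13_natural = 1.1,
                       background_ch4 = 0.5, background_co2 = 0.5,
                       noise = list(fe2 = 1.5, total_fe = 1.5,
                                    acetate = 0.15, gas = 0.3,
                                    atom13 = 1.0, ph = 0.03),
                       gradient = list(n_fractions = 14,
                                       bd_range = c(1.770, 1.820),
                                       light_center = 1.782,
                                       light_sd = 0.004,
                                       heavy_center = 1.7965,
                                       heavy_sd = 0.0045,
                                       label_shift = 0.6,
                                       total_copies = 1e8,
                                       qpcr_sdlog = 0.2),
                       taxa = list(
                         baseline = c(Geobacter = 0.024,
                                      Dechloromonas = 0.020,
                                      Clostridium = 0.030,
                                      Pseudomonas = 0.015,
                                      Solibacillus = 0.010,
                                      Bacillus = 0.020),
                         enrichment = list(
                           FER = c(Geobacter = 13, Dechloromonas = 7,
                                   Clostridium = 2.5, Bacillus = 2,
                                   Solibacillus = 5),
                           GOE = c(Geobacter = 4.7, Clostridium = 1.7,
                                   Pseudomonas = 3.1)),
                         depth = 3990),
                       seed = NULL) {
  amd <- c("FER", "GOE", "CTR")
  for (nm in c("rate", "f_fe", "f_meth", "fe2_initial", "total_fe", "ph")) {
    v <- get(nm)
    if (!all(amd %in% names(v))) {
      stop("`", nm, "` must be named for FER, GOE and CTR", call. = FALSE)
    }
  }
  if (any(rate <= 0)) stop("consumption rates must be positive", call. = FALSE)
  if (any(f_fe < 0 | f_fe > 1) || any(f_meth < 0 | f_meth > 1)) {
    stop("f_fe and f_meth must lie in [0, 1]", call. = FALSE)
  }
  if (any(f_fe[amd] + f_meth[amd] > 1 + 1e-12)) {
    stop("f_fe + f_meth must not exceed 1 for any amendment", call. = FALSE)
  }
  if (any(gradient$label_shift < 0 | gradient$label_shift > 1)) {
    stop("label_shift must lie in [0, 1]", call. = FALSE)
  }
  if (sum(taxa$baseline) > 1) {
    stop("baseline genus proportions must sum to at most 1", call. = FALSE)
  }
  if (taxa$depth <= 0) stop("sequencing depth must be positive", call. = FALSE)
  structure(list(acetate_pulses = acetate_pulses, rate = rate, f_fe = f_fe,
                 f_meth = f_meth, fe2_initial = fe2_initial,
                 total_fe = total_fe, ph = ph,
                 atom13_substrate = atom13_substrate,
                 atom13_natural = atom13_natural,
                 background_ch4 = background_ch4,
                 background_co2 = background_co2,
                 noise = noise, gradient = gradient, taxa = taxa,
                 seed = seed),
            class = "sim_params")
}

.maybe_seed <- function(params) {
  if (!is.null(params$seed)) set.seed(params$seed)
  invisible(params$seed)
}

# Residual acetate concentration (umol g-1) at times `t` under first-order
# decay between pulses.
.acetate_residual <- function(t, pulses, k) {
  vapply(t, function(ti) {
    past <- pulses$day <= ti
    sum(pulses$amount[past] * exp(-k * (ti - pulses$day[past])))
  }, numeric(1))
}

#' Simulate the biogeochemical time course of one microcosm
#'
#' Generates Fe(II), total Fe, acetate, cumulative headspace CH4 and CO2
#' and their 13C atom percentages over a sampling schedule, from the
#' configured acetate kinetics and pathway partition.  Noiseless
#' stoichiometry: cumulative Fe(II) formation equals `8 * f_fe` per unit
#' acetate consumed, CH4 equals `f_meth` per acetate, CO2 equals
#' `2 * f_fe + f_meth` per acetate plus background mineralisation, and
#' total extractable Fe stays constant.  Gas atom percentages mix the
#' substrate label with the natural-abundance background.  Gaussian
#' measurement noise is added last (Fe(II) is then clipped into
#' `[0, total Fe]` and atom percentages into `[0, 100]` so the series
#' stays physically valid).
#'
#' @param spec A [microcosm_spec()].
#' @param params A [sim_params()].
#' @param times Sampling days; must cover every pulse day.
#' @param noise Add measurement noise? Set `FALSE` for exact
#'   stoichiometric output.
#' @return A list of class `microcosm_sim` with elements `series` (a
#'   data.frame: `time_days`, `fe2`, `total_fe`, `acetate` in umol g-1,
#'   `ch4_total`, `co2_total` in umol per vial, `atom13_ch4`,
#'   `atom13_co2` in percent, `ph`) and `truth` (realized pathway
#'   partition, consumed acetate, Fe(II) formed, electron production and
#'   percent-to-Fe per vial, plus the seed).
#' @examples
#' sim <- simulate_microcosm(microcosm_spec("NF", "FER", "C13"),
#'                           sim_params(seed = 1))
#' sim$truth$percent_to_fe  # 75
#' @export
simulate_microcosm <- function(spec, params = sim_params(),
                               times = c(0, 0.5, 1, 1.5, 2, 3, 4),
                               noise = TRUE) {
  stopifnot(inherits(spec, "microcosm_spec"), inherits(params, "sim_params"))
  .maybe_seed(params)
  pulses <- params$acetate_pulses
  if (any(pulses$day < min(times) | pulses$day > max(times))) {
    stop("acetate pulse schedule lies outside the simulation horizon",
         call. = FALSE)
  }
  a <- spec$amendment
  k <- params$rate[[a]]
  f_fe <- params$f_fe[[a]]
  f_meth <- params$f_meth[[a]]
  dry <- spec$soil_dry_mass

  residual <- .acetate_residual(times, pulses, k)
  added <- vapply(times, function(ti) sum(pulses$amount[pulses$day <= ti]),
                  numeric(1))
  consumed <- added - residual                      # umol g-1, cumulative

  fe2 <- params$fe2_initial[[a]] + 8 * f_fe * consumed
  total_fe <- rep(params$total_fe[[a]], length(times))

  ch4_acet <- dry * f_meth * consumed               # umol per vial
  co2_acet <- dry * (2 * f_fe + f_meth) * consumed
  ch4_bg <- params$background_ch4 * times
  co2_bg <- params$background_co2 * times
  ch4_total <- ch4_acet + ch4_bg
  co2_total <- co2_acet + co2_bg

  s_atom <- if (spec$isotope == "C13") params$atom13_substrate else
    params$atom13_natural
  nat <- params$atom13_natural
  atom_mix <- function(acet, bg) {
    tot <- acet + bg
    ifelse(tot > 0, (s_atom * acet + nat * bg) / tot, nat)
  }
  atom13_ch4 <- atom_mix(ch4_acet, ch4_bg)
  atom13_co2 <- atom_mix(co2_acet, co2_bg)
  ph <- rep(params$ph[[a]], length(times))

  if (noise) {
    ns <- params$noise
    total_fe <- total_fe + stats::rnorm(length(times), 0, ns$total_fe)
    fe2 <- fe2 + stats::rnorm(length(times), 0, ns$fe2)
    fe2 <- pmin(pmax(fe2, 0), total_fe)
    residual <- pmax(residual + stats::rnorm(length(times), 0, ns$acetate), 0)
    ch4_total <- pmax(ch4_total + stats::rnorm(length(times), 0, ns$gas), 0)
    co2_total <- pmax(co2_total + stats::rnorm(length(times), 0, ns$gas), 0)
    atom13_ch4 <- pmin(pmax(
      atom13_ch4 + stats::rnorm(length(times), 0, ns$atom13), 0), 100)
    atom13_co2 <- pmin(pmax(
      atom13_co2 + stats::rnorm(length(times), 0, ns$atom13), 0), 100)
    ph <- ph + stats::rnorm(length(times), 0, ns$ph)
  }

  consumed_vial <- dry * consumed[length(times)]
  fe2_formed_vial <- dry * 8 * f_fe * consumed[length(times)]
  truth <- list(
    f_fe = f_fe, f_meth = f_meth, f_assimilated = 1 - f_fe - f_meth,
    acetate_added_umol = dry * sum(pulses$amount),
    acetate_consumed_umol = consumed_vial,
    fe2_formed_umol = fe2_formed_vial,
    e_production = 8 * consumed_vial,
    percent_to_fe = 100 * f_fe,
    ch4_total_umol = ch4_acet[length(times)] + ch4_bg[length(times)],
    co2_total_umol = co2_acet[length(times)] + co2_bg[length(times)],
    seed = params$seed
  )
  structure(
    list(series = data.frame(time_days = times, fe2 = fe2,
                             total_fe = total_fe, acetate = residual,
                             ch4_total = ch4_total, co2_total = co2_total,
                             atom13_ch4 = atom13_ch4,
                             atom13_co2 = atom13_co2, ph = ph),
         spec = spec, truth = truth),
    class = "microcosm_sim"
  )
}

#' Estimate the electron partition from a measured time course
#'
#' Recovers the percentage of acetate-derived electrons flowing into
#' Fe(III) reduction from a (possibly noisy) biogeochemical series: the
#' acetate consumed is the total dosed minus the final residual, Fe(II)
#' formed is the first-to-last concentration increase scaled to the vial,
#' and the partition follows [electron_balance()].
#'
#' @param series A data.frame like the `series` of [simulate_microcosm()]
#'   (columns `fe2`, `acetate`).
#' @param spec The matching [microcosm_spec()] (for the dry mass).
#' @param pulses The acetate dosing schedule (data.frame `day`, `amount`
#'   in umol g-1).
#' @return An [electron_balance()] object.
#' @examples
#' sim <- simulate_microcosm(microcosm_spec("NF", "FER", "C13"),
#'                           sim_params(seed = 7))
#' estimate_electron_partition(sim$series, sim$spec)$percent_to_fe
#' @export
estimate_electron_partition <- function(series, spec,
                                        pulses = data.frame(
                                          day = c(0, 1.5, 3), amount = 3.3)) {
  n <- nrow(series)
  consumed_g <- sum(pulses$amount) - series$acetate[n]
  consumed_vial <- spec$soil_dry_mass * consumed_g
  fe2_formed_vial <- spec$soil_dry_mass * (series$fe2[n] - series$fe2[1])
  electron_balance(max(fe2_formed_vial, 0),
                   acetate_electron_yield(max(consumed_vial, 0)))
}

#' Simulate a pair of density-gradient profiles
#'
#' Builds bacterial and archaeal gradient profiles as Gaussian band
#' mixtures on a descending-density fraction grid.  Under the 13C
#' isotope, a proportion `label_shift` of the bacterial signal moves
#' from the light band to the heavy band; the archaeal profile never
#' shifts (acetoclastic methanogens turn over carbon without detectable
#' rRNA labeling on this time scale in these soils).  Per-fraction
#' multiplicative lognormal noise emulates qPCR variability.
#'
#' @param params A [sim_params()] (the `gradient` element is used).
#' @param isotope "C13" or "C12".
#' @param treatment Optional label carried on the profiles.
#' @param noise Add lognormal qPCR noise?
#' @return A list with elements `Bacteria` and `Archaea`
#'   ([gradient_profile()]s) and `truth` (the applied shift per domain
#'   and the expected heavy-window mass fraction of the bacterial
#'   profile, from the Gaussian band integrals).
#' @examples
#' g <- simulate_gradient(sim_params(seed = 2), "C13")
#' g$truth$label_shift_bacteria  # 0.6
#' @export
simulate_gradient <- function(params = sim_params(), isotope = c("C13", "C12"),
                              treatment = NA_character_, noise = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  isotope <- match.arg(isotope)
  .maybe_seed(params)
  g <- params$gradient
  bd <- seq(g$bd_range[2], g$bd_range[1], length.out = g$n_fractions)
  shift_b <- if (isotope == "C13") g$label_shift else 0

  band_mix <- function(shift) {
    w <- (1 - shift) * stats::dnorm(bd, g$light_center, g$light_sd) +
      shift * stats::dnorm(bd, g$heavy_center, g$heavy_sd)
    g$total_copies * w / sum(w)
  }
  make_profile <- function(shift, domain) {
    copies <- band_mix(shift)
    if (noise) {
      copies <- copies * stats::rlnorm(length(copies), 0, g$qpcr_sdlog)
    }
    gradient_profile(seq_along(bd), bd, copies, domain = domain,
                     treatment = treatment)
  }
  # expected heavy-window mass of the bacterial mixture (band integrals)
  win <- density_windows()
  band_frac <- function(center, sd) {
    stats::pnorm(win$heavy_hi, center, sd) - stats::pnorm(win$heavy_lo, center, sd)
  }
  expected_heavy <- (1 - shift_b) * band_frac(g$light_center, g$light_sd) +
    shift_b * band_frac(g$heavy_center, g$heavy_sd)

  list(Bacteria = make_profile(shift_b, "Bacteria"),
       Archaea = make_profile(0, "Archaea"),
       truth = list(label_shift_bacteria = shift_b,
                    label_shift_archaea = 0,
                    expected_heavy_mass_bacteria = expected_heavy,
                    seed = params$seed))
}

# Treatment-level genus proportions: enrichment factors apply to the 13C
# samples of the named amendment; the "Other" pool absorbs the change.
.treatment_proportions <- function(taxa, amendment, isotope) {
  p <- taxa$baseline
  if (isotope == "C13" && amendment %in% names(taxa$enrichment)) {
    ef <- taxa$enrichment[[amendment]]
    p[names(ef)] <- p[names(ef)] * ef
  }
  other <- 1 - sum(p)
  if (other < 0) {
    stop("enriched genus proportions exceed 1 for amendment ", amendment,
         call. = FALSE)
  }
  c(p, Other = other)
}

#' Simulate genus count tables for all treatments
#'
#' Draws multinomial genus counts for three heavy-fraction samples per
#' soil x amendment x isotope treatment at the configured sequencing
#' depth.  Under the 13C isotope the configured enrichment factors scale
#' the affected genera's proportions (the "Other" pool compensating), so
#' fold changes between amended and control labeled treatments recover
#' the configured factors in expectation.
#'
#' @param params A [sim_params()].
#' @param soil Soil label stamped into the metadata.
#' @param amendments,isotopes Treatments to generate.
#' @param n_fractions Replicate heavy-fraction samples per treatment.
#' @return A list of class `taxon_table_sim`: `counts` (samples x genera
#'   integer matrix), `metadata` (data.frame: `sample`, `soil`,
#'   `amendment`, `isotope`, `fraction`), `truth` (true proportions per
#'   treatment, the enrichment factors and the seed).
#' @examples
#' tt <- simulate_taxon_table(sim_params(seed = 3))
#' dim(tt$counts)
#' @export
simulate_taxon_table <- function(params = sim_params(), soil = "NF",
                                 amendments = c("FER", "GOE", "CTR"),
                                 isotopes = c("C13", "C12"),
                                 n_fractions = 3) {
  stopifnot(inherits(params, "sim_params"))
  .maybe_seed(params)
  taxa <- params$taxa
  depth <- taxa$depth
  if (is.null(depth) || depth <= 0) {
    stop("sequencing depth must be positive", call. = FALSE)
  }
  rows <- list()
  meta <- list()
  truth_p <- list()
  for (a in amendments) {
    for (iso in isotopes) {
      p <- .treatment_proportions(taxa, a, iso)
      truth_p[[paste(a, iso, sep = "_")]] <- p
      for (f in seq_len(n_fractions)) {
        id <- sprintf("%s_%s_%s_F%d", soil, a, iso, f + 4)  # fractions 5-7
        rows[[id]] <- stats::rmultinom(1, depth, p)[, 1]
        meta[[id]] <- data.frame(sample = id, soil = soil, amendment = a,
                                 isotope = iso, fraction = f + 4L,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  counts <- do.call(rbind, rows)
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  structure(
    list(counts = counts, metadata = metadata,
         truth = list(proportions = truth_p,
                      enrichment = taxa$enrichment,
                      depth = depth, seed = params$seed)),
    class = "taxon_table_sim"
  )
}
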