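#' Electron yield of complete acetate oxidation
#'
#' Complete microbial oxidation of acetate to CO2
#' (CH3COO- + 4 H2O -> 2 HCO3- + 9 H+ + 8 e-) releases eight electron
#' equivalents per mole of acetate, so acetate consumption in an anoxic
#' slurry maps directly onto the electrons available to terminal electron
#' acceptors such as Fe(III) oxyhydroxides.
#'
#' @param acetate_umol Acetate consumed, in micromoles. Vectorised.
#' @return Electron production in microequivalents (meq e- in the
#'   micromole-scale bookkeeping used throughout).
#' @examples
#' acetate_electron_yield(24)  # 192
#' @export
acetate_electron_yield <- function(acetate_umol) {
  if (!is.numeric(acetate_umol)) {
    stop("`acetate_umol` must be numeric", call. = FALSE)
  }
  if (any(acetate_umol < 0, na.rm = TRUE)) {
    stop("acetate consumption must be non-negative", call. = FALSE)
  }
  8 * acetate_umol
}

#' Partition acetate-derived electrons to Fe(III) reduction
#'
#' Each mole of Fe(III) reduced to Fe(II) accepts exactly one electron, so
#' the electron flow into iron reduction equals Fe(II) formation and the
#' percentage routed to Fe(III) is `100 * fe2_formed / e_production`.
#' A percentage above 100 is reported as-is (never clamped) with a warning:
#' it implies electron donors other than the added acetate (e.g. soil
#' organic matter) contributed to iron reduction.
#'
#' @param fe2_formed Fe(II) formed over the incubation, micromoles per vial.
#' @param e_production Total electron production, microequivalents; usually
#'   [acetate_electron_yield()] of the acetate consumed, but measured or
#'   tabulated values can be passed directly.
#' @param acetate_consumed Optional acetate consumption (micromoles) used to
#'   derive `e_production` when the latter is missing.
#' @return An object of class `electron_balance`: a list with elements
#'   `fe2_formed`, `acetate_consumed`, `e_production`, `e_to_fe`,
#'   `percent_to_fe` (exact), `percent_reported` (two significant figures,
#'   half away from zero) and `exceeds_production` (logical flag).
#' @examples
#' eb <- electron_balance(142, 192)
#' eb$percent_reported  # 74
#' @export
electron_balance <- function(fe2_formed, e_production = NULL,
                             acetate_consumed = NULL) {
  if (is.null(e_production)) {
    if (is.null(acetate_consumed)) {
      stop("supply `e_production` or `acetate_consumed`", call. = FALSE)
    }
    e_production <- acetate_electron_yield(acetate_consumed)
  }
  if (any(!is.finite(e_production)) || any(e_production <= 0)) {
    stop("electron production must be positive; percentage undefined",
         call. = FALSE)
  }
  if (any(fe2_formed < 0)) {
    stop("Fe(II) formation must be non-negative", call. = FALSE)
  }
  percent <- 100 * fe2_formed / e_production
  exceeds <- percent > 100
  if (any(exceeds)) {
    warning("electron flow to Fe(III) exceeds acetate-derived production; ",
            "additional electron donors implied (value not clamped)",
            call. = FALSE)
  }
  structure(
    list(fe2_formed = fe2_formed,
         acetate_consumed = acetate_consumed,
         e_production = e_production,
         e_to_fe = fe2_formed,
         percent_to_fe = percent,
         percent_reported = signif_away(percent, 2),
         exceeds_production = exceeds),
    class = "electron_balance"
  )
}

#' @export
print.electron_balance <- function(x, ...) {
  cat("Electron balance (acetate -> Fe(III))\n")
  cat(sprintf("  electron production : %s meq e-\n",
              paste(format(x$e_production), collapse = ", ")))
  cat(sprintf("  flowed into Fe(III) : %s meq e-\n",
              paste(format(x$e_to_fe), collapse = ", ")))
  cat(sprintf("  percent to Fe(III)  : %s %%\n",
              paste(format(x$percent_reported), collapse = ", ")))
  if (any(x$exceeds_production)) {
    cat("  note: exceeds 100% -- electron sources beyond acetate implied\n")
  }
  invisible(x)
}

#' Hydroxylamine-reducible Fe(III) by difference
#'
#' Reducible Fe(III) is the difference between total HCl/hydroxylamine
#' extractable iron and ferrozine-measured Fe(II).  Iron is conserved
#' exactly: `fe2 + reducible_fe3 = total_fe`.
#'
#' @param total_fe Total extractable Fe, micromoles per g dry soil.
#' @param fe2 Fe(II), same units. Vectorised with `total_fe`.
#' @param time_days Optional time stamps used to name the offending
#'   measurement when `fe2 > total_fe`.
#' @return Fe(III) in the same units.
#' @examples
#' reducible_fe3(155, 75)  # 80
#' @export
reducible_fe3 <- function(total_fe, fe2, time_days = NULL) {
  if (any(fe2 < 0)) stop("Fe(II) must be non-negative", call. = FALSE)
  bad <- fe2 > total_fe
  if (any(bad)) {
    where <- if (!is.null(time_days)) {
      paste0("day ", paste(time_days[bad], collapse = ", "))
    } else {
      paste0("index ", paste(which(bad), collapse = ", "))
    }
    stop("measurement inconsistency at ", where,
         ": Fe(II) exceeds total extractable Fe", call. = FALSE)
  }
  total_fe - fe2
}

#' Ferrihydrite formula units from an iron amount
#'
#' Ferrihydrite is dosed by iron content but tallied in mineral formula
#' units Fe5HO8.4H2O, i.e. five Fe atoms per unit.
#'
#' @param fe_umol Iron amount, micromoles.
#' @return Formula units of Fe5HO8.4H2O, micromoles.
#' @examples
#' ferrihydrite_formula_units(140)  # 28
#' @export
ferrihydrite_formula_units <- function(fe_umol) {
  if (any(fe_umol < 0)) stop("iron amount must be non-negative", call. = FALSE)
  fe_umol / 5
}

#' 13C-labeled share of a gas pool
#'
#' Converts a total headspace gas amount and its measured 13C atom
#' percentage into the amount of 13C-bearing gas.
#'
#' @param total_gas Total gas, micromoles.
#' @param atom13 13C atom percentage in `[0, 100]`.
#' @return Micromoles of 13C gas.
#' @examples
#' labeled_gas_amount(12.4, 80)  # 9.92
#' @export
labeled_gas_amount <- function(total_gas, atom13) {
  if (any(atom13 < 0 | atom13 > 100)) {
    stop("atom13 must lie in [0, 100]", call. = FALSE)
  }
  if (any(total_gas < 0)) stop("gas amount must be non-negative", call. = FALSE)
  total_gas * atom13 / 100
}

#' 13C recovery from gaseous and dissolved products
#'
#' Total proportion of added 13C recovered as 13CH4 plus gaseous and
#' dissolved 13CO2.  Tables report it to the nearest integer percent
#' (half away from zero).
#'
#' @param gas_13ch4,gas_13co2,dissolved_13co2 Product pools, micromoles 13C.
#' @param c13_added 13C added as labeled substrate, micromoles; must be > 0.
#' @param rounded Report to the nearest integer percent (table convention)?
#' @return Recovery in percent.
#' @examples
#' c13_recovery(7.6, 4.1, 8.0, 60, rounded = TRUE)  # 33
#' @export
c13_recovery <- function(gas_13ch4, gas_13co2, dissolved_13co2, c13_added,
                         rounded = FALSE) {
  if (any(c13_added <= 0)) {
    stop("recovery undefined: no 13C added", call. = FALSE)
  }
  if (any(c(gas_13ch4, gas_13co2, dissolved_13co2) < 0)) {
    stop("product pools must be non-negative", call. = FALSE)
  }
  rec <- 100 * (gas_13ch4 + gas_13co2 + dissolved_13co2) / c13_added
  if (rounded) round_away(rec, 0) else rec
}

#' Suppression of gas production relative to a control
#'
#' Percentage by which a treatment lowered cumulative gas production
#' relative to the unamended control; negative values indicate
#' stimulation and are returned as-is.
#'
#' @param treatment_total Cumulative gas in the treatment, micromoles.
#' @param control_total Cumulative gas in the control, micromoles; > 0.
#' @return Suppression in percent.
#' @examples
#' suppression_percent(6.5, 10)  # 35
#' @export
suppression_percent <- function(treatment_total, control_total) {
  if (any(control_total <= 0)) {
    stop("suppression undefined for a zero control", call. = FALSE)
  }
  100 * (control_total - treatment_total) / control_total
}
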