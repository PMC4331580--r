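# Ideal gas constant, L atm mol^-1 K^-1
.R_GAS <- 0.082057

#' Carbonate-system constants and vial geometry
#'
#' Container for the equilibrium constants and phase volumes needed to
#' partition headspace CO2 into the dissolved inorganic carbon pool
#' (CO2(aq) + HCO3- + CO3^2-).  Defaults are 25 degC freshwater values:
#' Henry constant 0.0339 mol L-1 atm-1, pK1 = 6.35, pK2 = 10.33.  The
#' default liquid volume is the pore-water volume of a 5-ml slurry aliquot
#' (5 ml) and the default headspace is 20 ml (25-ml serum vial minus
#' slurry); all are overridable because slurry composition varies.
#'
#' @param kh Henry's law constant for CO2, mol L-1 atm-1.
#' @param pk1,pk2 First and second acid-dissociation exponents of carbonic
#'   acid (pK1 < pK2).
#' @param temperature Temperature in Kelvin.
#' @param v_liquid Effective liquid (pore-water) volume, litres.
#' @param v_gas Headspace volume, litres.
#' @return An object of class `carbonate_system`.
#' @examples
#' carbonate_system()
#' @export
carbonate_system <- function(kh = 0.0339, pk1 = 6.35, pk2 = 10.33,
                             temperature = 298.15,
                             v_liquid = 0.005, v_gas = 0.020) {
  if (any(c(kh, temperature, v_liquid, v_gas) <= 0)) {
    stop("carbonate-system constants and volumes must be positive",
         call. = FALSE)
  }
  if (pk1 >= pk2) stop("pK1 must be smaller than pK2", call. = FALSE)
  structure(list(kh = kh, pk1 = pk1, pk2 = pk2, temperature = temperature,
                 v_liquid = v_liquid, v_gas = v_gas),
            class = "carbonate_system")
}

#' @export
print.carbonate_system <- function(x, ...) {
  cat(sprintf(
    "Carbonate system: KH = %g M atm-1, pK1 = %g, pK2 = %g, T = %g K\n",
    x$kh, x$pk1, x$pk2, x$temperature))
  cat(sprintf("  volumes: liquid %g L, headspace %g L\n", x$v_liquid, x$v_gas))
  invisible(x)
}

#' Dissolved CO2 pool from a headspace amount and slurry pH
#'
#' Estimates the dissolved inorganic carbon in equilibrium with a measured
#' headspace CO2 amount.  The gas partial pressure follows the ideal gas
#' law, CO2(aq) follows Henry's law, and bicarbonate/carbonate follow the
#' two acid-dissociation equilibria at the measured pH:
#' \deqn{p = n RT / V_g,\quad [CO_2(aq)] = K_H p,\quad
#'       [HCO_3^-] = K_1 [CO_2(aq)]/[H^+],\quad
#'       [CO_3^{2-}] = K_2 [HCO_3^-]/[H^+].}
#' The returned amount is the DIC concentration times the liquid volume.
#' It is strictly increasing in both pH and the gas amount, and
#' homogeneous of degree one in the gas amount.
#'
#' @param gas_co2 Headspace CO2 (or 13CO2), micromoles.
#' @param ph Slurry pH, in (0, 14).
#' @param sys A [carbonate_system()].
#' @return Dissolved CO2 pool, micromoles.
#' @examples
#' dissolved_co2(2.6, 7.7)
#' @export
dissolved_co2 <- function(gas_co2, ph, sys = carbonate_system()) {
  if (!inherits(sys, "carbonate_system")) {
    stop("`sys` must be a carbonate_system()", call. = FALSE)
  }
  if (any(gas_co2 < 0)) stop("gas amount must be non-negative", call. = FALSE)
  if (any(ph <= 0 | ph >= 14)) stop("pH must lie in (0, 14)", call. = FALSE)
  p <- gas_co2 * 1e-6 * .R_GAS * sys$temperature / sys$v_gas  # atm
  h <- 10^(-ph)
  k1 <- 10^(-sys$pk1)
  k2 <- 10^(-sys$pk2)
  co2aq <- sys$kh * p                       # mol L-1
  hco3 <- k1 * co2aq / h
  co3 <- k2 * hco3 / h
  (co2aq + hco3 + co3) * sys$v_liquid * 1e6  # umol
}
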