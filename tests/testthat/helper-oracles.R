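# Independent oracles used across test files.

# Exhaustive one-sided permutation p-value by bitmask enumeration over all
# subsets of the pooled observations (independent of utils::combn).
perm_p_bitmask <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  k <- length(x)
  obs <- mean(x) - mean(y)
  hits <- 0L
  total <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    if (sum(bits) != k) next
    total <- total + 1L
    d <- mean(pooled[bits == 1]) - mean(pooled[bits == 0])
    if (d >= obs - 1e-9) hits <- hits + 1L
  }
  hits / total
}

# Numerical equilibrium solver for the carbonate system: Newton root-solve
# (pracma::fsolve) of the coupled Henry / acid-dissociation equations in
# (CO2(aq), HCO3-, CO3^2-), concentrations in umol L-1.
dic_numeric_oracle <- function(gas_co2, ph, sys) {
  p <- gas_co2 * 1e-6 * 0.082057 * sys$temperature / sys$v_gas
  h <- 10^(-ph)
  k1 <- 10^(-sys$pk1)
  k2 <- 10^(-sys$pk2)
  f <- function(x) {
    c(x[1] - sys$kh * p * 1e6,
      x[2] * h - k1 * x[1],
      x[3] * h - k2 * x[2])
  }
  sol <- pracma::fsolve(f, c(1, 1, 1), tol = 1e-14)$x
  sum(sol) * sys$v_liquid
}

# Two-Gaussian test profile on a descending BD grid.
make_two_band_profile <- function(shift, n = 14, bd_hi = 1.82, bd_lo = 1.77,
                                  light = 1.782, light_sd = 0.004,
                                  heavy = 1.7965, heavy_sd = 0.0045,
                                  domain = "Bacteria") {
  bd <- seq(bd_hi, bd_lo, length.out = n)
  w <- (1 - shift) * dnorm(bd, light, light_sd) +
    shift * dnorm(bd, heavy, heavy_sd)
  gradient_profile(seq_len(n), bd, w, domain = domain)
}
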