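#' Density-gradient rRNA profile
#'
#' One isopycnic (CsTFA) gradient resolved into fractions, with the
#' measured buoyant density (BD, g ml-1) and the RT-qPCR rRNA copy number
#' of each fraction.  Fractions are kept in gradient order (as supplied)
#' and BD must be strictly monotone across them; at least four fractions
#' are required for any band structure to be interpretable.
#'
#' @param fraction Integer fraction indices, gradient order.
#' @param bd Buoyant densities, g ml-1, strictly monotone.
#' @param copies rRNA copies per fraction volume, non-negative.
#' @param domain "Bacteria" or "Archaea".
#' @param treatment Optional label (e.g. "NF_FER_C13") carried in outputs.
#' @return A data.frame of class `gradient_profile` with attributes
#'   `domain`, `treatment` and `normalized`.
#' @examples
#' gradient_profile(1:5, seq(1.81, 1.77, by = -0.01), c(1, 4, 9, 20, 6))
#' @export
gradient_profile <- function(fraction, bd, copies, domain = "Bacteria",
                             treatment = NA_character_) {
  domain <- match.arg(domain, c("Bacteria", "Archaea"))
  n <- length(fraction)
  if (n < 4) stop("a gradient profile needs at least 4 fractions",
                  call. = FALSE)
  if (length(bd) != n || length(copies) != n) {
    stop("fraction, bd and copies must have equal length", call. = FALSE)
  }
  d <- diff(bd)
  if (!(all(d > 0) || all(d < 0))) {
    stop("buoyant density must be strictly monotone across fractions",
         call. = FALSE)
  }
  if (any(copies < 0)) stop("copy numbers must be non-negative",
                            call. = FALSE)
  structure(
    data.frame(fraction = as.integer(fraction), bd = bd, copies = copies),
    class = c("gradient_profile", "data.frame"),
    domain = domain, treatment = treatment, normalized = FALSE
  )
}

#' Normalise a gradient profile to its maximum
#'
#' Rescales each fraction's copy number by the profile maximum, so the
#' best-represented fraction of every treatment plots at 1.  This is the
#' standard display normalisation for density-resolved qPCR profiles; it
#' is idempotent and invariant to rescaling of the raw copy numbers.
#'
#' @param profile A [gradient_profile()].
#' @return The profile with `copies` divided by `max(copies)` and the
#'   `normalized` attribute set.
#' @examples
#' p <- gradient_profile(1:4, c(1.80, 1.79, 1.78, 1.77), c(2, 8, 4, 1))
#' normalize_profile(p)$copies  # 0.25 1.00 0.50 0.125
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "gradient_profile"))
  m <- max(profile$copies)
  if (m <= 0) {
    stop("degenerate profile: all fractions have zero copies", call. = FALSE)
  }
  profile$copies <- profile$copies / m
  attr(profile, "normalized") <- TRUE
  profile
}

#' Buoyant-density windows for light/heavy classification
#'
#' Windows defining where unlabeled ("light") and 13C-labeled ("heavy")
#' rRNA bands sit in a CsTFA gradient, plus the narrower sub-window from
#' which heavy fractions are picked for sequencing.  Defaults follow the
#' band positions typical of rRNA-SIP: light centred at 1.782 g ml-1
#' (half-width 0.004), heavy spanning 1.791-1.806, and a selection window
#' of 1.791-1.801 (the three fractions routinely sequenced).
#'
#' @param light_center Centre of the light band, g ml-1.
#' @param light_halfwidth Half-width of the light window, g ml-1.
#' @param heavy_lo,heavy_hi Bounds of the heavy window, g ml-1.
#' @param select_lo,select_hi Bounds of the sequencing selection window,
#'   nested inside the heavy window.
#' @return An object of class `density_windows`.
#' @examples
#' density_windows()
#' @export
density_windows <- function(light_center = 1.782, light_halfwidth = 0.004,
                            heavy_lo = 1.791, heavy_hi = 1.806,
                            select_lo = 1.791, select_hi = 1.801) {
  if (!(light_center < heavy_lo && heavy_lo <= select_lo &&
        select_lo < select_hi && select_hi <= heavy_hi)) {
    stop("windows must satisfy light_center < heavy_lo <= select_lo < ",
         "select_hi <= heavy_hi", call. = FALSE)
  }
  if (light_halfwidth <= 0) stop("light_halfwidth must be positive",
                                 call. = FALSE)
  structure(list(light_center = light_center,
                 light_halfwidth = light_halfwidth,
                 heavy_lo = heavy_lo, heavy_hi = heavy_hi,
                 select_lo = select_lo, select_hi = select_hi),
            class = "density_windows")
}

#' Classify fractions as light, heavy or other
#'
#' @param bd Buoyant densities, g ml-1. Values outside the plausible
#'   CsTFA range (1.74-1.85) trigger a warning.
#' @param windows A [density_windows()].
#' @return Character vector in `{"light", "heavy", "other"}`.
#' @examples
#' classify_fraction(c(1.795, 1.782, 1.750), density_windows())
#' @export
classify_fraction <- function(bd, windows = density_windows()) {
  stopifnot(inherits(windows, "density_windows"))
  if (any(bd < 1.74 | bd > 1.85)) {
    warning("buoyant density outside the plausible CsTFA range (1.74-1.85)",
            call. = FALSE)
  }
  out <- rep("other", length(bd))
  out[bd >= windows$heavy_lo & bd <= windows$heavy_hi] <- "heavy"
  out[abs(bd - windows$light_center) <= windows$light_halfwidth] <- "light"
  out
}

# Pair fractions of two gradients by nearest buoyant density.
# Returns an index into `other` for each fraction of `ref`, or errors if
# the grids do not overlap within the tolerance.
pair_fractions <- function(ref, other, tol = 0.003) {
  idx <- vapply(ref$bd, function(b) which.min(abs(other$bd - b)), integer(1))
  dist <- abs(other$bd[idx] - ref$bd)
  if (all(dist > tol)) {
    stop("gradient pairing failed: no fractions within ", tol,
         " g ml-1 of each other (non-overlapping BD ranges?)", call. = FALSE)
  }
  ok <- dist <= tol
  idx[!ok] <- NA_integer_
  idx
}

#' Detect a 13C labeling shift between paired gradients
#'
#' Compares the heavy-window mass fraction of a labeled (13C substrate)
#' gradient against its unlabeled (12C) parallel.  Profiles are
#' max-normalised if they are not already; fractions are paired by
#' nearest buoyant density (measured BDs differ slightly between runs,
#' so pairing by index would misalign bands).  The profile is called
#' shifted when the heavy-window mass fraction of the labeled gradient
#' exceeds the unlabeled one by more than `threshold`.
#'
#' @param labeled,unlabeled [gradient_profile()]s for the 13C and 12C
#'   incubations of the same treatment and domain.
#' @param windows A [density_windows()].
#' @param threshold Minimum heavy-mass-fraction difference to call a
#'   shift; default 0.15.
#' @param pair_tol Pairing tolerance in g ml-1.
#' @return An object of class `labeling_evidence`: list with the paired
#'   per-fraction normalised differences, the two heavy mass fractions,
#'   their `difference` and the logical `shifted`.
#' @examples
#' bd <- seq(1.812, 1.772, length.out = 11)
#' light <- exp(-0.5 * ((bd - 1.782) / 0.004)^2)
#' heavy <- exp(-0.5 * ((bd - 1.797) / 0.005)^2)
#' lab <- gradient_profile(1:11, bd, 0.4 * light + 0.6 * heavy)
#' unl <- gradient_profile(1:11, bd, light)
#' labeling_evidence(lab, unl)$shifted  # TRUE
#' @export
labeling_evidence <- function(labeled, unlabeled,
                              windows = density_windows(),
                              threshold = 0.15, pair_tol = 0.003) {
  stopifnot(inherits(labeled, "gradient_profile"),
            inherits(unlabeled, "gradient_profile"))
  if (!isTRUE(attr(labeled, "normalized"))) labeled <- normalize_profile(labeled)
  if (!isTRUE(attr(unlabeled, "normalized"))) unlabeled <- normalize_profile(unlabeled)
  idx <- pair_fractions(labeled, unlabeled, tol = pair_tol)
  diff_fraction <- labeled$copies - unlabeled$copies[idx]

  heavy_mass <- function(p) {
    cls <- classify_fraction(p$bd, windows)
    sum(p$copies[cls == "heavy"]) / sum(p$copies)
  }
  hf_lab <- heavy_mass(labeled)
  hf_unl <- heavy_mass(unlabeled)
  difference <- hf_lab - hf_unl
  structure(
    list(fraction = labeled$fraction, bd = labeled$bd,
         diff_fraction = diff_fraction,
         heavy_mass_fraction_labeled = hf_lab,
         heavy_mass_fraction_unlabeled = hf_unl,
         difference = difference, threshold = threshold,
         shifted = difference > threshold,
         domain = attr(labeled, "domain"),
         treatment = attr(labeled, "treatment")),
    class = "labeling_evidence"
  )
}

#' @export
print.labeling_evidence <- function(x, ...) {
  cat(sprintf("Labeling evidence (%s%s)\n", x$domain,
              if (is.na(x$treatment)) "" else paste0(", ", x$treatment)))
  cat(sprintf("  heavy mass fraction: labeled %.3f, unlabeled %.3f (diff %.3f)\n",
              x$heavy_mass_fraction_labeled, x$heavy_mass_fraction_unlabeled,
              x$difference))
  cat(sprintf("  shifted (threshold %.2f): %s\n", x$threshold, x$shifted))
  invisible(x)
}

#' Select heavy fractions for sequencing
#'
#' Returns, in gradient order, the indices of fractions whose buoyant
#' density lies inside the selection window.  Selection depends only on
#' BD, never on fraction numbering.
#'
#' @param profile A [gradient_profile()].
#' @param windows A [density_windows()].
#' @return Integer vector of fraction indices (possibly empty, with a
#'   warning).
#' @examples
#' p <- gradient_profile(1:6, seq(1.810, 1.780, by = -0.006), rep(1, 6))
#' select_heavy_fractions(p)
#' @export
select_heavy_fractions <- function(profile, windows = density_windows()) {
  stopifnot(inherits(profile, "gradient_profile"),
            inherits(windows, "density_windows"))
  sel <- profile$bd >= windows$select_lo & profile$bd <= windows$select_hi
  if (!any(sel)) {
    warning("no fractions fall inside the selection window [",
            windows$select_lo, ", ", windows$select_hi, "]", call. = FALSE)
    return(integer(0))
  }
  profile$fraction[sel]
}
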