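---
title: "Methods: mass balances and rRNA-SIP analysis for iron-reducing soil communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass balances and rRNA-SIP analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ironSIP)
```

## The experimental system

`ironSIP` analyses anoxic paddy-soil slurry microcosms in which
dissimilatory Fe(III) reduction competes with acetoclastic
methanogenesis for acetate.  Two soils (non-fertilized, `NF`, and
long-term nitrogen-fertilized, `N`) are incubated in sealed serum vials
under three amendments — ferrihydrite (`FER`), goethite (`GOE`) or no
added iron (`CTR`) — with acetate dosed at 3.3 µmol g⁻¹ dry soil at days
0, 1.5 and 3, either ¹³C-labeled (99 atom%) or unlabeled.  The package
covers the downstream quantitative chain: electron and carbon mass
balances from the geochemical time courses, detection of rRNA labeling
in isopycnic CsTFA density gradients, and genus-level enrichment
scoring of amplicon count tables from the heavy gradient fractions.

## Electron balance

Complete oxidation of acetate releases 8 electron equivalents per mole
(CH₃COO⁻ + 4 H₂O → 2 HCO₃⁻ + 9 H⁺ + 8 e⁻), and each Fe(III) → Fe(II)
transition consumes exactly one.  With per-vial acetate consumption
$\Delta A$ (µmol) and Fe(II) formation $\Delta Fe$ (µmol),

$$e^-_{\mathrm{prod}} = 8\,\Delta A, \qquad
  \%\to\mathrm{Fe} = 100\,\frac{\Delta Fe}{e^-_{\mathrm{prod}}}.$$

Percentages above 100 are reported unclamped with a warning: they are
diagnostic of electron donors other than the added acetate (soil
organic matter, ammonium) and clamping would hide that signal.
Reducible Fe(III) is computed by difference (total extractable Fe minus
Fe(II)) so that iron is conserved exactly, and ferrihydrite doses are
converted to mineral formula units at five Fe per Fe₅HO₈·4H₂O.

Reported percentages follow the table convention of the source
measurements: two significant figures, rounding half away from zero
(`signif_away()`); ¹³C recoveries round to the nearest integer percent.
R's default banker's rounding cannot reproduce such tables, which is
why the package carries its own rounding policy.

Two quirks of the bundled reference measurements are handled
deliberately.  The printed electron-production values were evidently
derived from unrounded acetate measurements, so four of the six columns
differ slightly from 8× the printed acetate; the printed values are
therefore treated as authoritative inputs when reproducing the
percentages.  Similarly, one recovery column (FER/NF) prints 27% while
its printed components sum to 26% at integer rounding; the recomputed
value is reported and the discrepancy documented rather than patched.

## Carbonate speciation

Dissolved ¹³CO₂ is estimated from the headspace amount and the slurry
pH.  The partial pressure follows the ideal gas law
($R = 0.082057$ L atm mol⁻¹ K⁻¹), CO₂(aq) follows Henry's law, and
bicarbonate and carbonate follow the two acid-dissociation equilibria:

$$[\mathrm{CO_2(aq)}] = K_H p,\quad
  [\mathrm{HCO_3^-}] = \frac{K_1 [\mathrm{CO_2(aq)}]}{[\mathrm{H^+}]},\quad
  [\mathrm{CO_3^{2-}}] = \frac{K_2 [\mathrm{HCO_3^-}]}{[\mathrm{H^+}]}.$$

Defaults are 25 °C freshwater constants ($K_H = 0.0339$ mol L⁻¹ atm⁻¹,
p$K_1 = 6.35$, p$K_2 = 10.33$), an effective liquid volume of 5 ml
(the pore water of a 5-ml slurry aliquot) and a 20-ml headspace (25-ml
vial minus slurry).  All are configurable because slurry ionic strength
and pore-water volume vary between studies and the source measurements
do not state the constants used; consequently the closed-form
speciation is validated against an independent numerical equilibrium
solver (Newton root-solve of the coupled system) to six significant
figures in the test suite, not against the reference dissolved-CO₂
column.  The function is strictly increasing in pH and homogeneous of
degree one in the gas amount — both properties are tested.

A per-vial dry mass is needed to convert per-gram concentrations to
vial totals.  It is rarely reported; the default of 3.0 g is derived
from the internal consistency of per-vial and per-gram Fe(II) figures
(~142 µmol per vial against ~47 µmol g⁻¹) and is flagged in every run
log so the assumption is auditable.

## Density-gradient analysis

Gradient profiles (fraction index, buoyant density, rRNA copies from
RT-qPCR) are normalised to the profile maximum — the standard display
convention, idempotent and scale-invariant, which removes run-to-run
differences in extraction yield while preserving band shape.
Fractions are classified against configurable density windows: light
band at 1.782 ± 0.004 g ml⁻¹, heavy window 1.791–1.806 g ml⁻¹,
sequencing selection window 1.791–1.801 g ml⁻¹.  These defaults match
where unlabeled and ¹³C-labeled rRNA band in CsTFA gradients.

Labeling evidence compares the heavy-window *mass fraction* (share of
total normalised signal inside the heavy window) between a labeled
gradient and its unlabeled parallel.  Fractions are paired by nearest
buoyant density (tolerance 0.003 g ml⁻¹) rather than by index, because
measured densities drift between centrifuge runs and index pairing
would misalign bands.  A shift is called when the difference exceeds
0.15.  That threshold is a package decision — the qualitative
description it operationalises ("considerably higher in the heavy
fractions") carries no number — chosen so that two-band profiles of
the kind the generator produces classify as a practitioner would read
them: under the default noise model the null difference has a spread
far below 0.15 while a 0.6 shift produces differences near 0.5, so the
operating point is insensitive to the exact value over a wide range.
The false-positive and detection rates at this threshold are measured
in the acceptance tests rather than asserted.

Heavy-fraction selection returns the fractions whose density lies in
the selection window, by density only, so it is invariant to how
fractions are numbered.

## Enrichment screening

Relative abundances are percentages of classified sequences per sample
(rows sum to 100).  A genus is flagged as a putative ¹³C assimilator
when its abundance in the three heavy-fraction samples of a labeled
treatment exceeds the unlabeled parallel by an exact one-sided
permutation test on the difference of means at α = 0.05.  With three
replicates per side the permutation distribution has exactly
$\binom{6}{3} = 20$ points, so the smallest attainable p-value is 0.05
and the test is exact by enumeration; a t-test was rejected because
normality is untestable at n = 3, and the enumeration is cheap.  No
multiple-testing correction is applied by default, mirroring the
per-genus convention of such screens; Benjamini–Hochberg adjustment is
available as an option.  Effect sizes are reported two ways — net
proportional change (percentage points versus the unamended control)
and fold change — which satisfy
`net_change = mean_control * (fold_change - 1)`.  Zero-control fold
changes use a flagged pseudo-count (half the minimum nonzero relative
abundance) only on request.

The putative iron-reducer filter is a curated genus list (11 genera
spanning *Proteobacteria*, *Acidobacteria* and *Firmicutes*) standing
in for the functional marker gene that does not exist for
dissimilatory iron reduction; it restricts a count table by column
intersection and never alters counts.

## The synthetic-data generator

The generator exists so every stage can be tested closed-loop against
recorded ground truth, without sequence data.  It emulates:

* **Acetate kinetics** — first-order decay between pulses, rate 2.0
  d⁻¹ under FER (near-complete consumption between pulses, as observed
  in ferrihydrite-amended slurries) and 1.0 d⁻¹ otherwise.  Rates are
  free parameters, not mechanistic claims.
* **Pathway partition** — fractions `f_fe` (8 Fe(II) + 2 CO₂ per
  acetate) and `f_meth` (1 CH₄ + 1 CO₂), with `f_fe + f_meth ≤ 1` and
  the remainder assimilated into biomass.  Defaults (FER 0.75/0.20,
  GOE 0.22/0.50, CTR 0.08/0.60) place the electron partition in the
  observed per-amendment ranges.  Note an inherent tension in the
  source system: an electron partition of ~0.75 implies most acetate
  carbon leaves as CO₂, which is not compatible with the low (~30%)
  gas-phase ¹³C recoveries under the same strict stoichiometry.  The
  generator keeps the stoichiometric constraint; recovery-like
  scenarios are produced by choosing a large assimilated pool
  (`f_fe + f_meth ≈ 0.3`), and the tests exercise both régimes
  explicitly rather than pretending one parameter set reproduces both
  tables.
* **Isotopes** — substrate at 99 atom% ¹³C (or 1.1 atom% for the
  unlabeled parallel) mixed with natural-abundance background gas
  production; measured atom percentages are the pool-weighted mixture.
* **Gradients** — Gaussian bands on a 14-fraction grid spanning
  1.77–1.82 g ml⁻¹ (descending density, as gradients are collected),
  light band at 1.782, heavy at 1.7965; under ¹³C a proportion
  `label_shift` (default 0.6) of the bacterial signal moves to the
  heavy band; archaeal profiles never shift.  Multiplicative lognormal
  noise (σ(log) = 0.2) emulates qPCR variability.
* **Count tables** — multinomial draws at depth 3990 per sample (the
  rarefaction convention for these libraries), three heavy-fraction
  samples per treatment.  Enrichment factors scale the affected
  genus's relative abundance directly and the unassigned "Other" pool
  absorbs the complement, so a configured 13-fold enrichment is
  recovered as a 13-fold observed fold change in expectation — the
  property the closed-loop tests rely on.

Gaussian measurement noise is added last (σ: Fe 1.5 µmol g⁻¹, acetate
0.15 µmol g⁻¹, gases 0.3 µmol, atom% 1.0, pH 0.03), then clipped to
physical ranges (Fe(II) ≤ total Fe, atom% ∈ [0, 100]).  All randomness
flows through one seed recorded in every ground-truth record;
identical seeds give byte-identical output.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: mineralogical transformation of the iron
phases, pH drift, isotopic fractionation, cross-feeding of ¹³C through
intermediate pools, compositional correlation structure beyond the
multinomial, chimeras/classification error in the count tables, and
gradient artefacts (smiles, wall effects) beyond Gaussian bands with
lognormal noise.

## Problem sizes and numerical choices

The stochastic checks use 50 seeds for the closed-loop electron and
enrichment recoveries, 200 replicate gradient pairs for
detection/false-positive rates, and 1000 null genera for the
permutation-test size — sizes chosen so that Monte-Carlo standard
errors are several times smaller than the tolerances being checked
while the whole suite runs in seconds.  Degenerate inputs fail loudly:
all-zero gradient profiles, zero electron production, zero added ¹³C,
zero control totals and non-overlapping gradient grids are errors, not
NaNs.  Floating-point ties in the permutation statistic are absorbed
with a 10⁻⁹ tolerance so that identical treatments give p = 1 exactly.

## Limitations

The mass balances treat the vial as two well-mixed phases at
equilibrium; kinetic limitation of CO₂ dissolution is ignored.  The
electron balance attributes all Fe(II) formation to acetate-derived
electrons, which the over-100% warning only partially mitigates.  The
screen's unit of replication is the gradient fraction, not the
biological replicate, so its p-values describe fraction-level
reproducibility.  The iron-reducer list is a literature snapshot and
will age as new taxa are characterised.
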