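# ironSIP

Quantitative analysis of ¹³C-acetate RNA stable-isotope-probing (SIP)
microcosm experiments on iron-reducing soil communities.

Flooded paddy soils host intense dissimilatory Fe(III) reduction:
bacteria such as *Geobacter* respire ferric oxyhydroxides while
oxidising acetate, competing with acetoclastic methanogens for the same
substrate.  Because no functional marker gene covers iron reducers,
RNA-SIP is the tool of choice — organisms that assimilate ¹³C-acetate
produce denser rRNA, separable on a CsTFA buoyant-density gradient and
identifiable by sequencing the "heavy" fractions.  `ironSIP`
implements the analysis chain such experiments need, for
biogeochemists and microbial ecologists working from tabular
measurements (no raw reads required):

- **Electron balance** — complete acetate oxidation yields 8 e⁻ per
  mole; each Fe(III)→Fe(II) accepts one, so the share of electrons
  routed to iron reduction is `100 · ΔFe(II) / (8 · Δacetate)`.
- **¹³C mass balance** — labeled CH₄ and CO₂ from headspace totals and
  atom-percent data, dissolved CO₂ from Henry's law plus the two
  carbonate acid-dissociation equilibria at the slurry pH, and the
  total ¹³C recovery.
- **Gradient analysis** — max-normalised density profiles, light/heavy
  window classification, labeling-shift detection from heavy-window
  mass fractions, heavy-fraction selection for sequencing.
- **Enrichment screening** — genus relative abundances, exact
  permutation tests for ¹³C assimilators, net proportional change and
  fold change versus the unamended control, and a curated putative
  iron-reducer genus filter.
- **Synthetic data** — a seeded generator for time courses, gradients
  and count tables with recorded ground truth, so the whole chain is
  testable closed-loop.

## Worked example

```r
library(ironSIP)

# Ferrihydrite-amended, non-fertilized soil: 24 umol acetate consumed,
# 142 umol Fe(II) formed over 4 days
electron_balance(fe2_formed = 142, e_production = acetate_electron_yield(24))
#> Electron balance (acetate -> Fe(III))
#>   electron production : 192 meq e-
#>   flowed into Fe(III) : 142 meq e-
#>   percent to Fe(III)  : 74 %
```

74% of the electrons released by acetate oxidation went into Fe(III)
reduction — ferrihydrite outcompetes methanogenesis for the substrate.

```r
recovery_table()[, c("soil", "amendment", "recovery", "recovery_reported")]
#>   soil amendment recovery recovery_reported
#> 1   NF       FER 26.33333                26
#> 2    N       FER 32.83333                33
#> 3   NF       GOE 30.83333                31
#> 4    N       GOE 35.83333                36
#> 5   NF       CTR 32.83333                33
#> 6    N       CTR 35.16667                35
```

Only ~26–36% of the added ¹³C returns as gaseous plus dissolved
CH₄/CO₂; the unrecovered label is what ends up in biomass — including
the rRNA that SIP detects.

```r
g13 <- simulate_gradient(sim_params(seed = 1), "C13")
g12 <- simulate_gradient(sim_params(seed = 2), "C12")
labeling_evidence(g13$Bacteria, g12$Bacteria)
#> Labeling evidence (Bacteria)
#>   heavy mass fraction: labeled 0.512, unlabeled 0.008 (diff 0.505)
#>   shifted (threshold 0.15): TRUE

tt  <- simulate_taxon_table(sim_params(seed = 3))
rel <- relative_abundance(tt$counts)
md  <- tt$metadata
scr <- assimilator_screen(rel[md$amendment == "FER" & md$isotope == "C13", ],
                          rel[md$amendment == "FER" & md$isotope == "C12", ])
scr[scr$assimilator, c("genus", "mean_rel_labeled", "mean_rel_unlabeled", "p_value")]
#>           genus mean_rel_labeled mean_rel_unlabeled p_value
#> 1     Geobacter        30.952381           2.364244    0.05
#> 2 Dechloromonas        13.943191           1.896408    0.05
#> 3   Clostridium         7.861320           3.149541    0.05
#> 5  Solibacillus         5.079365           1.136174    0.05
#> 6      Bacillus         4.126984           2.172097    0.05
```

Half the bacterial rRNA signal moved into the heavy window under ¹³C
(difference 0.505, far above the 0.15 call threshold), and the exact
3-vs-3 permutation screen flags the genera whose abundance rose in the
labeled heavy fractions — *Geobacter* at ~31% versus ~2.4% unlabeled.
`run_all(run_config(seed = 1))` chains all stages and writes the
summary tables, the labeling-evidence JSON and a run log that records
every defaulted parameter.

Small example input files in each supported TSV schema (all produced
by the package's own generator) ship under `inst/extdata/`.

## Documentation

The methods vignette (`vignettes/iron-sip-methods.Rmd`) describes the
model, its assumptions, the default parameters and their rationale,
what the synthetic generator does and does not emulate, and known
limitations.
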