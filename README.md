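# connscape

Forest loss does not just remove habitat — it severs the dispersal
network that keeps a population demographically and genetically whole.
`connscape` is an R package for quantifying that process for
wide-ranging, forest-dependent carnivores (the motivating system is the
Sunda clouded leopard, *Neofelis diardi*, on Borneo). It implements, as
one tested and reusable pipeline, the full chain from expert habitat
ratings to projected population size, connectivity and genetic diversity
under landscape change:

1. **Expert elicitation** — aggregate a panel's 1–5 habitat-suitability
   ratings per land-cover class; quantify agreement with the two-way
   mixed, consistency intraclass correlations
   ICC(3,1) = (MS_R − MS_E)/(MS_R + (k−1)MS_E) and
   ICC(3,k) = (MS_R − MS_E)/MS_R; check internal consistency against the
   panel's density estimates by OLS R².
2. **Resistance mapping** — invert suitability linearly to a 1–100
   resistance scale (best observed class ⇒ 1, worst ⇒ 100), with
   bilinear resampling; project a future surface by adding
   `risk × resistance(plantations/regrowth)` per cell, clipped at 100.
3. **Source points** — seed dispersers by thresholding `u/r` (uniform
   noise over resistance) at the value giving a target point count, and
   reapply the same threshold (same noise) to later epochs.
4. **Connectivity** — cumulative resistant kernels
   `k = max(0, 1 − cost/bandwidth)` summed over sources at 125/250 kcu,
   and factorial least-cost-path density over all source pairs, smoothed
   by a 10 km focal mean; cost distance is Dijkstra over the 8-neighbour
   lattice with edge weight `cell_size · (r_a + r_b)/2` (×√2 diagonal).
5. **Pattern metrics** — threshold surfaces at a shared first-epoch
   percentile; report PLAND, largest patch index, number of patches and
   correlation length (area-weighted mean radius of gyration), plus
   relative changes between epochs.
6. **Genetic simulation** — a CDPOP-style individual-based model on the
   source points: inverse-square mating/dispersal truncated at the
   dispersal threshold, Poisson(2) litters, infinite-allele mutation at
   5e-4, non-overlapping generations; He, Ho, F = 1 − Ho/He and allele
   counts at generation 200.
7. **Local diversity (sGD-style)** — Mantel correlogram of
   shared-allele distance against cost distance sets a neighbourhood
   radius (half the significant-autocorrelation range); local allele
   counts, Ho and He within cost-distance windows.
8. **Regression** — local diversity against focal resistance, path
   density and (reciprocal-transformed) kernel density, single-variable
   versus global models compared by deviance explained.

A seedable synthetic-landscape module (land cover, edge-concentrated
deforestation risk, expert panels) makes the whole chain testable with no
data downloads.

## Worked example

```r
library(connscape)

scen <- build_scenario(shape = c(80, 80), seed = 11)  # three-epoch fixture
suit <- aggregate_ratings(scen$panel)
head(suit, 4)
#>   class_code n_responses min max        sd mean_suitability mean_density
#> 1          1          10   1   2 0.4898979         1.400000    0.4229273
#> 2          2          11   2   4 0.6030227         3.000000    1.0136719
#> 3          3          11   4   5 0.4810457         4.363636    1.6218210
#> 4          4           9   4   5 0.4969040         4.444444    1.5210555

ag <- agreement_report(scen$panel)
#> ICC(3,1) = 0.80, ICC(3,k) = 0.98, density R2 = 0.99
```

Each row summarises one land-cover class: 9–11 of 13 experts responded,
water (class 1) is poor habitat (mean 1.4), lowland forest (class 3) is
the best (mean 4.36). The averaged-panel agreement ICC(3,k) of 0.98 says
the class ranking is essentially uncontested even though single experts
disagree more (ICC(3,1) = 0.80).

```r
r0  <- build_resistance(scen$grids$t0, suit)
#> resistance_grid 't0': 80 x 80 cells, range [1.00, 100.00]
src <- seed_source_points(r0, 80, seed = 5)
k   <- cumulative_resistant_kernel(r0, src, 125000)
b   <- threshold_to_binary(k$raster, percentile = 10)
compute_metrics(label_patches(b), sum(!is.na(r0$raster$values)))
#>      pland      lpi n_patches correlation_length_m
#> 1 53.01562 53.01562         1              24957.1
```

53% of this landscape is connected by dispersal at the 125 kcu threshold,
all of it in a single patch whose correlation length (the average
within-patch traversal distance) is about 25 km.

```r
p    <- sim_params(generations = 100, n_reps = 3, seed = 2)
runs <- run_simulation(src, r0, p)
summarise_runs(runs)
#>   stat  n         he         ho          f total_alleles ...
#> 1 mean 80 0.29998872 0.28319444 0.05519263     70.000000
#> 2   sd  0 0.01899364 0.01287179 0.02400313      2.645751
```

All 80 sites stay occupied (the landscape is well connected), and after
100 generations of drift at this deliberately small scale He has fallen
to 0.30 with a mild inbreeding coefficient of 0.055. Running the same
chain on the degraded epochs — or simply `run_scenario(scenario_config())`
for the whole analysis with outputs and a manifest on disk — shows the
contrast: connected area, population size, heterozygosity and allele
counts all fall, faster in the second interval, while F rises.

## Layout

* `R/` — implementation (raster container and ESRI ASCII I/O, synthetic
  generators, expert aggregation, resistance, connectivity engine,
  pattern metrics, genetic simulator, local diversity, regression,
  pipeline orchestration).
* `tests/testthat/` — unit, property and end-to-end suites, including
  independent oracles (min-plus closure, exhaustive path enumeration,
  ANOVA sums of squares, normal equations, Wright–Fisher drift law).
* `vignettes/connscape-methods.Rmd` — the models, their assumptions, and
  every open design choice with its rationale.
* `inst/scripts/connscape-run.R` — thin command-line wrapper
  (`synth`, `run-all`).
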