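# reefconn

Biophysical reef connectivity from simulated coral larval dispersal.

Coral populations on isolated reef systems are linked by larvae drifting on
ocean currents. Whether two reefs exchange enough larvae to behave as one
population — and where persistent dispersal barriers lie — cannot be
observed directly; it has to be inferred by simulating larval transport and
survival over many spawning events, and then asking which reef clusters hold
together across the stochastic variability of the ocean. `reefconn`
implements that whole chain for spatial ecologists and marine population
geneticists: Lagrangian particle tracking on gridded surface currents, a
mechanistic larval competency/mortality/settlement model, potential-
connectivity matrices, flow-based reef clustering with a consistency
analysis, and a direct comparison of modelled larval flow against observed
gene-flow (migration-rate) matrices.

Because multidecadal hydrodynamic hindcasts are enormous, the package ships
synthetic generators for every input — analytic velocity fields (uniform,
solid-body rotation, double gyre with a controllable leaky separatrix), reef
grids with grouped reef cells, spawning calendars, and planted-structure
gene-flow matrices — so the full pipeline is testable end to end on a
laptop, against analytic oracles.

## The model

Each virtual particle is released from a reef cell and advected as a
passive, positively buoyant surface drifter (fixed-step RK4, bilinear
spatial and linear temporal interpolation of u/v). The particle represents a
cohort of larvae whose state is split into a pre-competent pool L1 and a
competent pool L2:

    dL1/dt = -(alpha + mu_m(t)) L1
    dL2/dt =  alpha L1 - (beta + mu_m(t) + mu_s F_r(t)) L2

where `alpha` is the competency acquisition rate (zero before the minimum
competency period `t_c`), `beta` the competency loss rate, `mu_m(t)` the
(constant or Weibull) mortality hazard, `mu_s` the settling rate and
`F_r(t)` the reef fraction of the currently occupied grid cell. A *settling
event* `j` is a maximal interval spent over one reef cell (`F_r > 0`,
`t >= t_c`); the larvae settling during it are

    S_j = (rho A_i mu_s F_r^j / N) * integral of L2 over the event

with fecundity `rho`, source-cell area `A_i`, and `N` particles per cell
(up to 60 events per particle, 120 days of drift by default). Within each
trajectory step the linear system is propagated *exactly*, so settling
integrals and the larval mass balance are exact under the piecewise-constant
discretisation of `F_r` and `mu_m`.

Summing `S_j` and dividing by larvae released gives a potential-connectivity
matrix `C[source, destination]` per spawning date. Ensembles of 1000
matrices, each the mean of 10 random spawning dates in the October–March
season, are partitioned into modules by minimising the two-level map
equation with 1% teleportation; the module-membership vectors across the
ensemble are passed through a centred PCA, and PC1 separation between reef
groups acts as a proxy for persistent dispersal barriers. Finally, modelled
larval flow between sampled site pairs can be compared with a BayesAss-style
migration matrix: the ensemble gives a feasible range per pair, and
observations exceeding the ensemble maximum are flagged.

## Worked example

The demo configuration is a double-gyre ocean (two counter-rotating cells,
100 km scale) with three reef groups placed on one orbit in each gyre. With
a steady separatrix (`perturbation = 0`) the two gyres cannot exchange
larvae; the clustering should recover that bipartition in every bootstrap
replicate.

```r
library(reefconn)
res <- run_pipeline(default_config(seed = 7), out_dir = "demo_out")

# mean potential connectivity between reef groups (x 1000):
round(1000 * Reduce(`+`, lapply(res$matrices, unclass)) / length(res$matrices), 2)
#>          group_01 group_02 group_03 group_04 group_05 group_06
#> group_01    43.74    41.35    53.05     0.00     0.00     0.00
#> group_02    60.36    33.62    52.07     0.00     0.00     0.00
#> group_03    55.99    47.37    39.79     0.00     0.00     0.00
#> group_04     0.00     0.00     0.00    31.17    38.51    46.48
#> group_05     0.00     0.00     0.00    30.67    25.98    39.20
#> group_06     0.00     0.00     0.00    42.69    35.90    35.42

res$partitions$partitions[[1]]$modules   # first bootstrap replicate
#> [1] 1 1 1 2 2 2
res$pca$explained_variance_ratio[1]      # PC1 share of membership variance
#> [1] 1
res$pca$scores[, 1]                      # PC1 separates the two gyres
#> group_01 group_02 group_03 group_04 group_05 group_06
#>       -5       -5       -5        5        5        5
```

Between 10 and 15% of larvae released at each group settle, always within
the source gyre (the rest die, lose competency or are still adrift at 30
days), and the off-block entries are exactly zero:
the separatrix is impermeable. All 100 bootstrap replicates recover the
two-gyre split, PC1 explains 100% of membership variance, and the PC1
scores fall in two disjoint values — the signature of a hard dispersal
barrier. Setting `ocean$perturbation = 0.15` makes the separatrix oscillate:
a small inter-gyre flow appears (under 1% of within-gyre flow), the mean
adjusted Rand index against the planted truth stays above 0.9, and PC1
still separates the gyres — a *permeable* barrier.

## Layout

- `R/` — generators (`make_double_gyre`, `make_reef_grid`,
  `make_synthetic_geneflow`, ...), advection (`advect`,
  `sample_reef_fraction`), larval fate (`integrate_fate`, `settle_events`),
  connectivity (`accumulate_connectivity`, `bootstrap_ensemble`,
  `distance_decay`, `generations_to_common_ancestor`), partitioning
  (`map_equation`, `optimize_partition`, `consistency_pca`), comparison
  (`compare_pairs`), and the `run_pipeline` driver with plain-text
  (JSON/CSV) round-trip IO.
- `vignettes/reef-connectivity-methods.Rmd` — the methods vignette: model
  assumptions, parameter choices, numerical design, and limitations.
- `tests/testthat/` — unit, property and acceptance tests, including
  exhaustive-enumeration oracles for the map-equation optimiser.
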