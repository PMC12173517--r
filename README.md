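# riversync

Spatial synchrony, fragmentation and portfolio effects of fish
populations in dendritic river networks.

## The problem

River networks are trees: two sampling sites can be near each other on a
map yet far apart along the watercourse, on the same branch
(*flow-connected*) or on different branches (*flow-unconnected*). Spatial
synchrony — the temporal correlation of density fluctuations at two
sites — decays with watercourse distance and is weaker between branches.
Dams cut this structure further: they block dispersal and change the
environment, so site pairs separated by a barrier should be *less*
synchronous than unseparated pairs at the same distance, converging again
at distances where regional stochasticity dominates. Asynchrony in turn
stabilizes aggregates: a river fragment whose subpopulations fluctuate
out of phase has a steadier total — a portfolio effect.

`riversync` is for ecologists analysing long-term, spatially referenced
density panels (e.g. national electrofishing registries) on fragmented
river networks. It provides:

* **Network geometry** — rooted dendritic trees, watercourse and
  Euclidean distances, flow-connectedness, barriers on routes, and
  clustering of sites into fragments (`build_network()`,
  `pair_geometry_table()`, `assign_fragments()`).
* **Filtered pairwise synchrony** — Spearman correlations over matching
  years, minimum-year and positive-overlap filters, between-fragment
  distance truncation, fragment means (`pairwise_synchrony()`,
  `truncate_between_fragment_pairs()`, `fragment_mean_synchrony()`).
* **Multimembership mixed models** — each pair loads on its two member
  sites; profiled-REML fits of

  *y* = *Xβ* + *Z*<sub>c</sub>*u*<sub>c</sub> +
  *Z*<sub>s</sub>*u*<sub>s</sub> + *ε*,

  with catchment intercept *u*<sub>c</sub>, multimembership site effect
  *u*<sub>s</sub>, Wald tests, marginal/conditional R², singular-fit
  flags, and a type-I-error simulation harness (`fit_mm_lmm()`,
  `fit_synchrony_lmm()`, `type1_simulation()`).
* **Portfolio effect** — Taylor's power law (var = *c*·mean<sup>*z*</sup>)
  across subpopulations, the mean-variance-CV portfolio effect
  PE = CV<sub>uniform</sub>/CV<sub>obs</sub> per fragment, and its mixed-model
  association with fragment synchrony (`taylor_fit()`,
  `fragment_portfolio_effects()`, `pe_synchrony_association()`).
* **Performance metrics** — occurrence rate, mean/s.d. of log-density,
  detrended residual s.d. and trajectory slope per fragment, with
  Benjamini–Hochberg correction across the test family
  (`fragment_performance()`, `performance_associations()`).
* **Fluvial synchrogram** — D1–D4 classification from catchment-wise
  median splits of Euclidean distance and the quotient
  d<sub>E</sub>/d<sub>W</sub>, and an ML/AIC test of whether barrier
  information improves the framework (`classify_pairs()`,
  `compare_barrier_models()`).
* **Synthetic riverscapes** — random bifurcating trees with sites and
  barriers, density panels whose correlation decays with watercourse
  distance and drops across barriers and branches, zero-inflation and
  irregular sampling, plus null panels for calibration
  (`generate_riverscape()`, `simulate_riverscape_densities()`,
  `null_riverscape_densities()`).
* **Pipeline** — `run_pipeline()` / `sensitivity_run()` sequence
  everything into seed-stamped CSV reports; a thin CLI wrapper lives at
  `inst/cli/riversync.R`.

## Worked example

Simulate a trout-like riverscape (strong, small-scale synchrony; barriers
cut cross-fragment correlation to 40%), estimate pair synchrony, and fit
the distance-by-barrier model on flow-connected pairs:

```r
library(riversync)

cfg <- species_archetype("trout", n_catchments = 3, n_edges = 20,
                         n_sites = 30, n_barriers = 4, seed = 1)
rs <- generate_riverscape(cfg)
rs
#> riverscape: 3 catchments, 90 sites, 12 barriers (seed 1)

geometry  <- riverscape_geometry(rs)
densities <- simulate_riverscape_densities(rs, geometry = geometry, seed = 2)
records   <- pairwise_synchrony(densities, geometry, min_years = 6)
records   <- truncate_between_fragment_pairs(records)

fit <- fit_synchrony_lmm(records, "distbarrier", flow = "connected")
fit
#> multimembership LMM (REML); n = 477
#>                  term estimate std_error t_value   p_value
#> 1         (Intercept)  0.46300   0.04173 11.0961 1.310e-28
#> 2           sqrt_d_km -0.09611   0.01509 -6.3710 1.878e-10
#> 3           barrier01 -0.13242   0.09787 -1.3530 1.761e-01
#> 4 sqrt_d_km:barrier01  0.01018   0.03447  0.2954 7.677e-01
#> variance components:
#>    group   member residual
#> 0.001231 0.006850 0.051289
#> R2 marginal 0.181, conditional 0.292; AIC 44.8
```

Reading the output: synchrony at zero distance is about 0.46 and declines
with the square root of watercourse distance (the `sqrt_d_km` term);
pairs separated by a barrier start about 0.13 lower (`barrier01`, the
fragment-crossing effect — at this small example size the Wald test is
not significant), and the positive interaction means the separated and
unseparated curves converge with distance. Variance is partitioned across
catchments, sites (the multimembership component) and the residual.

Fragment-level synchrony and its stability consequences:

```r
fs <- fragment_mean_synchrony(records)
head(fs, 3)
#>   fragment  mean_rho n_pairs catchment
#> 1 c01_s001 0.2580331      10       c01
#> 2 c01_s003 0.1807882     276       c01
#> 3 c02_s001 0.1462789     276       c02
```

The full analysis — geometry, synchrony, all mixed models, Taylor fit,
portfolio effects, performance associations, synchrogram comparison —
runs as one deterministic pipeline whose CSV outputs carry the seed:

```r
res <- run_pipeline(run_config("synthetic", out_dir = "out", seed = 1))
```

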