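---
title: "Methods: synchrony, fragmentation and stability in dendritic river networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synchrony, fragmentation and stability in dendritic river networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Spatial synchrony — the temporal correlation of abundance fluctuations at
spatially separated sites — arises from dispersal, from spatially
correlated environmental stochasticity (the Moran effect), and from shared
trophic interactions. In rivers two geometric peculiarities modulate it.
First, the habitat is a dendritic tree: two sites can be close in
straight-line distance yet far apart along the watercourse, and a pair can
be *flow-connected* (one site lies on the other's downstream route to the
outlet) or *flow-unconnected* (their route descends through a confluence
and climbs another branch). Second, dams fragment the network: they block
dispersal and create abrupt environmental discontinuities, so pairs of
sites separated by a barrier should be less synchronous than unseparated
pairs at the same watercourse distance, with the difference fading at
distances where stochasticity dominates anyway.

Asynchrony matters because it stabilizes aggregates: a fragment whose
subpopulations fluctuate out of phase has a steadier total — a portfolio
effect — which links synchrony to metapopulation persistence. `riversync`
implements the full chain from network geometry to those stability
consequences, and ships a synthetic riverscape generator so every stage
can be exercised and calibrated without field data.

# Network model and pairwise geometry

A catchment is a rooted tree (`build_network()`): edges are stored
upstream→downstream, every node except the single outlet has exactly one
downstream edge, and edge lengths are positive metres. Cycles, braids and
multi-component inputs are rejected rather than repaired, because every
downstream computation assumes the route between two points is unique.
Sites and barriers are *placements*: an edge plus an offset from its
upstream end. Real-mode point tables are snapped by perpendicular
projection onto the nearest straight edge, ties broken by lowest edge id,
so snapping is deterministic.

All point-to-point quantities follow from the tree metric:

* **Watercourse distance** `d_W`: partial offsets at both ends plus the
  node path between. Internally a full node-to-node distance table is
  precomputed per network, so pairwise tables are lookups.
* **Flow-connectedness**: the pair is flow-connected iff
  `d(a, outlet) = d(b, outlet) + d(a, b)` or vice versa (the route is
  monotone with respect to flow). A relative tolerance of 1e-6 absorbs
  floating-point accumulation.
* **Barriers on the route**: barrier `c` lies on the open route a–b iff
  `d(a,c) + d(c,b) = d(a,b)` and both partial distances exceed the
  tolerance — a barrier coincident with a site's own placement does not
  separate that site from its side. This open-route rule is a deliberate
  choice for a case the field data cannot adjudicate; it is configurable
  in spirit (the strictness lives in one tolerance constant).
* **Fragments**: connected components of the site graph with an edge
  wherever the route crosses zero barriers; labels are the smallest member
  site id, making assignment invariant to enumeration order.

Unit convention: metres internally everywhere; kilometres appear only in
model covariates (`sqrt_d_km`) and presentation.

# Pairwise synchrony

Synchrony of a site pair is the Spearman rank correlation of their density
series over the years sampled at both sites, with average ranks for ties
(`pairwise_synchrony()`). Three filters guard estimate quality:

* at least `min_years` matching years (default 6; the sensitivity arm
  uses 10, which can only shrink the record set — a monotone filter);
* at least one matching year in which *both* densities are positive.
  Pairs without such a year produce negatively biased correlations driven
  by alternating zeros. Whether one or both sites must be positive is
  genuinely ambiguous; both-positive is the default and an
  `positive_rule = "either"` variant is available;
* non-degenerate ranks (a constant series has no rank correlation); such
  pairs are excluded with a reason code rather than assigned 0.

Because between-fragment pairs can span longer distances than
within-fragment pairs, each catchment's between-fragment records are
*truncated* to the maximum within-fragment distance
(`truncate_between_fragment_pairs()`). Truncation is implemented as record
removal, not distance capping: capping would fabricate geometry, while the
statistical problem being solved is the unequal distance ranges of the two
groups in interaction models. Fragment-level synchrony is the plain
arithmetic mean of within-fragment pair correlations; it deliberately
ignores spatial sampling density, which keeps it interpretable as "the
synchrony of the sampled sites".

# The multimembership mixed model

Each observation is a pair, so each site contributes to many observations:
rows are not independent. The model treats a synchrony value as a group
with its two member sites: alongside a catchment random intercept, a
*multimembership* site effect enters through an incidence matrix with two
unit weights per row (configurable to 0.5),

$$ y = X\beta + Z_c u_c + Z_s u_s + \varepsilon,\qquad
   u_c \sim N(0, \sigma^2_c I),\; u_s \sim N(0, \sigma^2_s I),\;
   \varepsilon \sim N(0, \sigma^2_e I). $$

`fit_mm_lmm()` profiles the (restricted) likelihood over the variance
ratios $\gamma_k = \sigma^2_k/\sigma^2_e$ and reduces all linear algebra
to $q \times q$ systems via the Woodbury identity ($q$ = catchments +
sites), so fits scale with the number of sites rather than pairs.
Numerical choices, all deterministic:

* start at unit ratios (all components equal to a third of the OLS
  residual variance);
* bounded quasi-Newton (L-BFGS-B) on the ratios, followed by a
  derivative-free polish on the square-root scale ($\gamma = t^2$), where
  the zero boundary becomes an interior stationary point — boundary
  line-search failures on null-like data are thereby avoided; the better
  criterion wins;
* ratios below 1e-5 are re-evaluated at exactly zero; fits with a ratio
  below 1e-6, or with a one-level random block, are flagged *singular*
  and reported, never suppressed;
* p-values use the large-sample normal reference. Pairwise synchrony
  datasets here have hundreds to thousands of rows, where
  Satterthwaite-style corrections are negligible; the type-I simulation
  below verifies the consequence rather than assuming it.

Model presets mirror the analysis structure: the three-way interaction of
sqrt-watercourse-distance, flow-connectedness and fragment-border
crossing; distance-by-barrier models on flow-stratified subsets; and
main-effects-only variants. The square root of distance linearizes the
concave distance decay of synchrony. Marginal and conditional $R^2$ use
the variance-decomposition definition (fixed-predictor variance over
total, with random components added to the numerator for the conditional
version). AIC and likelihood-ratio comparisons across different fixed
structures (the synchrogram test) always use ML fits; REML is reserved
for inference within one structure.

## Type-I calibration

`type1_simulation()` fixes a riverscape, simulates null density panels
(identity correlation, no trends — so every fixed effect is truly zero
while the multimembership structure is fully preserved), runs the entire
synchrony pipeline and the three-way model on each, and reports per-term
rejection proportions with binomial Monte Carlo errors. At the scale used
in the acceptance harness (40 sites × 4 catchments, 30 years, per-site
sampling probability 0.5, 500 replicates) every non-intercept term's
rejection proportion at $\alpha = 0.05$ falls within three binomial
standard errors of 5%.

# Portfolio effect

Across subpopulations, temporal variance scales with temporal mean as
$\mathrm{var} = c\,\mathrm{mean}^z$ (Taylor's power law); `taylor_fit()`
estimates $z$ by OLS on log10–log10 axes pooled across a species' sites.
When $z$ is materially different from 2 (tolerance 0.1), the average-CV
portfolio effect is invalid and the mean-variance CV metric is required
(`choose_pe_metric()`).

For an eligible fragment (≥ 4 subpopulations, each with ≥ 10 sampled
occasions) the metapopulation series is the per-year sum of subpopulation
densities over the years in which *all* eligible subpopulations were
sampled. This strict common-year rule means the sum always adds the same
populations; the alternative (partial coverage with imputation) trades
bias for sample size and is deliberately not the default. Then

$$ \mathrm{PE} \;=\; \frac{\mathrm{CV}_\text{uniform}}{\mathrm{CV}_\text{obs}},
  \qquad \mathrm{CV}_\text{uniform} = \frac{\sqrt{c\,\mu_T^{\,z}}}{\mu_T}, $$

with $\mu_T$ the metapopulation mean. PE > 1 means the aggregate is more
stable than a single uniform population of the same size; PE = 1.5 reads
as "1.5 times more stable". The orientation (uniform over observed) is
chosen so that this reading holds. Closed-form anchors used in the tests:
two independent equal-CV subpopulations under $z = 2$ give
$\mathrm{PE} \to \sqrt2$; perfectly correlated identical subpopulations
give $\mathrm{PE} \to 1$; PE is non-increasing in within-fragment
correlation.

The association between fragment mean synchrony and PE is a mixed model
with a catchment random intercept (fragments of one catchment share
geography); a negative slope is the stabilizing-asynchrony signal.

# Performance metrics

Five further fragment metrics (`fragment_performance()`): occurrence rate,
mean and standard deviation of `log(density + 1)` (site-level, averaged
unweighted to the fragment), and — from one regression per fragment of
log-density on year in interaction with site identity — the residual
standard deviation and the mean per-site trend slope. The interaction
regression gives every site its own intercept and slope, so the residual
s.d. is a *detrended* variability: adding a common linear trend to all
sites changes the trajectory estimate and leaves the residual s.d.
untouched (a property the tests assert to 1e-10). Whether the regression
uses a reference level or fully separate per-site parameters does not
affect residuals; fully separate parameters are used. Sites with a single
observation cannot carry a slope and are left out; fragments with fewer
observations than parameters are dropped with a reason.

Each metric (plus the PE) is regressed on fragment mean synchrony with a
catchment random intercept; the six p-values per species form one
Benjamini–Hochberg family, since the portfolio-effect test belongs to the
same question.

# Synchrogram categories and the barrier test

For each pair, the quotient $q = d_E/d_W$ indexes functional
connectivity. Catchment-wise median splits of $d_E$ (short/long) and $q$
(high/low) define four classes: D1 same-branch near, D2 same-branch far,
D3 adjacent-branch near, D4 separate-branch far. Ties are deterministic:
$d_E$ at its median counts as short, and $q$ at its median counts as
high — the latter so that a perfectly straight channel, where every pair
has $q = 1$ exactly, classifies as same-branch (D1/D2) as the geometry
demands. Both splits are catchment-wise.

The barrier test fits two ML mixed models with the usual random
structure — synchrony on category, and synchrony on category × barrier
crossing — and compares AIC and the likelihood ratio. Empty
category-by-barrier cells drop their interaction columns (logged). On
panels generated with a strong barrier effect, the barrier model wins
decisively and the largest within-versus-between-fragment synchrony gap
sits in D1, the class where dispersal coupling is strongest.

# The synthetic riverscape generator

`generate_riverscape()` grows, per catchment, a random recursive
bifurcating tree embedded in the plane; edge lengths are the Euclidean
lengths of the straight embedded segments, which makes
$d_E \le d_W$ hold exactly. Sites and barriers are placed uniformly along
the channel (edge picked proportional to length). The target correlation
of two sites' log-density deviations is

$$ C_{ij} = s_0\, e^{-d_W/\rho}\; \beta^{[\text{barrier crossed}]}\;
   \gamma^{[\text{flow-unconnected}]}, $$

i.e. a baseline synchrony $s_0$ decaying with watercourse distance over
range $\rho$, multiplicatively reduced across fragment borders ($\beta$)
and across branches ($\gamma$). Correlation, not covariance, is the
target because Spearman synchrony is scale-free; site variances are set
independently. The multiplicative form is not guaranteed positive
semidefinite, so the matrix is repaired by eigenvalue clipping at 1e-8
and rescaled to unit diagonal; the largest entry adjustment is recorded
on the result (`"psd_adjustment"`). Given $C$, annual multivariate normal
deviates drive site log-densities with site-specific intercepts and
trends; densities are exponentiated, zeroed with the zero-inflation
probability (hurdle-style, emulating electrofishing zero catches), and
each site-year is retained with the sampling probability, producing the
irregular coverage typical of monitoring registries.

Defaults describe a mid-sized boreal riverscape: 6 catchments × 40
segments of 0.5–5 km, 60 sites and 6 barriers per catchment, 30 annual
campaigns with sampling probability 0.7, $s_0 = 0.6$, $\rho = 10$ km,
zero-inflation 0.1, log-density intercepts $N(2, 0.5^2)$, year-to-year
s.d. 0.6, trend s.d. 0.01/yr. Species archetypes capture contrasting
ecologies: `"trout"` ($\rho \approx 10$ km, $\beta = 0.4$ — mobile lotic
salmonid, sharp barrier response), `"minnow"` (similar, slightly weaker),
`"pike"` ($\rho \to \infty$, $\beta = \gamma = 1$ — sedentary generalist
synchronized by regional climate, insensitive to distance and barriers).

What the generator does *not* emulate — and hence what passing tests do
not show about real data: mechanistic dispersal or demography (no stage
structure, no explicit kernels), density dependence, observation error in
the electrofishing sense beyond zero-inflation, non-stationary
environments, or barrier-specific attributes (height, regulation). The
generator is a correlation-structure emulator, which is exactly what the
estimators under test consume.

## Problem sizes used in the automated checks

Simulation scale in the test-suite is a package choice balancing Monte
Carlo error against desk-scale runtimes: type-I calibration uses 500 null
replicates at 40 sites × 4 catchments; barrier-effect and synchrogram
recovery use 100 replicates at the generator default (60 × 6), with a
fresh riverscape every 10 replicates; geometry oracles sweep 200 random
20-edge riverscapes; REML dominance checks 20 tiny datasets against a
20³ variance-component grid; portfolio-effect limits use series of
2 000–20 000 years. All randomness descends from fixed integer seeds.

# Known limitations

* Braided channels are rejected, not resolved; real vector layers need
  upstream cleaning before ingestion.
* The multimembership model assumes homoskedastic residuals, while pair
  correlations estimated from different numbers of matching years have
  different sampling variances; the type-I simulation shows the Wald
  tests nevertheless hold their level under the study's missingness
  pattern.
* Fragment mean synchrony depends on the spatial sampling distribution;
  it is an estimate of the sampled sites' synchrony, not a
  geometry-corrected quantity.
* PE eligibility (≥ 4 subpopulations × ≥ 10 occasions, strict common
  years) can leave few eligible fragments in sparse panels; the
  association models then lean on few points and singular fits are
  flagged rather than hidden.
* p-values use the normal reference throughout; with very few catchments
  the catchment-variance component is weakly identified (flagged via the
  singular rule for one-level blocks).
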