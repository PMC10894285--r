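---
title: "Modelling native-vegetation loss under property-level Legal Reserve constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling native-vegetation loss under property-level Legal Reserve constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cerradosim` implements a spatially explicit, stochastic model of
native-vegetation conversion on a regular grid, of the family used to
project deforestation in Brazilian biomes. The landscape is a binary map
(1 = native vegetation, 0 = anthropogenic use) on 1 km² cells; the model
asks, for every native cell $x$ and two-year interval $t$, with what
probability it is converted:

$$P_{\mathrm{nvl},x,t} = \frac{1}{1 + e^{-k_{x,t}}}, \qquad
  k_{x,t} = \beta_0 + \sum_v \beta_v\, z_v(x, t).$$

The covariates $z_v$ are the ten landscape drivers (distances to roads,
cities and rivers; dry-season length; elevation; agricultural potential;
cattle density; permanent- and annual-crop fractions; a binary
protected-area indicator) plus one endogenous channel, the local
anthropogenic fraction (`land_cover`), recomputed from the evolving map at
every simulation step. That recomputation is what makes conversion
pressure spread along existing clearing fronts instead of raining down
i.i.d. on the map.

This vignette records the modelling decisions, their defaults and the
reasoning behind them; every number quoted here is computed by the test
suite or the analysis scripts, not asserted from memory.

## The calibration model

For each two-year calibration period we form one Bernoulli record per cell
that is native at the period start (outcome 1 if it converted by the
period end; reversions are rejected as data errors, since the model is a
loss model). Coefficients get independent $N(0, 10^2)$ priors and are
sampled by random-walk Metropolis: joint Gaussian proposals whose global
scale adapts during burn-in toward a 20–40% acceptance rate
(Robbins–Monro on the log scale, window of 100 iterations). Defaults are
20,000 iterations, 50% burn-in, thinning to at least 1,000 retained draws
— comfortably more than the 100 draws the projection stage consumes. The
kernel is compiled (Rcpp) and draws all randomness from R's stream, so
`set.seed()` makes chains exactly reproducible.

Two scaling conventions matter for interpretability:

* continuous drivers are z-standardized over the training cells, with the
  (mean, sd) pairs frozen in the stack and reused verbatim at every
  projection step;
* the protected-area indicator and the `land_cover` fraction enter raw.
  Both are already bounded, and leaving them unscaled makes their
  coefficients directly readable: a protection coefficient of $-1.4$ is a
  log-odds shift, a `land_cover` coefficient of $+2.5$ spans the fraction's
  $[0,1]$ range.

A covariate that is constant within a period carries no information and is
excluded from that period's model rather than fitted: its posterior would
merely resample the prior, and a prior-width coefficient attached to a
covariate that later *does* vary (the canonical case is `land_cover` in a
first period that starts all-native) would inject noise into projections.

**Model selection** follows held-out likelihood: a seeded random 70/30
cell split per period, greedy forward selection from the always-included
`land_cover` channel, scored by the test-sample log-likelihood at the
posterior-mean coefficients. Ties break toward the smaller subset, then
lexicographically. Greedy search visits ~40 candidate fits per period
instead of $2^{10}$ exhaustive subsets; the exhaustive route is available
via `select_model()` with an explicit candidate list. Goodness of fit is
reported as AUC in its Mann–Whitney form (exact over all pairs, ties
counted half), checked in the tests against an $O(n^2)$ pair-counting
oracle.

The per-period contribution table (`summarize_contributions()`) reports
the median posterior coefficient per variable, with zeros for variables
the selection excluded, in a fixed reporting order — negative means the
variable suppresses conversion (protection being the canonical example).
The underlying "relative contribution" convention is deliberately simple
(median coefficients); no significance testing or multiplicity correction
is applied, since the quantity reported is a posterior summary, not a
test.

## Projection under constraints

Projection runs in two-year steps from the last observed state to the
horizon (2050/2070). Each of the (default 100) Monte Carlo iterations
draws *one* coefficient vector from the posterior and keeps it for the
whole trajectory, so every iteration is an internally consistent world;
the accumulated conversion probability of a cell at year $Y$ is the
fraction of iterations in which it had converted by $Y$ — values live on
the $m/100$ lattice for a single model. Dynamic drivers are held at their
final observed layer throughout (the model deliberately does not
extrapolate census variables), while `land_cover` is recomputed each step.

Two constraints bind during projection but not during calibration, where
observed transitions are taken as-is and protection acts only as a
covariate:

* **Protected areas** are a hard mask: strictly protected cells never
  convert. (During calibration the same cells carry the soft negative
  coefficient instead.) Both behaviours are independently switchable in
  `constraint_set()`.
* **Legal Reserve floors**: a property only yields cells while its native
  area strictly exceeds `lr_fraction` × property area, and any conversion
  that would push it below the integer-cell floor
  `ceiling(lr_fraction * n_cells)` is cancelled, in randomized cell order,
  within the step — the floor is exact, verified by `lr_audit()` over all
  iterations. Properties that *enter* projection already below their floor
  (possible, because calibration-period transitions are taken as-is —
  a historical Legal Reserve deficit, as exists in the real biome) simply
  yield nothing; the audit flags only projection-caused breaches. Cells
  outside any property and outside protection (public untitled land)
  convert with no floor.

A resolution artefact worth knowing: at 100-ha cells every property of
150 ha or less is a single cell, and a single-cell property with any
positive Legal Reserve fraction can never convert its only cell. Loss in
the smallest class is therefore structurally near zero on these synthetic
landscapes; the medium and large classes, which span many cells, carry
the signal.

The four period-specific projections are **ensembled** by cellwise
averaging of accumulated probabilities (equal model weights); their
per-iteration loss distributions are pooled as an equal-weight mixture,
which keeps the ensemble's expected loss equal to the mean of the member
expectations. Intervals are central 95% quantiles of the across-iteration
total-loss distribution, reported as ± half-width. (Whether such
intervals should span posterior draws or Monte Carlo iterations is a
modelling choice; here each iteration carries one posterior draw, so the
across-iteration spread includes both sources.)

## Scenarios

A scenario is a transformation of the constraint set
(`apply_scenario()`): Legal Reserve overrides by region, added protected
areas, and the headline *large-property rule* — freeze a fixed share
(default 30%) of every property above an area threshold (default
2500 ha). Two readings of that rule coexist and both are implemented:

* **additive** (default): the frozen share sits on top of the Legal
  Reserve, so a 3000-ha property in a 20% region keeps at least 50% of its
  area. Mechanically, the scenario freezes specific cells and those
  frozen cells are *not* allowed to count toward the property's Legal
  Reserve, which is what makes the shares add.
* **max**: total protection is `max(lr_fraction, protected_fraction)`,
  for readers who take the rule as a ceiling rather than a complement.

Frozen cells are chosen as the currently native cells with the highest
native-neighbourhood fraction (ties broken at random), emulating
protection of contiguous remnants; the placement rule is a design choice,
not an empirical claim.

Avoided loss is BAU expected loss minus scenario expected loss. BAU and
scenario runs share per-iteration seeds, and the simulator draws one
uniform per grid cell per step regardless of constraints, so the paired
runs are coupled cell-for-cell and the difference estimator is
low-variance. A cheap static-mask approximation (`scenario_mask()`) —
zero out BAU probability on newly frozen cells — is provided alongside
re-simulation; it ignores displaced conversion pressure and so slightly
overstates avoidance.

## The synthetic landscape generator

No real land-cover, census or property-registry data ship with the
package; the generator builds landscapes with the statistical structure
the analysis assumes, and the generating coefficients double as ground
truth for recovery tests.

* **Drivers**: distance variables are Euclidean distance transforms from
  randomly seeded source cells; continuous fields are Gaussian-filtered
  white noise (autocorrelation length 5 cells by default) rescaled to
  plausible units; the protected mask thresholds a smooth field at the
  configured share (default 8.3% of cells, the biome's approximate
  strictly-protected share), producing contiguous reserves. Census-like
  variables (cattle, the two crop fractions) drift between periods as an
  AR(1) process (ρ = 0.9) on the latent field — a stand-in, since real
  census layers are only known to vary between collection years.
* **Properties**: target areas are drawn from a lognormal law (default
  meanlog = log 200 ha, sdlog = 1.5 — heavy-tailed enough that a 200×200
  grid populates all five size classes C1–C5: 1–150, 150–400, 400–1000,
  1000–2500, >2500 ha) and grown as contiguous patches by seeded region
  growing on the non-protected grid, which ends up partitioned exactly.
  Legal Reserve fractions follow vertical region bands weighted
  0.70/0.15/0.10/0.05 toward 20/35/50/80% — the general savanna regime
  dominating, the Legal-Amazon regimes minor.
* **History**: starting all-native, each period applies the model's own
  logistic rule with the configured coefficients. The defaults are sparse
  in the style of reported driver tables — `land_cover` +2.5,
  protection −1.4, distance-to-rivers +0.3, agricultural potential +0.4,
  intercept −4.5 — giving ≈1% conversion of native cells per two-year
  step, a realistic recent-decades rate. Generation errors out if the
  expected conversions per period fall below one cell, since such a
  history cannot calibrate anything.

What the generator does *not* emulate: real geography (roads are random
points, not networks), spatial autocorrelation in the *residual*
conversion noise (cells convert independently given the predictor),
measurement error in land-cover classification, and the self-declared
biases of a property registry. Passing tests on these landscapes
therefore demonstrate that the machinery is correct and well-calibrated
under the model's own assumptions — not that the model is right about any
particular real biome.

## Numerical choices and problem sizes

* Likelihood probabilities are clipped to $[10^{-12}, 1-10^{-12}]$; the
  compiled kernel uses the overflow-safe softplus form of the same
  expression.
* The floor arithmetic `lr_fraction * n_cells` is evaluated with a
  $10^{-9}$ tolerance before `ceiling()`, so 0.35 × 20 is 7 cells, not 8.
* Probability rasters are exact on the $m/100$ lattice; ASCII-grid
  export writes full precision, and run manifests store configuration
  numbers as `%.17g` strings, so `replay_manifest()` reproduces a run's
  outputs with identical checksums.
* The test suite and acceptance script run the full study conditions —
  a 200 × 200 grid (~40,000 native cells), four periods (~157,000 pooled
  Bernoulli records), chains of 3,000–8,000 iterations (shorter for the
  many candidate fits of forward selection, longer for the posteriors
  that feed projections and recovery checks), 100-iteration projections
  over 27 two-year steps — and smaller grids (32–128 cells a side) for
  unit-level properties. Parameter-recovery experiments use 20 seeded
  replicates at full scale.

## Known limitations

* Loss only: no regeneration, no carbon or extinction accounting.
* Drivers are frozen at their last observed layer during projection, so a
  road built in 2040 cannot attract conversion; this mirrors the model
  family's stated static-variable limitation.
* Selection by held-out likelihood with a 30% test split is noisy for
  variables with weak effects; spurious inclusions have near-zero
  coefficients and are harmless for projection, but the selected-subset
  table should be read with that in mind.
* The Legal Reserve mechanics operate on whole cells; properties smaller
  than ~2 cells are effectively frozen (see above), which understates
  small-property loss relative to a sub-cell implementation.
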