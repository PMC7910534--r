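---
title: "Stacked movement models for origin-destination flows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked movement models for origin-destination flows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowstack)
```

## The modelling problem

An origin-destination (OD) matrix records, for every ordered pair of regions
(i, j), the number of trips (or a normalised intensity of contact) from i to
j. Spatial-interaction models predict these flows from three ingredients:
the origin population m_i, the destination population n_j, and some notion
of separation — either the distance r_ij or the *intervening population*
s_ij, the total population living strictly closer to the origin than the
destination is. flowstack implements the five classical models of this kind,
fits each by Poisson maximum likelihood, combines them with a stacked
Poisson GLM, and compares everything by cross-validated Poisson deviance.
No single spatial-interaction model fits every kind of movement data —
short-range commuting, long-range travel, and navigation-app traces all
weight distance and opportunity differently — which is exactly why a stacker
that learns data-driven weights over all five is worth the extra machinery.

## The five base models

All models force self-loops to zero: T_ii = 0 identically, because none of
these models describes within-region movement.

* **Gravity**: T_ij = θ m_i^α n_j^β / r_ij^γ. α and β tune how strongly
  flows scale with origin and destination size; γ is the distance decay; θ
  is a free scale (trips, or intensity units).
* **Gravity with distance cut-off**: an independent gravity parameter set
  for short trips (r ≤ δ) and long trips (r > δ), so the two regimes decay
  differently. The boundary r = δ is assigned to the short branch (the
  definition leaves it open; some convention is needed and this one is
  fixed here). δ is measured in km and by default estimated jointly with
  the other parameters through a log transform; `fit_config(fix_delta =)`
  freezes it instead.
* **Radiation**: T_ij = θ m_i n_j / ((m_i + s_ij)(m_i + n_j + s_ij)),
  motivated by commuters accepting the closest sufficient job offer. θ is
  nominally the commuting proportion of the origin population; we fit it as
  an unconstrained positive scale because on normalised (GPS-like)
  intensities the proportion reading is meaningless.
* **Radiation with selection**:
  T_ij = θ (1 − λ^P/P)(1 − λ^Q/Q) / (1 − λ^R/R) with P = m_i, Q = n_j and
  R = m_i + n_j + s_ij, λ ∈ (0, 1). λ^P is computed as exp(P log λ), which
  underflows cleanly to zero at census-scale populations (each factor → 1,
  the flux → θ). That near-degeneracy at large P is a property of the
  printed equation, not a numerical defect; the stacker is free to give the
  resulting near-constant predictor a small (or offsetting) weight.
* **Intervening opportunities** (stochastic, Schneider form):
  T_ij = κ (exp(−λ(s_ij + m_i)^θ) − exp(−λ(s_ij + m_i + n_j)^θ)): the
  probability that an acceptable destination appears in region j and none
  closer. The proportionality constant κ is made explicit and fitted,
  because Poisson likelihood needs an absolute intensity scale.

The intervening population uses a fixed geometric convention: a circle
centred at the **origin** with radius r_ij, strict inequality, both
endpoints excluded. Regions tied at exactly r_ij do not count. This is the
standard radiation-model construction; a union-of-two-circles reading of
"around both population centres" exists but is not adopted here.

Distances are Euclidean on projected kilometre coordinates, or haversine
(Earth radius 6371 km) on lon/lat input. Road distance or travel time is a
known limitation of the whole model family, not something the package
attempts.

## Fitting

Each model is fitted by minimising the Poisson negative log-likelihood
Σ (μ − y log μ) over the off-diagonal cells (the y-independent log y! term
is dropped). Observed values may be non-integer, so normalised intensities
fit through the identical code path. Predictions are clamped at 1e-10
before any log — the same floor used in the deviance and in the stacker
design matrix.

Optimisation is BFGS on unconstrained transformed parameters: log for
θ, κ, δ, the intervening-opportunities λ and exponent; logit for the
selection λ ∈ (0, 1); identity for α, β, γ. Gradients are numerical central
differences — five heterogeneous models share one objective wrapper, and at
these problem sizes correctness is worth more than analytic speed. Starting
values: exponents at 1, scale constants matched so the unit-scale model
mean equals the observed mean, selection λ at 0.5, IO λ solving
exp(−λ · median(s + m)) = 1/2, δ at the median off-diagonal distance. The
first optimum is polished by a second BFGS pass; a non-converged run gets
up to `max_restarts` seeded jittered restarts and is reported (never
silently) with `converged = FALSE` if all fail. `fit_config(tolerance =)`
is the optimiser's relative convergence tolerance; the default 1e-10 is
deliberately tight so that noise-free synthetic flows recover their
generating parameters to ~1e-3 or better. Fitting is deterministic given
the config: refits are bit-identical.

Zeros are data: a zero flow contributes μ to the likelihood. Cells can be
masked out (cross-validation masks held-out cells this way) but are never
zero-filled, which would bias the scale parameter downward. An all-zero
matrix is accepted with a warning — the scale collapses towards the floor,
which is the correct ML answer for such input.

## The stacked ensemble

The stacker is a Poisson GLM with log link regressing the observed flows on
the five log-predictions:

log(μ_k) = β_0 + β_1 log λ_1k + … + β_5 log λ_5k,

with the columns fixed in the order gravity, gravity-distance, radiation,
radiation-with-selection, intervening-opportunities, and the coefficients
serialised with those names so nothing can silently misalign. Diagonal
cells are excluded from the design (base predictions there are exactly zero
and their log is undefined).

Fitting is iteratively reweighted least squares, with each weighted
least-squares step solved by SVD on the square-root-weighted design.
Rank-deficient or nearly collinear designs therefore get the minimum-norm
pseudo-inverse solution rather than dropped columns. This matters: when two
base models make near-identical predictions (the two radiation variants on
census-scale populations, typically), the unregularised ML solution can
carry huge offsetting weights on the pair. That is faithful stacker
behaviour and is preserved; an optional ridge penalty
(`ensemble_config(ridge =)`) is available for users who prefer stability
over fidelity, and is off by default.

Because the GLM's feasible set contains every "pure" weighting (β_a = 1,
rest 0) and the equal-weight average lies inside its convex hull in
log-space, the converged ensemble's training deviance can never exceed the
training deviance of any single base model. The test suite asserts this
exactly on every synthetic fixture.

## Evaluation

Model comparison is k-fold cross-validation (default k = 5) scored by
Poisson deviance D = 2 Σ [y log(y/μ) − (y − μ)] with the y = 0 term equal
to 2μ. Deviance is a relative measure: the report structure keeps models
side by side on one dataset and is never aggregated across datasets.

Folds partition the off-diagonal *cells*, not the regions: the task is
predicting unobserved flows between known regions, so each fold masks a
random fifth of the pairs from every model's training likelihood. The
ensemble inside CV is trained per fold, on that fold's training cells, using
base predictions from models fitted to those same cells — no information
from held-out cells leaks into either stage. The report also carries a
`mean` row, the unweighted average of the five base predictions, as the
baseline that data-driven weighting has to beat.

## The synthetic-data generator

`synthetic_scenario()` fixes the study conditions; `generate_locations()`
and `generate_flows()` realise them reproducibly from one seed.

* Populations are log-uniform on [3,000, 25,000] by default — the band of
  Australian SA2 census regions, with the heavy small-population tail that
  makes urban/rural contrast. The log-uniform law itself is a stand-in: the
  census defines the band but no generative law.
* Coordinates are uniform on a 500 km square by default (a state-scale
  extent), or Gaussian clusters around hubs for urban heterogeneity.
* Flows come from a generating model's expectation, optionally a convex
  mixture of two models. Each mixture component is first rescaled to the
  scenario's `mean_flow` so a 50/50 weight is a genuine half-and-half;
  without that, whichever component happens to have the larger natural
  scale would dominate and the weight would be meaningless. The mixture
  default used throughout the package's own experiments is half gravity
  (θ=1, α=0.8, β=0.6, γ=1.5 — also the parameter point used in recovery
  tests), half intervening opportunities, at mean flow 25 trips per pair
  (tens of commuters between typical region pairs).
* Noise is independent per-cell Poisson sampling; `"expectation"` mode
  passes the expectation through exactly and exists for closure testing
  (fit-on-noise-free-data must recover the generating parameters almost
  exactly). Census-like output is integer counts (Poisson draws already
  are); GPS-like output divides by the matrix total so intensities sum
  to one.

What the generator does *not* emulate: spatial autocorrelation of
residuals, day-of-week or seasonal structure, the sampling bias of
navigation-app users, road-network geometry, and region polygons (regions
are points). Passing tests on this generator therefore demonstrate the
pipeline's statistical machinery — identifiability, stacking gains, honest
cross-validation — not that any model is adequate for a particular real
dataset.

## Problem sizes and numerical choices

The package's own experiments run at desk scale, chosen as the smallest
sizes at which the phenomena of interest are unambiguous: 50 regions for
parameter recovery, 60 regions and five seeds for the held-out
ensemble-versus-base comparison, k = 5 folds throughout. The shared
prediction floor is 1e-10; ensemble linear predictors are capped at
exp-scale 1e12 with a warning; the IRLS stops on a relative deviance change
below 1e-10. CSV writers emit 17 significant digits so write/read
round-trips are bit-identical; fitted-model JSON does the same.

## Known limitations

* Euclidean (or great-circle) distance only; no road network.
* The radiation-with-selection equation as printed degenerates to a
  constant at large populations; it is kept as printed.
* The stacker is the plain GLM stacker: no cross-validated super-learner
  weighting, no production/attraction constraints on the gravity variants.
* Deviance comparisons are within-dataset only, by construction.

## A worked run

```{r example, eval = FALSE}
scn <- synthetic_scenario(
  40, model = "gravity",
  mixture = list(
    model = "intervening_opportunities",
    params = intervening_opportunities_params(1, log(2) / 15000, 1),
    weight = 0.5),
  mean_flow = 25, noise = "poisson", seed = 1)
locs <- generate_locations(scn)
geom <- pairwise_geometry(locs)
flows <- generate_flows(scn, locs, geom)

report <- cross_validate(flows, locs, geom, k = 5, seed = 1)
print(report)
```

The same pipeline is exposed on the command line (`inst/cli/flowstack`)
as `simulate`, `fit`, `predict`, `ensemble`, `cv` and `scale`
subcommands over a YAML config, and `scripts/acceptance.R` reruns the
package's headline computations end to end from a single seed.
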