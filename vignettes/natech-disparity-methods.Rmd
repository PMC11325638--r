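---
title: "Methods: screening, wind exposure, and spatial disparity models for hurricane-related contaminant releases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, wind exposure, and spatial disparity models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hurricanes trigger technological accidents — "natech" events — at refineries,
chemical plants, storage terminals, and pipelines: flooding and wind damage
cause unauthorized air emissions and spills of hazardous material to land and
water. Because industrial facilities are not sited uniformly with respect to
race and income, the burden of these releases raises an environmental-justice
question: *are neighborhoods with more Hispanic, Black, low-income, or renter
households more likely to sit next to (and downwind of) hurricane-related
releases than otherwise comparable neighborhoods near the same kinds of
facilities?*

`natechdisparity` implements the full analytical chain needed to answer that
question at the census block-group level: screening raw release reports,
constructing matched business-as-usual comparison periods, classifying block
groups by buffer distance and wind sector, descriptive summaries, and a
Bayesian binomial Leroux conditional autoregressive (CAR) model for the
disparity estimates. A synthetic-data module generates every input the
pipeline consumes, with known ground truth, so each stage is testable at desk
scale without regulatory or census extracts.

## Screening release reports

Land/water release reports are free-text field reports and need filtering
before analysis. `filter_landwater()` retains a report only if

* its cause code is in the whitelist (flood, hurricane, equipment failure,
  natural phenomenon, sinking vessel, unknown) and not in the blacklist
  (derailment, dumping, explosion, operator error, overpressuring,
  trespasser);
* its source type is whitelisted (fixed, mobile, pipeline, storage tank,
  unknown sheen, vessel) and is not an aircraft or railroad;
* its description contains no air-release keyword (default list: *flaring*,
  *scrubber*, *atmosphere*; whole-word, case-insensitive — the list is
  configurable because the vocabulary is open-ended);
* it is not a status update of an earlier report.

Two conservative choices are deliberate. First, codes outside the whitelist
are **excluded** and logged as unrecognized rather than retained: an explicit
whitelist reading. Second, every exclusion is logged with the *first* rule
that fired, in a fixed order (update, excluded cause, excluded type,
unrecognized cause, unrecognized type, air keyword), so exclusion counts are
reproducible and auditable.

## Study periods

Each hurricane window starts two days before landfall (to capture planned
shutdowns) and ends a week after the storm leaves the region. Business-as-usual
comparison windows in surrounding years must match the hurricane window's
length *and* its weekday/weekend composition, because excess-emissions
reporting has a strong weekly cycle. `build_reference_period()` searches
start-date shifts in the order 0, −1, +1, −2, +2, … days and returns the
first window with the same number of weekend days (weekend = Saturday and
Sunday), i.e. the qualifying window whose start is closest to the hurricane's
month-day, ties resolved to the earlier start. A qualifying window always
exists within ±6 days because weekday patterns recur weekly. For 14-day
windows every shift qualifies (any 14 consecutive days contain exactly 4
weekend days), so the same-date window is chosen. `sample_random_days()`
implements the secondary comparison: a uniform sample of dates, ignoring the
day of week, with the reference windows removed from the pool.

## Wind direction and exposure classes

Hourly zonal (*u*, eastward) and meridional (*v*, northward) winds give the
wind speed `ws = sqrt(u^2 + v^2)` and the **leeward angle** — the direction
the wind blows toward — `atan2(v/ws, u/ws) * 180 / pi`. All angles in the
package use the mathematical convention (degrees counterclockwise from east)
so leeward angles and facility-to-centroid bearings are directly comparable;
geodesic mode converts compass bearings into the same convention.

The daily predominant direction per grid point is the **arithmetic median**
of the non-calm hourly angles (middle value, or the mean of the two middle
values for an even count). Taken literally on degree values, the arithmetic
median is ill-defined across the 0/360 wrap — `c(350, 0, 10)` has arithmetic
median 10, though the circular center is 0. We implement the literal
convention as the default and provide a wrap-aware circular median
(`daily_dominant(method = "circular")`) for sensitivity checks; for the
synthetic wind regimes the two rarely differ. Calm hours (`ws = 0`) carry no
direction and are removed before the median; a point-day with no non-calm
hour is flagged calm.

Each event takes the direction of the geometrically nearest grid point
(distance ties to the lowest point id). A block group is **downwind** when
the bearing from the facility to the block-group centroid lies within 45° of
the leeward direction — a 90° sector, boundary inclusive.

Air-exposure classes, per hurricane set, with precedence top to bottom:

1. **exposed** — within 2 km of a facility that reported an event *and*
   downwind on at least one event day (multi-day events contribute one
   direction per day);
2. **excluded (upwind)** — within 2 km of an event facility but downwind on
   no event day; calm wind on all event days also lands here and is logged;
3. **at_risk** — within 2 km of a regulated facility that reported no event;
   this is the comparison group, because block groups without a nearby
   regulated facility are not at risk of an excess emissions event at all;
4. **unexposed** — 2–10 km from the nearest regulated facility;
5. **excluded (far)** — beyond 10 km of every facility.

The sensitivity variant (`use_wind = FALSE`) drops the wind requirement, so
the exposed set can only grow. Land/water classes use the releases
themselves: exposed within 2 km, unexposed at 2–10 km, excluded beyond.

Distance and bearing need a convention the source material leaves open: we
measure buffer distance from the facility or release point to the **nearest
point of the block-group polygon** (so a block group partially inside the
ring counts) and take bearings to the **polygon centroid**. Both choices are
recorded in the classification's metadata and switchable
(`distance_from = "centroid"`). Buffers are strict (`< 2 km`); the sector
boundary is inclusive. Synthetic mode uses planar kilometres; real-data mode
(`distance_mode = "geodesic"`) uses WGS84 geodesic distances via
`geosphere`.

## The spatial disparity model

For the air outcome the analysis rows are exposed vs at-risk block groups;
for land/water, exposed vs unexposed. With `y_i = 1` for an exposed block
group, the model is

$$y_i \sim \mathrm{Bernoulli}(p_i), \qquad
  \mathrm{logit}(p_i) = \mathbf{x}_i^\top\boldsymbol\beta + \phi_i,$$

with the Leroux CAR prior on the spatial effects:

$$\boldsymbol\phi \sim \mathrm{N}\!\left(\mathbf 0,\;
  \tau^2\left[\rho(\mathbf D-\mathbf W) + (1-\rho)\mathbf I\right]^{-1}\right),$$

where $\mathbf W$ is the queen-contiguity adjacency matrix (neighbors share
an edge *or* a vertex), $\mathbf D$ its diagonal row-sum matrix, $\rho \in
[0,1]$ blends independence ($\rho=0$) against an intrinsic CAR ($\rho \to
1$), and $\tau^2$ scales the spatial variance. The full conditional of one
effect is Normal with mean $\rho\sum_j w_{ij}\phi_j / (\rho\sum_j w_{ij} + 1
- \rho)$ and variance $\tau^2/(\rho\sum_j w_{ij} + 1-\rho)$, which reduces to
an independent $\mathrm N(0, \tau^2)$ at $\rho = 0$.

Covariates are block-group percentages — Hispanic, Black, Asian/Pacific
Islander, and other race/ethnicity, with the White percentage as the omitted
reference — plus, in adjusted models, percent of households without a
vehicle, percent below twice the poverty line, percent renters, and
population density in hundreds of persons per km². All covariates enter in
their natural units, so an odds ratio reads "per one-percentage-point
increase" (per 100 persons/km² for density).

Two supporting analyses frame the CAR fit. A county-fixed-effect logistic
baseline (`fit_logistic_fe()`) provides maximum-likelihood estimates, flags
separation explicitly, and supplies Pearson residuals whose spatial
autocorrelation is tested with Moran's I
($I = (n/S_0)\, \mathbf z^\top \mathbf W \mathbf z / \mathbf z^\top\mathbf
z$, expectation $-1/(n-1)$) under a two-sided permutation test — the
diagnostic that motivates the spatial model. Block groups with no
queen neighbor among the analysis rows cannot inform a CAR fit; they are
dropped and logged before fitting.

### MCMC scheme

Priors (configurable through `car_priors()`): independent
$\mathrm N(0, 10^5)$ on each fixed effect, $\mathrm{InvGamma}(1, 0.01)$ on
$\tau^2$, $\mathrm{Uniform}(0,1)$ on $\rho$. The sampler, written in C++, is

* single-site random-walk Metropolis for each $\beta_j$ and each $\phi_i$,
  with step sizes adapted every 50 sweeps during burn-in toward 40–50%
  acceptance and frozen afterwards (adaptation during burn-in only, so the
  post-burn-in chain is a valid fixed-kernel Markov chain);
* conjugate inverse-gamma Gibbs for $\tau^2$;
* random-walk Metropolis for $\rho$, with the prior determinant
  $\tfrac12\log|\rho(\mathbf D-\mathbf W)+(1-\rho)\mathbf I|$ evaluated from
  the eigenvalues of $\mathbf D - \mathbf W$, computed once per graph and
  reusable across fits (`eigen_M`). Because a single $\rho$ move is cheap,
  five updates run per sweep; this is what keeps $\rho$ mixing on short
  chains. Proposals outside $[0,1)$ are rejected.
* $\boldsymbol\phi$ is recentred to mean zero every sweep with the mean
  absorbed into the intercept — the standard sum-to-zero identification for
  an intercept-plus-spatial-field model.

Three chains run from overdispersed starts (maximum-likelihood centre plus
noise; $\phi$ initialized at the scale of the initial $\tau^2$, which matters:
a small-$\phi$ start would make the first $\tau^2$ Gibbs draw collapse and pin
the field at zero). The default run is 3 chains × 20 000 iterations with the
first 10 000 discarded; the packaged demo and the test suite use shorter
chains (3 × 3000–6000) that we verified give the same posterior summaries on
their problem sizes. Convergence is gated numerically: a potential scale
reduction factor above 1.1 on any fixed effect, $\rho$, or $\log\tau^2$
raises a warning, never a silent pass. With a fixed seed every chain is
bit-reproducible (all randomness flows through R's RNG).

Odds ratios are posterior medians and central 95% credible intervals of
$\exp(\beta_j)$ over the post-burn-in draws pooled across chains
(`extract_or()`, type-7 sample quantiles).

The sampler was cross-validated against an independent implementation of the
same model in JAGS (multivariate-normal prior with the explicit Leroux
precision matrix) on a small lattice; posterior quantiles for
$\boldsymbol\beta$, $\rho$, and $\tau^2$ agree. One behavior worth knowing:
with a single Bernoulli observation per areal unit, the data carry little
information about $\tau^2$, and under the default $\mathrm{InvGamma}(1,
0.01)$ prior its posterior concentrates well below a moderate generating
value. The independent JAGS fit reproduces exactly the same concentration,
and fixed-effect inference is unaffected — parameter-recovery simulations at
$n = 3000$ return the generating odds ratio — but $\tau^2$ itself should not
be over-interpreted in binary-outcome fits.

## The synthetic-data generator

The generator emulates the *structure* of the study inputs, not Texas:

* **Region** — an `n_rows × n_cols` planar grid of 1 km² square block
  groups partitioned into contiguous counties. Planar geometry keeps every
  distance and adjacency exact in tests.
* **Demographics** — a spatial Dirichlet model: gamma shape parameters for
  the five race/ethnicity shares vary with a smooth gradient around a random
  "urban core", so the non-White share, poverty, renters, and density all
  rise toward the core and the White share is anticorrelated with the rest,
  qualitatively matching urban industrial corridors. Shares are normalized
  to sum to exactly 100; closure holds by construction. Poverty, renters,
  and vehicle access are beta-distributed with gradient-shifted shapes;
  density is log-normal (median 3 hundred persons/km² at the fringe, ~20 at
  the core).
* **Facilities** — points placed uniformly within the region, across the
  five NAICS groupings used for point sources, with a per-year reporting
  dropout of 15%.
* **Reports** — per-facility, per-day Poisson counts at an event rate that
  is higher inside hurricane periods (defaults 0.06 vs 0.02
  events/facility/day, chosen to yield a hurricane:reference ratio in the
  two-to-three range typical of natech screening studies at the demo scale).
  Air events carry log-normal per-pollutant-group masses (meanlog
  `log(1500)` lbs, sdlog 2.5 — a heavy tail spanning <1 lb to millions of
  pounds, as excess-emissions reports do). Land/water reports carry cause
  and type codes, with a 20% contamination fraction of excluded codes so the
  screening filters have real work to do, 5% air-keyword descriptions, 10%
  status updates, and 5% ungeocoded reports.
* **Wind** — hourly u/v on a coarse grid: a constant regime (the oracle for
  exposure tests), a rotating regime, and a random regime with smooth
  per-day directions, hourly jitter, log-normal speeds, and occasional calm.
* **Outcomes** — `generate_outcomes()` is the generative twin of the fitted
  model: Leroux-CAR-distributed spatial effects at configurable $\beta$,
  $\rho$, $\tau^2$, then Bernoulli draws. This is what parameter-recovery
  and coverage tests consume.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: realistic meteorology (no storms, fronts,
or diurnal structure), NAICS-specific release behavior, geocoding error
beyond a coordinate-dropout flag, reporting biases in public incident
databases, and real census geography (no rivers, no irregular polygons, no
population-weighted centroids). Tests demonstrate that the *methods* are
implemented correctly, not that the substantive findings of any particular
study generalize.

All generators are pure functions of their arguments and one master seed,
fanned out through a deterministic stream splitter, so every synthetic data
set is bit-reproducible and no call disturbs the session RNG.

## Numerical choices and degenerate inputs

* Queen contiguity is detected by snapped-vertex hashing (tolerance 1e−8)
  plus a vertex-on-edge pass for T-junctions between bounding-box
  neighbors; it is invariant to vertex order and ring orientation. Isolated
  polygons are dropped and reported, never silently retained.
* Point-in-polygon uses the even-odd ray cast; point-to-polygon distance is
  zero inside, else the minimum over edge segments.
* Zero-variance covariates are dropped from CAR fits with a warning rather
  than producing a singular fit; all-equal outcomes are an error (air) or an
  explicit separation status (logistic baseline).
* `rho = 1` on a disconnected graph makes the Leroux precision singular;
  `sample_leroux_effects()` detects this via the Cholesky factorization and
  tells the caller to use `rho < 1` or connect the graph.
* The Moran permutation p-value is two-sided with the add-one correction,
  `min(1, 2 * min(P_ge, P_le))`; its size is calibration-tested at
  $\alpha = 0.05$ over 1000 null replicates.
* A reference-period mean of zero makes the hurricane:reference ratio
  undefined; it is flagged, never divided through.
* All display rounding (pounds to integers, events per facility to one
  decimal) happens in print methods; stored values are unrounded.

## Problem sizes in the test suite

The suite exercises the spatial models at $n = 3000$ block groups (a 60 × 50
grid, matching the scale of a multi-county block-group analysis) with 3
chains × 4000 iterations for recovery, coverage, and maximum-likelihood-limit
checks; the downwind classifier is compared against a brute-force oracle on
100 random layouts of up to ~200 block groups, 20 facilities, and 5 event
days; Moran's I runs 1000 null replicates of 999 permutations at $n = 100$.
The packaged demo is a 20 × 20 km region with 16 facilities and 3 × 6000
MCMC iterations, sized to finish in well under a minute.

### Spatial separability at small scales

A caution specific to unit-level binary CAR models: exposure defined by
proximity forms compact spatial clusters, and when the analysis contains only
a handful of such clusters the spatial field can reproduce the outcome
*exactly* — a saturated fit whose likelihood dominates any covariate-based
explanation. The fixed effects are then unidentified, and under the
conventional near-flat prior (variance $10^5$) their posterior simply
diffuses. The funnel-crossing scale move makes the sampler honest enough to
find this region, so small demonstrations show it clearly. The packaged demo
therefore uses a weakly-informative fixed-effect prior (variance 10, i.e. a
per-percentage-point log-odds almost surely within roughly $\pm 6$ — still
far wider than any plausible effect) through the `mcmc$beta_prior_var`
configuration key, yielding wide but finite intervals; the function default
remains the conventional $10^5$, appropriate when the comparison spans many
exposure clusters and several hundred exposed units, as in a real
multi-county analysis.

## Known limitations

* The arithmetic (wrap-naive) median of daily angles is the default by
  design; analyses of regions with prevailing winds near due east (0°/360°)
  should prefer the circular median.
* The CAR model drops county fixed effects, relying on $\phi$ to absorb
  spatial structure; the logistic baseline keeps them. Whether to carry
  county terms alongside a spatial field is a genuinely open modelling
  choice — both are reported.
* $\tau^2$ is weakly identified by binary outcomes (see above).
* Exposure classes are proximity indicators, not dispersion estimates: no
  plume modelling, no sub-daily exposure, no interpolation of wind between
  grid points. Results should be read as indicators of potential exposure
  risk, not exposure.
* Real-data mode expects geocoded inputs; free-text geocoding and raw export
  dialects of regulatory databases are out of scope.
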