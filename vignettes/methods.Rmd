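---
title: "Methods: Lagrangian features, biologging, and feeding-rate models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Lagrangian features, biologging, and feeding-rate models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, numerical
choices and the open design decisions we settled, in the spirit of the
long-form methods vignettes that accompany modelling packages. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The scientific problem

Pelagic predators must find prey that is patchy in space and ephemeral in
time. Submesoscale surface-current features (fronts, eddy boundaries; tens
of kilometres, hours to days) aggregate drifting organisms and are
hypothesised to mark feeding hot spots. The package quantifies that link at
three levels for a diving, lunge-feeding predator carrying a depth/GPS tag:

1. **Regional (third-order) selection** — do animals occupy stronger
   aggregative features than randomly available in their regional domain?
2. **Feeding-site (fourth-order) selection** — within the occupied area,
   does the *probability of feeding* on a dive rise with feature strength?
3. **Feeding intensity** — does the *feeding rate* itself rise with
   feature strength?

The feature proxy is the backward-in-time finite-time Lyapunov exponent
(FTLE) of the surface velocity field: high backward FTLE at a point means
initially distant tracers converged there over the preceding integration
horizon — an attracting Lagrangian coherent structure.

## FTLE computation

**Model.** Tracers seeded on a grid refined 10× relative to the current
grid (600 m from 6 km currents; fencepost rule `(n−1)·R + 1` seeds per
axis) are advected by the interpolated velocity field from the analysis
hour `t0` over a signed horizon `T = −48 h`. The flow-map gradient `∇Φ` is
taken by central differences over each seed's four grid neighbours
(one-sided at grid edges, such cells flagged lower-confidence), and
`FTLE = ln λmax((∇Φ)ᵀ∇Φ) / (2|T|)`, converted to day⁻¹. The 48 h default
horizon averages over tidal currents while keeping most tracers inside a
coastal-scale domain; it is a configuration default, not hard-wired.

**Interpolation contract.** Bilinear in space inside the enclosing cell,
linear in time between bracketing hourly frames. These choices make the
interpolant exact for globally linear fields and continuous across cell
boundaries, both of which are asserted by tests.

**Land (free-slip).** The paper-level requirement is that tracers slide
along, not into, the coast. Our discretization: land nodes are filled with
the nearest water value so bilinear interpolation stays continuous, and
within any cell one of whose edges is entirely land, the velocity component
normal to that edge is tapered linearly to zero at the edge. This leaves
the tangential component untouched and gives exactly zero normal flow on
the land edge. How to discretize free-slip on a staggered-free grid was an
open choice; this rule is ours and is stated in the function docs.

**Data gaps.** HF-radar-like dropouts inside the water domain are not
restored by any gap-filling model. During advection a gap node borrows the
nearest valid node's velocity if one exists within one parent cell;
otherwise the tracer freezes where it is and is flagged, and every FTLE
cell whose stencil touches a frozen tracer is masked invalid. Freezing (vs
deleting) keeps the damage local: a stray tracer corrupts its own stencil,
not the whole field. The same freeze-and-flag policy applies to tracers
that leave the grid hull. Both policies are recorded in the output objects.

**Adaptive integration.** Classical Runge–Kutta–Fehlberg 4(5) with one
common step size shared by all live tracers, controlled by the worst
per-tracer error estimate (absolute floor 1e−7 km, relative default 1e−6).
Sharing the step sequence has two consequences we exploit in tests: the
numerical flow-map *gradient* is exactly invariant to adding a uniform
translation to the flow (the drift cancels in neighbour differences), and
step sizes are quantized to multiples of 2⁻²⁰ h so that last-ulp noise in
the error estimator cannot perturb the accept/reject sequence — without
this, integrating a time-periodic flow at `t0` and `t0 + period` gives
visibly different step sequences whose truncation-level differences are
then amplified exponentially in high-stretching (chaotic) regions.

**Extraction.** A dive is matched to the temporally nearest FTLE field if
one lies within 30 min, then to the nearest *valid* grid cell (searching
outward a bounded number of rings). Missing is a value, not an error: dives
without a match stay in the table flagged, and downstream statistics
exclude them explicitly.

## Biologging processing

Dives are excursions beyond 10 m depth (strict inequality; a 9.9 m cast is
not a dive). Post-dive surface duration is the time to the next dive start;
the record's final dive has an undefined surface duration and therefore an
undefined feeding rate, and is flagged rather than imputed. The per-dive
feeding rate divides the lunge count by the full dive cycle (dive +
surface) — the denominator charges the transit and recovery time to the
dive — and is expressed in lunges h⁻¹ (×3600 at the formula).

GPS fixes are filtered for implied speeds above 6 m s⁻¹. The published
tooling's removal order is not documented, so we made the filter exact
instead: dynamic programming finds the *largest* subset of fixes whose
consecutive pairs all satisfy the speed bound (ties broken toward keeping
earlier fixes), verified against exhaustive enumeration on small tracks.
Dive-start locations are linearly interpolated between bracketing fixes
only when the bracket spans under 15 min (strict).

Feeding rates are percentile-normalized per individual (`FR_pct`, rank/n ×
100, ties averaged, feeding dives only — non-feeding dives are pinned at
0%, which also settles an ambiguity about whether the normalization pool
includes them). States split at the 25th/75th percentiles; the boundary
value 75 is assigned to *heavy* because one of the two overlapping printed
state definitions has to win, and heavy's "≥" is the stricter reading. In
the separate *weighted pooled* rate split (below) the worked example we
target places the 75th-percentile value in the moderate segment, so that
function uses `(q25, q75]` for moderate; the two conventions are each
documented at their function.

## Habitat selection

Availability is simulated at 10 background points per real location, drawn
uniformly in the ±1° box around each individual's location extent at the
real location's timestamp, with FTLE extracted identically to real points.
Draws with missing FTLE (land, no coverage) are retried up to 100 times and
then kept as missing and excluded *visibly* (the exclusion count is an
attribute): silently dropping them would bias availability toward covered
water. Individuals are equalized by weights `1/(n_locations ×
n_deployments)` (locations) and `1/(n_feeding_dives × n_deployments)`
(rates), which sum to 1 by construction.

The test statistic is the one-sided two-sample Kolmogorov–Smirnov
`D = sup_x [F_background(x) − F_whale(x)]` on *weighted* ECDFs. Weights
invalidate the classical null distribution, so the p-value is a label
permutation (values keep their weights); with equal weights `D` reduces
exactly to the classical statistic and the classical asymptotic p-value is
reported alongside. Both decisions — permutation inference and surfacing
the classical value — were open; we ship both numbers.

## Feeding-site selection and null models

The mean model is logistic: feeding (≥1 lunge) on FTLE, with a
per-individual random intercept and continuous-time AR(1) serial
correlation in time-since-deployment-start, estimated by penalized
quasi-likelihood (`MASS::glmmPQL` with `nlme::corCAR1`). An alternative
design replaced PQL with estimating equations; since the canonical
estimator is available and robust here (with the Nelder–Mead `lme`
optimizer, which handles near-zero variance components far better than the
default), we fit the model as specified and validate it by *parameter
recovery on synthetic data* — slope 0.45 and slope 0 generators, coverage
of the fit's own 95% CI in ≥18/20 replicates — rather than by
coefficient-for-coefficient replication of any particular dataset.
Complete separation is detected on a preliminary GLM and aborts with a
diagnostic. With a single individual the model degrades gracefully to
plain logistic regression (tested against a direct MLE oracle).

**CRW nulls.** Each individual's track yields `r` (mean resultant length
of turning angles) and `h` (step-length scale, the mean step in km). Null
tracks resample the observed step lengths (scaled by `h`), draw turning
angles from a wrapped Cauchy with mean resultant length exactly `r`, start
uniformly inside the minimum convex polygon of the observed locations
(restarting if the start or any step lands on land), and keep the source's
timestamps and feeding labels — so the null randomizes *where* the animal
was, not *when* or *whether* it fed. The distributional choices (resampled
steps, wrapped Cauchy) were open; resampling preserves the empirical
step-length shape and the wrapped Cauchy's concentration parameter equals
`r` identically, which makes recovery testable.

**Time-shift nulls.** Timestamps shift forward by 24/48/96/192 h with
positions and labels fixed and FTLE re-extracted. If features decorrelate
within a day, shifted covariates decouple from feeding and the fitted
slope attenuates toward zero — asserted on synthetic fields with a 6 h
decorrelation time.

## Feeding-intensity model

With states known a priori (supervised), the hidden-Markov likelihood
factorizes by origin state: the next state follows a multinomial logit in
FTLE *at the origin dive* (the covariate-timing convention of the
animal-movement HMM tradition; the choice was open and is documented), with
the self-transition as reference category. Each origin's coefficients are
maximized by BFGS with analytic gradients; standard errors come from the
inverse Hessian; an independent multinomial-logit fitter is used as a
cross-check in the tests. Individual sequences never transition into each
other. Stationary probabilities solve `πΓ(x) = π, Σπ = 1` as a constrained
linear system, with reducibility rejected by a positivity check of
`(I + Γ)^{S−1}`.

The estimated overall feeding rate at FTLE `x` is `Σ π_state(x) ×
rate_state` with the non-feeding rate 0, evaluated over `x ∈ [−1.25, 1.5]`
day⁻¹ (values outside are computed but flagged as extrapolation).
Confidence curves re-evaluate the whole pipeline at the elementwise
interval endpoints `β ± 1.96 SE`; the delta method was the alternative, but
endpoint evaluation matches the "upper and lower confidence intervals of
the model" convention and keeps the band computable for any monotone
functional. Because the stationary map is nonlinear, the band is taken as
the envelope of the endpoint curves and the point curve. State mean rates
come from the *weighted pooled* feeding-rate distribution split at its
weighted 25th/75th quantiles (type-1 inverse-ECDF quantiles; pooled
weighted rates rather than pooled percentile ranks, the other reading of an
ambiguous convention).

## The synthetic-data layer

The generator defines the study conditions; it is not tuned.

- **Analytic flows**: uniform (`FTLE = 0`), linear saddle (`FTLE = a`
  exactly, any horizon, either time direction), and the standard
  double-gyre benchmark (`A = 0.1, ε = 0.25, ω = 2π/10` on `[0,2]×[0,1]`),
  with a flag to map the planar km domain onto lon/lat axes so geographic
  code paths run against known truth. `degrade_field()` masks
  `round(gap_fraction · n)` water samples and adds Gaussian noise,
  reproducibly by seed.
- **Whale deployments**: per individual, lognormal dive (mean 480 s,
  sdlog 0.35) and surface (120 s, 0.45) durations — an ~10-minute dive
  cycle; a meandering track at 1.5 m s⁻¹; four behavioural states driven
  by the multinomial-logit transition model with FTLE slopes
  `(−0.8, 0, +0.3, +0.8)` toward (non-feeding, light, moderate, heavy) and
  off-diagonal intercepts −1.5 (sticky states); zero-truncated Poisson
  lunges with state means `(0, 2.3, 4, 5.7)` per dive, yielding dive-cycle
  feeding rates in the low tens of lunges h⁻¹ as observed for rorquals;
  20% of dives lack a GPS fix. Deployment length defaults to 7 days
  (field deployments span roughly 2–18). All randomness flows from one
  seed via per-individual sub-seeds.
- **Stochastic FTLE fields**: spatially smoothed Gaussian fields evolving
  as AR(1) in time with a configurable decorrelation scale, for statistics
  that need known temporal persistence without paying for advection.

What the generator does *not* emulate: realistic coastal oceanography,
krill dynamics, depth-structured behaviour, tag measurement error, or
GPS spatial error. Passing tests therefore demonstrate that the estimators
recover known couplings under the stated noise structure — not that any
particular ocean or whale behaves this way.

## Problem sizes and numerical defaults

The test suite and acceptance script run desk-scale versions of every
analysis: FTLE grids of order 20×20 parent nodes at refinement 2–4
(the double-gyre oracle comparison uses a 41×21 grid at refinement 4
against a 4×-finer finite-difference oracle integrated by fixed-step RK4 on
the closed-form velocity); slope-recovery panels of 10 individuals × 150
dives × 20 replicates; transition-recovery chains of 20 000 transitions ×
20 replicates; permutation tests at 500–2000 permutations. These sizes were
chosen to make the stochastic acceptance checks comfortably stable on a
single CPU; all of them are function arguments, and scale up unchanged.

Numerical defaults: RKF tolerances `rel 1e−6 / abs 1e−7 km`, maximum step
0.5 h, step quantum 2⁻²⁰ h; weighted quantiles are inverse-ECDF (type 1);
percentile ranks average ties; the stationary solve uses QR on the
constrained system; multinomial fits start at 0 and stop at `reltol 1e−12`.

## Known limitations

- The free-slip taper is first-order in the cell fraction; curved coasts
  are rasterized at parent-grid resolution.
- PQL inference for binary responses is approximate; with strong random
  effects and short series its standard errors can undercover (one reason
  acceptance is phrased as CI coverage on synthetic data).
- The multinomial transition model assumes the covariate at the origin
  dive; if features evolve appreciably within a dive cycle, this is a
  discretization of convenience.
- Background availability ignores land unless the FTLE series masks it;
  exclusions are surfaced but the spatial null is otherwise uniform.
- Weighted K-S permutation inference permutes labels holding weights with
  values, which assumes exchangeability of (value, weight) pairs under the
  null.
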