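# ftleforage

Links submesoscale aggregative surface-current features to the habitat
selection and foraging performance of a marine predator. The package was
built around the blue whale / California Current study system — HF-radar
surface currents, multi-sensor biologging tags, lunge-feeding rorquals — but
every stage is generic: gridded currents in, located dive records in,
selection statistics and feeding-rate models out.

## What it computes

**Lagrangian features.** From hourly gridded surface currents `(u, v)` the
package computes the backward-in-time finite-time Lyapunov exponent (FTLE),

```
FTLE(x, t0) = ln λmax(C) / (2 |T|),   C = (∇Φ)ᵀ (∇Φ),
```

where `Φ` is the flow map obtained by advecting a tracer grid seeded at 10×
the current-grid resolution from `t0` over the horizon `T = −48 h` with
adaptive Runge–Kutta–Fehlberg 4(5) stepping, bilinear spatial and linear
temporal interpolation, and a free-slip condition along land. Ridges of
backward FTLE (units day⁻¹) mark attracting, aggregative transport
structures — fronts and eddy boundaries where drifting prey concentrates.

**Biologging.** 1 Hz depth traces become dives (excursions > 10 m); GPS
fixes are speed-filtered (> 6 m s⁻¹ implausible) and interpolated to
dive starts within 15-min gaps; each dive gets the nearest valid FTLE cell
within 30 min; per-dive feeding rate is
`lunges / (dive duration + post-dive surface duration)` in lunges h⁻¹,
percentile-normalized per individual (FR_pct) and split at the 25th/75th
percentiles into non-feeding / light / moderate / heavy states.

**Selection and feeding statistics.**

- *Regional (third-order) selection*: weighted one-sided two-sample
  Kolmogorov–Smirnov test of whale-encountered vs background FTLE, with
  10:1 background sampling in a ±1° availability box and per-individual
  weights `1/(n_locations × n_deployments)`; permutation p-values.
- *Feeding-site (fourth-order) selection*: logistic GLMM
  (`glmmPQL` + `corCAR1`) of feeding on FTLE, against correlated-random-walk
  null tracks (wrapped-Cauchy turning angles with concentration `r`,
  resampled step lengths with scale `h`, MCP starts) and time-shift nulls
  (+24/48/96/192 h).
- *Feeding intensity*: a supervised four-state Markov model whose
  transition probabilities are multinomial-logit functions of FTLE;
  stationary state probabilities π(FTLE) and the estimated overall feeding
  rate `Σ π_state(FTLE) × rate_state` over FTLE ∈ [−1.25, 1.5] day⁻¹.

A synthetic-data layer (analytic uniform/saddle/double-gyre flows with
known FTLE, degradable gappy/noisy fields, and a whale-deployment simulator
with known FTLE coupling) makes the whole pipeline testable offline.

## Worked example

```r
library(ftleforage)

# a saddle flow has constant FTLE equal to its strain rate (0.5 day^-1)
f  <- gen_analytic_field(flow_spec("saddle", list(a = 0.5),
                                   domain = c(-60, 60, -60, 60),
                                   grid_spacing = 6, time_span = c(0, 48)))
ff <- compute_ftle(f, t0 = 48, horizon = -48, refinement = 3)
mean(ff$ftle[ff$valid])
#> [1] 0.5

# simulate whale deployments over stochastic FTLE fields and fit the
# feeding-site selection model
ser <- simulate_ftle_series(hours = 0:120, seed = 3)
ws  <- simulate_whale_deployment(whale_sim_spec(n_individuals = 4,
                                                duration_days = 2), ser,
                                 seed = 11)
fit <- fit_feeding_model(ws$dives)
tidy(fit)
#> # A tibble: 2 × 5
#>   term        estimate std.error statistic    p.value
#>   <chr>          <dbl>     <dbl>     <dbl>      <dbl>
#> 1 (Intercept)    0.970     0.145      6.70 NA
#> 2 ftle           1.73      0.401      4.31  0.0000180
```

The positive `ftle` slope says the odds of a feeding dive rise with the
strength of the aggregative feature at the dive site — here recovering the
coupling built into the simulator. `estimate_feeding_rate_curve()` turns a
fitted 4-state transition model plus state mean rates into the overall
feeding-rate-vs-FTLE curve with confidence bands
(`autoplot()`-able), e.g. stationary probabilities
`(0.51, 0.12, 0.22, 0.15)` with state rates `(13.5, 23.9, 34.1)` lunges h⁻¹
give an overall `11.99` lunges h⁻¹ via `feeding_rate_from_probs()`.

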