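---
title: "Probabilistic two-zone exposure modelling with twozone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic two-zone exposure modelling with twozone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twozone)
```

## The model

Indoor exposure near a point source is poorly described by a single
well-mixed room: the worker's breathing zone sits in a small Near-Field
(NF) around the source where concentrations are far above the room
average. The two-zone (NF/FF) mass-balance model splits the room volume
$V_{room}$ into an NF volume $V_{NF}$ (here, a partially enclosed
pouring station of 1–2 m$^3$) and the remaining Far-Field
$V_{FF} = V_{room} - V_{NF}$, each treated as well mixed. With an
emission rate $G$ (mg/min) released into the NF, an inter-zonal
air-mixing flow $\beta$ (m$^3$/min), general ventilation
$Q = AER \cdot V_{room}/60$ (m$^3$/min) exhausting from the FF, and an
optional local exhaust $Q_{lev}$ drawing air straight out of the NF, the
governing equations are

$$V_{NF}\,\frac{dC_{NF}}{dt} = G + (\beta + Q_{lev})\,(C_{FF} - C_{NF}),$$
$$V_{FF}\,\frac{dC_{FF}}{dt} = \beta\,C_{NF} - (\beta + Q)\,C_{FF}.$$

Assumptions baked into this system:

* **Clean supply air and zero initial state.** Background concentrations
  are treated as insignificant for the pouring process; the shift starts
  from $C_{NF} = C_{FF} = 0$.
* **LEV topology.** The local exhaust is modelled with 0% source-capture
  efficiency: it removes no emitted material at the source, only NF air.
  Its make-up air is drawn from the FF, so the NF receives
  $\beta + Q_{lev}$ from the FF and returns $\beta$; the FF in turn
  receives $Q$ of clean make-up. This reproduces the observed ~70%
  reduction of the NF level by a 9.6 m$^3$/min rim exhaust at the
  packaged default $\beta$. At steady state the NF excess over the FF is
  $G/(\beta + Q_{lev})$, i.e. the LEV acts exactly like extra
  inter-zonal ventilation for the NF excess.
* **Piecewise-constant emissions.** Each bag pour is an emission segment
  with constant $G$; within-pour emission dynamics are not modelled.

`steady_state()` returns the fixed point of this system
($C_{FF}^* = \beta G / (Q(\beta + Q_{lev}))$, which reduces to the
familiar $G/Q$ without LEV). Note that with $Q_{lev} > 0$ the FF fixed
point is *below* $G/Q$: part of the contaminant leaves through the NF
exhaust without ever diluting into the FF balance.

### Exact propagation

`propagate()` advances the state with the closed-form
eigen-decomposition of the $2\times 2$ constant-coefficient system
rather than a fixed-step integrator. The off-diagonal product of the
coefficient matrix is strictly positive, so the eigenvalues are always
real, negative and distinct; no degenerate branch is needed, and the
only rejected configuration is $\beta \le 0$. Exactness means the 1-min
reporting grid of `simulate_timeline()` is cosmetic: time averages and
the mass balance are computed from the analytic integral
$\int C\,dt$ per segment, not from grid quadrature, and step size never
enters as a reproducibility variable. The packaged tests verify
agreement with adaptive and fixed-step ODE oracles to better than
$10^{-6}$ relative error and exact mass conservation
($V_{NF}C_{NF}(T) + V_{FF}C_{FF}(T) + \int [Q_{lev}C_{NF} +
(Q-Q_{lev})C_{FF}]\,dt = \int G\,dt$).

## Scenario parametrization

The packaged scenario library describes a paint-factory powder-pouring
shift derived from field observations: four tasks (TiO$_2$ from four
big bags, TiO$_2$ from ten small bags, Micro Mica from seventeen small
bags, and an emission-free cleaning phase that tracks residual air
concentrations), in a 1300–1500 m$^3$ naturally ventilated hall with
AER 2–8 1/h. Emission rates are triangular with the mode at the
field-estimated value and (0.5×, 2×) bounds; $\beta$ is triangular
(0.649, 3.2, 10) m$^3$/min, derived from random-air-speed measurements
via $\beta = \tfrac12 \cdot \mathrm{FSA} \cdot s$
(`beta_from_airspeed()`) for the partially enclosed station. "Linear
range" parameters are continuous uniform. Durations are in minutes,
volumes in m$^3$, rates in mg/min.

Seven variants encode alternative Conditions of Use: widened emission
bounds (1×–4× the mode), halved $\beta$ (0.33, 1.6, 5), AER reduced
five-fold, a 100 m$^3$ enclosure, a 10,000 m$^3$ hall, a 9.6 m$^3$/min
LEV, and a worst case combining the precautionary settings (with
$\beta$ minimum 0.325, as specified for that combination). Where a
realized emission time would exceed its pouring time, the emission is
truncated to the pouring time with a warning rather than rejected.

### Sampling scopes

Every distributed parameter carries a sampling scope: `per_shift`,
`per_task` or `per_repetition`. The defaults draw the building-scale
determinants ($V_{room}$, $AER$, $V_{NF}$) once per shift and the
process-scale determinants ($\beta$, $G$, $t_G$, $t_{pouring}$) afresh
for every repetition. This was a genuinely open design choice, settled
by the statistics it produces: each bag pour is a short, independent
realization of the local air movement and emission behaviour, and
averaging ~30 repetitions over the shift yields the narrow
shift-average distributions (GSD ≈ 1.13) and the determinant
correlation structure (strongly negative for $\beta$, moderately
positive for $G$) characteristic of this kind of multi-task shift. If
$\beta$ were instead frozen for a whole shift, its wide triangular
range would propagate undiluted into the shift average (GSD ≈ 1.6) —
a materially different, and for this workplace unrealistic, picture.
The scopes remain configurable per parameter in the scenario file for
workplaces where the local airflow genuinely persists across a shift.

Each Monte-Carlo iteration runs on a child seed derived from the root
seed, so any iteration is reproducible in isolation and the whole table
is bitwise reproducible.

## Exposure statistics

* **GM/GSD** use the sample ($n-1$) standard deviation of logs, the
  convention for exposure statistics.
* **Percentiles** use the type-7 linear-interpolation quantile
  (position $(n-1)p + 1$), fixed package-wide.
* **8-h TWA** divides by 480 min with zero exposure outside the
  modelled ~150-min shift.
* **Per-substance TWA** attributes strictly by task window. Residual
  tails (TiO$_2$ still airborne during the Micro Mica tasks) are
  credited to the later task's substance; this cross-contamination is
  accepted and documented rather than deconvolved.

## Sensitivity analyses

*Job sensitivity* asks which task drives the shift exposure. The share
of the average is each task's mean TWA contribution, normalized. The
share of variability is the covariance decomposition
$\mathrm{Cov}(X_k, S)/\mathrm{Var}(S)$ of the per-iteration TWA
$S = \sum_k X_k$: it always sums to 100% and attributes between-task
covariances proportionally. *Task sensitivity* correlates each sampled
determinant (its per-iteration task mean, the only scalar summary
available once determinants vary within a task) with the task's average
concentration via Spearman rank correlation, and reports variability
shares as normalized squared correlations. Both decompositions are
choices among defensible alternatives (rank-based shares ignore
interaction structure; the covariance decomposition includes it); they
are documented here precisely because different simulators use slightly
different formulas, and a few percentage points of disagreement between
implementations is expected. Constant determinants are excluded and
flagged — a fixed parameter contributes to the magnitude of the
estimate but not to its variability.

## Estimating parameters from stationary traces

With no emission and a comparatively clean FF, the NF concentration
decays as $e^{-(\beta/V_{NF})t}$, so `fit_decay()` runs a log-linear
OLS over a user-chosen window (peak selection is manual by design) and
`beta_from_decay()` converts $\lambda$ to $\beta = \lambda V_{NF}$.
Log-linear OLS was preferred to nonlinear least squares because the
multiplicative error model makes the log-residuals homoscedastic and
gives a closed-form estimator with exact confidence intervals. An
optional constant background is subtracted before the log transform,
with validation that all windowed values stay positive. Because the
model is linear in $G$, `back_calculate_G()` inverts it by simulating
the schedule once at unit emission rate and scaling — no optimization,
and exact on noiseless data.

## Compliance logic

The model-based screening verdict follows the 10%-of-OELV rule for the
95th percentile, with a *strict* inequality (exactly 10% already
triggers verification) as the precautionary reading. Re-measurement
intervals use left-closed brackets (a GM at exactly 0.1 OELV gets the
24-month, not the 36-month, interval). The statistical test for six or
more measurements computes the 70% upper confidence limit of the
lognormal 95th percentile with the noncentral-$t$ tolerance factor
$k = t'_{0.70,\,n-1}(\delta = z_{0.95}\sqrt n)/\sqrt n$, the standard
construction when the relevant standard's tables are not at hand; $k$
decreases to $z_{0.95} = 1.645$ as $n \to \infty$ and the UCL never
falls below the point estimate of the 95th percentile.

## Synthetic data

`generate_trace()` emulates a stationary optical dust monitor:
the exact model output with per-point multiplicative lognormal noise
(instrument error is proportional to the reading, and concentrations
stay positive — an additive Gaussian model would violate both) plus an
optional constant background. `generate_measurement_set()` draws
i.i.d. lognormal personal measurements for the compliance tests. What
the generator deliberately does *not* emulate: instrument drift and
calibration (density) error, non-constant backgrounds from other
sources, incomplete mixing within a zone, worker movement between
zones, and particle-size-dependent losses. Passing recovery tests on
these synthetic traces therefore demonstrates correctness of the
estimators under the model's own error structure, not robustness to
every failure mode of real field data.

## Problem sizes and numerical settings

The default Monte-Carlo size is 10,000 iterations per scenario —
enough to hold the GM stable within ±2% across seeds — and a full
eight-scenario comparison runs in about a minute on one core; the test
suite and the analysis scripts use this full size. Tolerances used in
validation: $10^{-6}$ relative against ODE oracles, $10^{-9}$ for mass
balance and the shift-average reconstruction identity, machine
precision for linearity in $G$.

## Known limitations

Two zones only (multi-source industrial halls may need more
compartments); no aerosol physics (deposition, coagulation,
size-dependent losses); no correlated determinant sampling; AER fixed
within a segment; the worker is assumed to stay in the NF for the
whole shift, so predicted NF averages are an upper-bound surrogate for
personal exposure rather than a breathing-zone measurement; and
emission rates estimated with precautionary NF parametrizations carry
that conservatism through to the predicted concentrations.
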