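# twozone

Probabilistic Near-Field/Far-Field (two-zone) occupational exposure
modelling for multi-task work shifts.

Occupational hygienists assessing Conditions of Use for a chemical
process — e.g. under REACH or for EN 689 exposure compliance — need
exposure estimates for every relevant combination of operational
conditions, far more combinations than can realistically be measured
with personal samplers. `twozone` answers this with a mechanistic
mass-balance model driven by Monte-Carlo sampling of the exposure
determinants: simulate the shift thousands of times under sampled
conditions, summarize the exposure distribution, find out which tasks
and determinants drive it, and screen the result against occupational
exposure limit values (OELVs).

## The model

The room volume is split into a small well-mixed Near-Field (NF) of
volume $V_{NF}$ enclosing the source and the worker, and the remaining
Far-Field (FF), $V_{FF} = V_{room} - V_{NF}$. With emission rate $G$
(mg/min) into the NF, inter-zonal air mixing $\beta$ (m³/min), general
ventilation $Q = AER \cdot V_{room}/60$ (m³/min, clean supply,
FF exhaust) and an optional local exhaust $Q_{lev}$ from the NF:

```
V_NF dC_NF/dt = G + (β + Q_lev) (C_FF − C_NF)
V_FF dC_FF/dt = β C_NF − (β + Q) C_FF
```

The package solves this system *exactly* (closed-form
eigen-decomposition per constant-emission segment, analytic time
integrals), chains it over an ordered schedule of pouring repetitions,
and wraps it in:

* seeded sampling of point / uniform / triangular / lognormal
  determinants with configurable per-shift / per-task / per-repetition
  scopes (`run_monte_carlo()`);
* exposure statistics: GM/GSD, percentiles, 8-h TWA in total and per
  substance (`summarize_scenario()`, `twa_8h()`);
* job and task sensitivity analyses: task contributions to the shift
  TWA and its variance, Spearman correlations of determinants
  (`job_sensitivity()`, `task_sensitivity()`);
* parameter estimation from stationary traces: exponential-decay fits
  for $\beta$ and emission-rate back-calculation by model inversion
  (`fit_decay()`, `beta_from_decay()`, `back_calculate_G()`);
* risk characterization and EN 689 compliance verdicts
  (`model_risk_verdict()`, `en689_preliminary_test()`,
  `ucl70_p95_lognormal()`, `en689_retest_interval()`);
* a synthetic-data module for testing every stage without field data
  (`generate_trace()`, `generate_measurement_set()`).

Eight ready-made scenarios (`scenario_library()`) describe a
paint-factory powder-pouring shift — TiO₂ from big and small bags,
Micro Mica from small bags, a cleaning phase — and seven
Conditions-of-Use variants (precautionary emission bounds, halved
mixing, reduced ventilation, small and large rooms, a local exhaust,
and a worst case).

## Worked example

```r
library(twozone)

# steady state at the scenario's modal parameters
g <- zone_geometry(V_NF = 1.5, V_room = 1400)
a <- airflow_params(beta = 3.2, AER = 5, V_room = 1400)
unlist(steady_state(G = 0.87, g, a))
#>        C_NF        C_FF
#> 0.279332143 0.007457143

# full pipeline on the observed scenario, 10,000 iterations
report <- run_pipeline("observed", seed = 1)
print(report)
#> Scenario 'observed' (N = 10000 iterations)
#>   shift NF concentration: GM 0.300 mg/m^3, GSD 1.129
#>   percentiles: P5 0.249, P95 0.369, P99 0.410 mg/m^3
#>   8-h TWA: GM 0.092, P95 0.113 mg/m^3
#>     TiO2: TWA GM 0.051, TWA P95 0.070 mg/m^3
#>     MicroMica: TWA GM 0.041, TWA P95 0.051 mg/m^3
#> job sensitivity (percent of average / of variability):
#>   task 1: 30% / 62%
#>   task 2: 25% / 14%
#>   task 3: 43% / 24%
#>   task 4: 1% / 0%
#>   TiO2: TWA P95/OELV = 0.007 -> well_controlled
#>   MicroMica: TWA P95/OELV = 0.010 -> well_controlled
#>   inorganic_dust: TWA P95/OELV = 0.023 -> well_controlled
```

Reading: over a ~150-min shift the worker's NF exposure averages
0.30 mg/m³ geometric mean with a narrow spread (GSD 1.13). Spread over
the 8-h reference period the inorganic-dust TWA is 0.092 mg/m³ — its
95th percentile is 2.3% of the 5 mg/m³ OELV, so the observed scenario
is well-controlled. The Micro Mica task drives the exposure level
(43% of the TWA) while the big-bag task drives its variability (62%).

The `analysis/` directory holds numbered narrative drivers
(`01_observed_scenario.R` … `05_compliance_assessment.R`) that run the
scenario comparison, sensitivity analyses, parameter-estimation
demonstration and compliance assessment, writing tables under
`results/`.

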