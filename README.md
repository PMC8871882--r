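# i2s2r

Simulation and analysis tools for the **I2S2R** interactive-infection model of
online rumor engagement during major public-health emergencies, together with
the density-based role-clustering analysis that motivates its compartments.

## The problem and the model

During an emergency, unverified content on microblogging platforms is driven
by three kinds of engagers: **advocates** (rumor-originating accounts, the
information source), **supporters** (users who both spread and create
unconfirmed content), and **amplifiers** (users who only share it). The I2S2R
model tracks the densities of five population classes on a homogeneous contact
network with mean degree *k*: ignorants *I*, supporter engagers *E_S*,
amplifier engagers *E_A*, and the two immune classes *R_S* and *R_A*, with a
relapse path from *R_A* back to the supporter class. With net
(post-intervention) rates α₁\*, α₂\*, γ₁\*, γ₂\*, θ\*, τ\* — each a base rate
minus a signed intervention adjustment in [−1, 1] — the mean-field equations
are

```
dI/dt   = c − α₁* I·E_S·k − α₂* I·E_A·k − g·I
dE_S/dt = α₁* I·E_S·k − γ₁* E_S·R_S·k − β₁·E_S + θ* E_A·E_S·k + τ* R_A·E_S·k − g·E_S
dE_A/dt = α₂* I·E_A·k − γ₂* E_A·R_A·k − β₂·E_A − θ* E_A·E_S·k − g·E_A
dR_S/dt = γ₁* E_S·R_S·k + β₁·E_S − g·R_S
dR_A/dt = γ₂* E_A·R_A·k + β₂·E_A − τ* R_A·E_S·k − g·R_A
```

with equal population turnover rates *c* = *g*. Six intervention modes adjust
one rate each (hindering: positive bar; persuasion: negative bar on a recovery
rate), at four intensity levels — 24 scenarios in total — and the package
classifies each scenario's effect on the engager peaks, peak times and
extinction times against the no-intervention benchmark.

The package provides:

* `model_parameters()`, `intervention()`, `effective_rates()`, `rumor_rhs()`,
  `rumor_jacobian()` — the parameterization and the mean-field system;
* `integrate_model()` (adaptive Runge–Kutta via deSolve's `ode45`),
  `euler_reference()` (independent first-order oracle),
  `summarize_trajectory()`;
* `benchmark_config()`, `scenario()`, `run_suite()`,
  `compare_to_benchmark()`, `targeted_effect()`, `suite_table()` — the
  24-scenario intervention study;
* `rumor_free_equilibrium()`, `find_equilibria()` — numerical equilibria
  (multi-start Newton with the analytic Jacobian) and local stability from
  Jacobian eigenvalues;
* `cluster_engagers()` (a DBSCAN implementation on z-standardized engagement
  features), `percent_reduction()`, `generate_synthetic_engagers()`,
  `role_feature_means()` — the engager role analysis;
* `run_config()` + `cmd_run()` / `cmd_suite()` / `cmd_stability()` /
  `cmd_cluster()` / `cmd_synth()`, with a thin command-line wrapper in
  `inst/cli/i2s2r`.

## Worked example

```r
library(i2s2r)
cfg  <- benchmark_config()                      # calibrated benchmark
traj <- integrate_model(cfg$initial, cfg$params, horizon = 1000)
summarize_trajectory(traj)
```

```
I2S2R trajectory summary (horizon 1000, extinction threshold 0.0001)
 compartment peak_value peak_time extinction_time descent_rate final_value
           I   0.900000    0.0000     not reached           NA 5.26379e-02
          ES   0.161884   12.5953            33.1   0.00789008 2.03300e-66
          EA   0.836776    3.2434     not reached           NA 4.74320e-03
          RS   0.373075   29.0124     not reached           NA 1.41599e-01
          RA   0.766440 1000.0000     not reached           NA 7.66440e-01
```

The supporter density peaks at 0.162 around t = 12.6 and dies out (falls below
10⁻⁴) by t = 33; the amplifier wave is much larger (peak 0.837 at t = 3.2) and
settles at a small endemic level instead of vanishing. Applying the strongest
supporter-persuasion scenario (mode 3, level 4, i.e. γ̄₁ = −0.04):

```r
suite <- run_suite(list(scenario(3, 4)), horizon = 1000)
compare_to_benchmark(suite$scenarios[["12"]]$summary, suite$benchmark$summary)
```

```
I2S2R effect report vs benchmark (materiality 1%)
 compartment peak_value_change peak_time_change extinction_time_change
          ES        -3.918e-01       -0.3026993                  -0.29
          EA         8.081e-05        0.0003554                     NA
 peak_value_class peak_time_class extinction_class
          lowered        advanced        shortened
        unchanged       unchanged        unchanged
```

Persuading supporters toward immunity cuts their peak by 39% and shortens
their survival time by 29%, while leaving the amplifier wave essentially
untouched — the benchmark comparison machinery turns each scenario run into
these signed changes and three-way classifications.

On the clustering side, `generate_synthetic_engagers()` builds a
density-separated per-user feature table whose group means match the observed
role profile, `cluster_engagers()` recovers the three roles with DBSCAN, and
`percent_reduction()` computes contrasts such as supporters using the "@"
mention feature 36.7% less than advocates.

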