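# foragesim

Simulation and analysis of spatial data-collection ("data-foraging")
strategies in a stylized geologic survey.

Field scientists sampling along a spatial gradient must decide where to
measure and how many replicates to take at each site — a foraging problem
over information rather than food. `foragesim` implements a complete,
seeded pipeline for studying that problem on a single dune transect with
22 labelled locations (dry crest to wet interdune) and up to 10 shear
strength measurements per location. It is aimed at behavioral and
cognitive-science researchers studying sampling heuristics, and at anyone
who needs a reproducible testbed for comparing spatial sampling designs
against a known ground truth.

## What it computes

**Ground truth.** Two competing hypotheses about the soil are encoded as
mean curves of shear strength *y* versus moisture *x*:

```
y = k·x   for x < b        (rising until saturation)
y = a     for x ≥ b        (stabilized strength)
```

with slope *k*, saturation moisture *b*, and stabilized strength *a*;
the *alternative* hypothesis additionally dips by a configurable depth
past saturation before levelling off. Datasets are 22 × 10 replicate
tables drawn from truncated normal noise (strength: sd 2, bound ±2;
moisture: sd 0.5, bound ±1) around these curves, fully reproducible from
one seed.

**Strategies.** Sampling plans are ordered (location, count) steps.
Plans are classified by the two heuristics of interest: *equal spacing*
(average interval discrepancy — sort the between-site intervals, average
the successive differences; ≤ 1 grid step counts as uniform) and the
*magic number* (a constant per-site count).

**Fit.** The piecewise-linear model above is fitted by grid search over
200 candidate breakpoints (through-origin slope below *b*, plateau mean
above), scored by RMSE — the *fitting error*. Fitting every record gives
the *representative fitting error*, the convergence reference.
*Effective coverage* is the fraction of 10 equal moisture bins a sample
has touched.

**Simulation.** Strategies are executed step by step against a dataset,
drawing replicates without replacement, yielding fitting-error /
coverage trajectories; `strategy_error_distribution` runs the
100-iteration heuristic-versus-random Monte-Carlo comparison.

**Behavior.** Participant logs (initial plan + executed steps +
conclusion) are classified for anchoring (no adjustment at all), waiting
versus mid-plan deviation (area-restricted search), magic-number changes,
and conclusion correctness (Type 1 / Type 2 errors), with cohort-level
summaries and exactly-composed synthetic fixture cohorts.

## Worked example

```r
library(foragesim)

d <- generate_dataset(gradient_model("given"), seed = 42)
fit <- fit_piecewise(d)
fit
#> Piecewise fit: k = 2.894, a = 8.964, b = 2.823%; RMSE = 1.337 (n = 220)
```

The fit recovers the generating model (k = 3, a = 9, b = 3 %) up to the
noise: the RMSE of 1.337 is the *representative* error of this dataset —
no strategy sampling fewer measurements can expect to beat it, only to
converge to it.

```r
s <- evenly_spaced_strategy(transect_grid(), 8, 3)
classify_strategy(s)
#> Strategy: 8 locations, 24 measurements; interval discrepancy 0 (equal spacing); magic number 3

log <- execute_strategy(d, s, seed = 1)
tail(fitting_trajectory(log, d), 3)
#>   step n_obs coverage     rmse
#> 6    6    18      0.8 1.386980
#> 7    7    21      0.9 1.460306
#> 8    8    24      1.0 1.396726
```

With 24 of 220 measurements the equally spaced plan already covers 100 %
of the moisture range and its fitting error (1.40) sits near the
representative value (1.34). The Monte-Carlo comparison makes the
heuristic's advantage explicit:

```r
dist_e <- strategy_error_distribution("even:11x3",   d, n_iter = 100, seed = 7)
dist_r <- strategy_error_distribution("random:11x3", d, n_iter = 100, seed = 7)
mean(abs(dist_e$final_errors - dist_e$representative_error))  # 0.138
mean(abs(dist_r$final_errors - dist_r$representative_error))  # 0.144
```

Evenly spaced sampling lands closer to the representative error than
random site selection with the same budget; across master seeds this
ordering holds in the large majority of runs (see the vignette for why
the contrast is tested as a majority-of-seeds property).

A thin command-line wrapper over the same functions ships at
`inst/cli/foragesim.R` with verbs `generate`, `simulate`, `trajectory`,
`experiment`, `cohort` and `fixture`.

## Package layout

- `R/` — synthetic data (`gradient_model`, `noise_model`,
  `generate_dataset`), strategies (`evenly_spaced_strategy`,
  `classify_strategy`, …), fitting (`fit_piecewise`,
  `representative_fitting_error`, `effective_coverage`), simulation
  (`execute_strategy`, `strategy_error_distribution`,
  `run_figure_experiment`), behavior (`classify_adaptation`,
  `cohort_summary`, `make_fixture_cohort`).
- `vignettes/data-foraging-simulation.Rmd` — the model, its assumptions,
  parameter choices and known limitations.
- `tests/testthat/` — unit, property and end-to-end tests, including
  independent brute-force oracles for the fit, the site placement and
  the truncated-normal sampler.
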