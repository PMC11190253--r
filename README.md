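# firthint

Firth-corrected Cox interaction models and simulation-based power for
small studies of predictive biomarkers.

## The problem

A *predictive* biomarker tells you **how** a patient should be treated:
the benefit of an experimental treatment differs between marker levels.
With a failure-time endpoint the standard test is a Cox proportional
hazards model on the binary marker *M*, the binary treatment *T* and
their product,

```
h(t; M, T) = h0(t) · exp(βM·M + βT·T + βI·MT),
```

where exp(βI) = HR_I is the interaction hazard ratio (the ratio of the
treatment hazard ratios at high vs. low marker level), and equivalently
the subgroup form `βM·M + βTM_low·TM_low + βTM_high·TM_high` for the
treatment effect within each marker level.  Biomarker series are small,
and in small samples this model estimates βI with bias, overestimates its
standard error, and fails to converge whenever a marker-treatment cell
has no events (monotone likelihood — the MLE is infinite).  Promising
markers can be abandoned on the basis of such artefacts.

Two simple modifications repair most of it: the **Firth penalty**, which
maximizes `l(β) + ½·log det I(β)` (finite estimates under separation,
first-order bias removed), and **profile-likelihood (PL)** confidence
intervals and tests in place of Wald ones.  `firthint` implements the
whole evaluation loop for biostatisticians who want to check, or plan
for, the small-sample behaviour of these estimators:

- `scenario()`, `scenario_grid()`, `study_presets()` — simulation
  conditions (four-cell multinomial design with margins `p_M`, `p_T` and
  odds ratio `OR_MT`; exponential event and censoring times; 5-year
  administrative censoring), including presets from five published
  breast-cancer studies;
- `simulate_dataset()` — reproducible replicate datasets;
- `cox_fit()`, `wald_ci()`, `profile_ci()`, `lr_test()`, `fit_both()` —
  from-scratch partial-likelihood and Firth-penalized estimation with
  both flavours of inference (broom-style `tidy()`/`glance()` methods);
- `run_scenario()`, `summarize_replicates()` — bias, SE accuracy,
  coverage, type I error / power over thousands of replicates, with
  Monte-Carlo standard errors, in both the converged-only and the
  non-convergence-penalizing sensitivity mode;
- `power_sim()`, `plot_power_curve()` — simulation-based power for the
  interaction test (no closed-form sample-size formula exists for this
  design);
- `replicate_table()`, `printed_results()` — re-run the published
  result tables at desk scale and compare cell by cell.

The numerical core (Breslow partial likelihood, analytic Firth-modified
score, step-bounded Newton with step-halving) is compiled via
Rcpp/RcppArmadillo; a 10000-replicate scenario takes a couple of minutes
on one core.

## A worked example

Simulate one 250-patient study with a harmful, 25%-prevalence marker
(HR_M = 3) and a strong qualitative interaction (HR_I = 0.25, no
treatment effect at low marker level), then fit the Firth-penalized
interaction model:

```r
library(firthint)

s   <- scenario(n = 250, p_M = 0.25, HR_M = 3, HR_T = 1, HR_I = 0.25)
d   <- simulate_dataset(s, replicate = 1)
fit <- cox_fit(d, method = "firth")
fit
#> Cox Firth-penalized fit (interaction parametrization): n = 250, events = 54
#> converged: TRUE (186 iterations)
#> # A tibble: 3 × 5
#>   term  estimate std.error statistic    p.value
#>   <chr>    <dbl>     <dbl>     <dbl>      <dbl>
#> 1 M        1.77      0.366      4.83 0.00000133
#> 2 T        0.496     0.374      1.33 0.185
#> 3 MT      -1.83      0.579     -3.16 0.00158

profile_ci(fit, "MT")
#> # A tibble: 1 × 7
#>   term  estimate pl_lo  pl_hi pl_lo_converged pl_hi_converged     lr_p
#> 1 MT       -1.83 -2.99 -0.740 TRUE            TRUE            0.000915
```

The estimated interaction log hazard ratio is −1.83 (true value
log 0.25 = −1.39), i.e. the treatment looks strongly beneficial only at
the high marker level; the 95% PL interval (−2.99, −0.74) excludes 0 and
the penalized likelihood-ratio p-value is 0.0009.  How often would a
study this size detect the interaction?

```r
power_sim(s, reps = 400, method = "firth", ci = "pl")
#> # A tibble: 1 × 10
#>   power_pct mc_lo_pct mc_hi_pct n_used n_eligible  reps method ci    alpha
#> 1      59.2      54.3      64.1    400        400   400 firth  pl     0.05
```

About 59% power (exact binomial 95% Monte-Carlo interval 54–64%) — a
250-patient study is underpowered even for this large an effect, which
is the package's cautionary tale in one number.

## Command line

A thin wrapper over the same functions:

```sh
Rscript inst/cli/firthint.R simulate --config scenarios.yml --reps 2000 --seed 1 --out out/
Rscript inst/cli/firthint.R power --config scenarios.yml --reps 1000 --method firth --ci pl
Rscript inst/cli/firthint.R replicate-table --table marker_effect --reps 2000
```

Scenario files are YAML key:value documents using the `scenario()` field
names; list-valued keys are crossed into a grid.

See the vignette (`vignettes/biomarker-interaction-simulation.Rmd`) for
the generating model, solver design, and the reasoning behind the
numerical choices.
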