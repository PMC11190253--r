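---
title: "Evaluating Cox interaction models for predictive biomarkers in small studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating Cox interaction models for predictive biomarkers in small studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A predictive biomarker is a characteristic that modifies the relative
benefit of an experimental treatment: patients at one marker level gain
from the treatment while patients at the other level do not.  With a
failure-time endpoint, the standard analysis is a Cox proportional hazards
model on a binary marker `M`, a binary treatment `T` and their product,

h(t; M, T) = h0(t) exp(bM·M + bT·T + bI·MT),

where exp(bI) is the interaction hazard ratio — the ratio of the treatment
hazard ratios at high vs. low marker level.  Biomarker series are usually
small (one or a few hundred patients), and in small samples this model
misbehaves: the interaction estimate is biased, its standard error is
overestimated, and whenever one of the four marker-treatment cells has no
events the partial likelihood is monotone and the maximum-likelihood
estimate is infinite, so the fit does not converge at all.

`firthint` packages the machinery needed to study — and plan around —
this behaviour: a synthetic-data generator for the four-cell design, a
from-scratch Cox estimator with an optional Firth penalty, Wald and
profile-likelihood (PL) inference, the standard Monte-Carlo performance
measures, and a scenario runner / power calculator.

## Generating model

Each simulated subject is assigned to one of the four (marker, treatment)
cells by a multinomial draw.  The cell distribution is the unique
bivariate Bernoulli law with margins `p_M`, `p_T` and odds ratio `OR_MT`
(Plackett construction): for `OR_MT = 1` the independence table, otherwise
the admissible root of the quadratic that the odds-ratio constraint
imposes on `p_11`.  `cell_probabilities()` exposes it, and a property
test confirms the margins and odds ratio round-trip to 1e-8.

Event times are exponential by inverse transform,

t_e = −log(U) / (λ_e · exp(bM·M + bT·T + bI·MT)),

with λ_e = −log(1 − p_e)/t_end so that a fraction `p_e` of baseline
subjects (M = 0, T = 0) has an event by the end of follow-up `t_end`.
Censoring times are exponential with rate λ_c built the same way from
`p_c`, independent of `M` and `T` (non-differential censoring); `p_c = 0`
means no random censoring.  Everyone still at risk at `t_end` is
administratively censored, so observed times never exceed `t_end` and
many subjects share the censoring time `t_end` exactly.  Uniform draws
are confined to the open interval (0, 1) so all latent times are finite
and strictly positive.

Default study conditions follow the published grid this package
re-implements: `p_T = 0.5`, `p_e = 0.2`, `t_end = 5` years, `HR_T = 1`
(a qualitative interaction: no treatment effect at low marker level),
with `n`, `p_M`, `p_c`, `OR_MT`, `HR_M` and `HR_I` varied;
`scenario_grid()` enumerates the full 2520-condition cross and
`study_presets()` carries five parameter sets extracted from real breast
cancer studies.

What the generator deliberately does not emulate: covariates beyond `M`
and `T` (no confounding or prognostic adjustment), non-exponential
baseline hazards, time-varying effects, informative censoring, staggered
accrual.  Passing tests therefore speak to the behaviour of the
estimators under clean proportional-hazards data, not to robustness
against violations of those assumptions.

### Reproducibility scheme

One master seed spawns a dedicated substream per (scenario, replicate):
the seed of replicate *r* is a fixed arithmetic combination of a
polynomial hash of the scenario's canonical key, the master seed and *r*,
reduced mod 2^31 − 1.  Any replicate can be regenerated in isolation,
runs are bit-identical across repeats, and replicate results do not
depend on execution order.

## Estimation

`cox_fit()` maximizes the Breslow partial likelihood from scratch.  Ties
need no special treatment: event times are continuous (exact ties have
probability zero) and the mass of ties at `t_end` are all censored;
subjects censored at *t* are kept at risk for events at *t*.

The Firth method (`method = "firth"`) maximizes the penalized objective

l*(β) = l(β) + ½ log det I(β),

where I(β) is the observed information.  The penalty removes the leading
small-sample bias of the estimates and, crucially, keeps them finite
under monotone likelihood.  The modified score adds
½ tr(I⁻¹ ∂I/∂β_j) to each score component; ∂I/∂β_j is computed from
analytic third-moment risk-set sums (validated against central
differences in the tests), not numerically.

### Solver

Newton–Raphson from β = 0 with two guards:

* **Step bound.**  Each Newton increment is rescaled, if necessary, so
  that its largest coordinate is `maxstep` (default 0.01 on the log
  hazard-ratio scale).  Rescaling the whole vector preserves the ascent
  property of the Newton direction; clipping coordinates independently
  does not, and in experiments it left fits stuck at non-stationary
  points that would then be miscounted as non-converged.  The small bound
  is deliberate: together with `maxiter = 1000` it is what makes
  "non-convergence" a meaningful diagnosis of monotone likelihood — a
  diverging coefficient can travel at most `maxiter × maxstep = 10` log
  hazard-ratio units, so separation shows up as a fit that exhausts its
  budget with a non-zero score rather than as an overflow.
* **Step halving.**  The information matrix underestimates the curvature
  of the *penalized* objective (in a two-subject closed-form case the
  penalty contributes half of it), so an unguarded step can overshoot
  and cycle.  A step that fails to increase the objective is halved, up
  to 12 times.

Convergence is declared when the maximum absolute component of the
(modified) score falls below `tol = 1e-6` within the step budget; the
iteration count is reported.  This makes "converged" a statement about
the score, with the published iteration-budget reading recovered as a
consequence.  Standard errors come from the inverse observed information
at the optimum for both methods (the penalized objective's exact Hessian
differs from I(β) by penalty-curvature terms; using I(β) matches standard
penalized-Cox practice).

### Inference

* **Wald:** β̂ ± z·se on the log hazard-ratio scale, p-value from the
  normal reference.
* **Profile likelihood:** the confidence set
  {b : 2[obj(β̂) − obj_profile(b)] ≤ χ²₁(0.95)}, with the *penalized*
  objective profiled for Firth fits.  `profile_ci()` locates the two
  bounds by outward bracketing (doubling steps of one Wald SE) and a
  bracketed root-finder to 1e-6; a bound not bracketed within 50 log
  hazard-ratio units of the estimate is flagged non-converged.  The
  associated test is the (penalized) likelihood-ratio test of β_j = 0
  against χ²₁; this is what "PL power" means throughout.

In the mass simulation the runner never root-finds the CI bounds: whether
the PL interval covers a value *b* is equivalent to the profile deviance
at *b* being below the χ² critical value, so coverage and rejection need
only two inner profile fits per coefficient (at the true value and at
zero).  For a concave profile the two formulations are identical; the
penalized profile is not guaranteed concave in pathological cases, but
the bounded search region makes a practical difference vanishingly rare.
"Bound convergence" maps onto convergence of the inner profile fit at the
evaluated point.  This is a deliberate reading of an ambiguity in the
source material: the reference engine tallies failures of its iterative
bound search, which can exclude a handful of flat-profile
(near-separation) replicates that the deviance test retains; both PL
denominators are reported in the summaries.

Both parametrizations of the model are fitted per replicate: the
interaction form (M, T, MT) for inference on bI, and the subgroup form
(M, TM_low, TM_high) whose last two coefficients are the treatment
effects within each marker level (truths log HR_T and
log HR_T + log HR_I).  Under plain partial likelihood the two fits are
exact reparametrizations; under the Firth penalty they are not (the
penalty is not invariant), so each fit carries its own convergence
status and the discrepancy is observable rather than assumed away.

## Performance measures

`summarize_replicates()` computes, per method and coefficient: bias and
relative bias (relative bias is undefined and reported `NA` when the true
coefficient is 0 — the subgroup treatment effect at low marker level
under the default `HR_T = 1`), model SE (root mean of variance
estimates) vs. empirical SE (SD of estimates) as the percentage error
100(ModSE/EmpSE − 1), coverage of 95% Wald and PL intervals, and
rejection rates at α = 0.05 (type I error when the truth is 0, power
otherwise; p = α counts as rejection).  Every rate carries a binomial
Monte-Carlo SE and the SE-ratio a jackknife SE, so tolerances in tests
are principled rather than ad hoc.

Datasets with more than one empty marker-treatment event cell are
ineligible and excluded everywhere, before any fitting.  Two summary
modes differ in how non-convergence is handled: `converged_only` divides
by the number of converged fits N_c (the headline convention), while
`sensitivity` keeps all eligible replicates and counts a non-converged
fit as covering the truth and not rejecting the null — the conservative
reading under which the standard Cox model's apparent power collapses in
separation-prone scenarios.

## Numerical and design choices

* Solver defaults `maxiter = 1000`, `maxstep = 0.01`, `tol = 1e-6`;
  all exposed through `cox_control()`.
* Profile bounds: bracketing radius 50 log hazard-ratio units; beyond
  that a hazard ratio is numerically degenerate.
* Deviances are clamped at zero (inner fits can beat the full fit by up
  to the solver tolerance).
* Eligibility counts events, not subjects, per cell; exactly one empty
  cell is allowed (the fit for the other parametrization's coefficients
  may still be informative, and exclusion is reserved for doubly
  degenerate tables).
* Replicate tables default to 2000 replicates per scenario (the
  published tables use 10000); at 2000 the binomial SE of a 50% rate is
  ~1.1 percentage points and every comparison in `replicate_table()`
  reports its own Monte-Carlo SE.  The package's own acceptance checks
  use 1000–10000 replicates per scenario, sizes chosen so a full check
  remains a coffee-break computation on one core.
* The command-line wrapper (`inst/cli/firthint.R`) is a thin veneer over
  `run_scenario()`, `power_sim()` and `replicate_table()`; the R
  functions are the interface of record.

## Known limitations

* Only the four-cell binary design is supported; no covariate
  adjustment, stratification, time-dependent effects, Efron/exact ties,
  or left truncation.
* The Firth fit removes first-order bias but is not unbiased; in
  protective-marker, low-prevalence, small-n corners it still shows
  double-digit relative bias of the interaction coefficient (visible in
  `replicate_table("marker_effect")`).
* The profile-deviance shortcut assumes an effectively concave profile;
  `profile_ci()` is the general tool when that is in doubt.
* Monte-Carlo results at 2000 replicates carry percentage-point noise;
  decisions at the margin (e.g. 80% vs. 81% power) need more replicates.

## A worked power calculation

```{r, eval = FALSE}
library(firthint)

# a plausible design: harmful marker of 25% prevalence, strong
# qualitative interaction, 20% baseline incidence over 5 years
s <- scenario(n = 400, p_M = 0.25, HR_M = 3, HR_T = 1, HR_I = 0.25)
power_sim(s, reps = 1000, method = "firth", ci = "pl")

# how fast does power grow with the study size?
plot_power_curve(s, n_values = c(200, 400, 600, 800), reps = 500,
                 method = "firth", ci = "pl")
```
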