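---
title: "Estimating disability-free life expectancy across birth cohorts with multistate life tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating disability-free life expectancy across birth cohorts with multistate life tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortmslt)
```

## The estimation problem

Panel surveys of the oldest-old (ages 80+) observe each participant's
activities-of-daily-living (ADL) disability status at a handful of
interview waves a few years apart, together with deaths between waves.
From these snapshots we want population summaries of the *lived
experience* between two bounded ages: partial life expectancy (LE, the
expected years lived between, say, ages 80 and 89), and its split into
disability-free life expectancy (DFLE) and disabled life expectancy.
Because older adults recover from and relapse into disability, prevalence
comparisons are misleading; a multistate model that tracks transitions
among *nondisabled*, *disabled*, and *dead* is the appropriate framework.
`cohortmslt` implements that pipeline end to end and, because real
long-running panel studies of this design (such as the CLHLS) are
access-restricted, ships a synthetic-panel generator with known
ground-truth dynamics so every stage can be validated.

Disability follows the Katz ADL definition: needing personal assistance
in one or more of bathing, transferring, dressing, eating, or toileting,
or being incontinent. `derive_disability_state()` implements exactly this
rule; missing items are an error (no item-level imputation is attempted,
and a precoded state column can be supplied instead).

## Pipeline

1. **Person-year expansion** (`expand_person_years()`). Observation
   intervals between waves are converted to one record per whole year of
   exposure. The model is a first-order annual Markov chain, so at most
   one transition is assumed per interval: when the states at the two
   ends differ, the single transition year is drawn uniformly over the
   interval's years. Deaths with a known date are placed
   deterministically in the year containing the date; deaths with unknown
   dates have their year drawn uniformly over the remaining scheduled
   interval. Intervals ending in loss to follow-up contribute nothing
   beyond the last observation. Interval lengths are differences of
   integer ages at interview, matching the annual-probability scale of
   the transition model.

2. **Attrition weighting** (`fit_attrition()`, `analysis_weights()`).
   Dropout is modelled as a sequence of interval-specific events: among
   individuals observed at an interval's first wave, a pooled logistic
   regression relates dropping out before the next wave to sex,
   residence, schooling, the disability state at the interval start, any
   auxiliary predictors, and the sampling weight. A record in interval
   *j* is weighted by the sampling weight divided by the cumulative
   fitted retention probability through interval *j*; the product over
   all intervals is the individual's complete-case probability, so the
   final-interval weight is the classical complete-case
   inverse-probability weight. We chose the sequential-hazard form over a
   single complete-case regression because completeness also depends on
   death (death under observation *is* a complete outcome — down-weighting
   it would bias mortality), which contaminates a one-shot complete-case
   model: in synthetic experiments the one-shot weights over-corrected
   DFLE while the sequential weights are unbiased. Weights are truncated
   at the empirical (1st, 99th) percentiles by default to bound variance;
   truncation is configurable and can be disabled.

3. **Transition modelling** (`fit_ppo()`). Annual transitions are fitted
   by weighted maximum likelihood as a cumulative-logit model on the
   severity ordering nondisabled < disabled < dead, stratified by origin
   state (two fully separate fits). Age enters continuously with a slope
   shared across the two cumulative logits; sex, urban/rural residence,
   and schooling are binary covariates with *logit-specific* coefficients
   — a partial proportional-odds model. The ordering places death as the
   top category of a single severity scale, the only ordering compatible
   with one cumulative model over these outcomes. Age is centered at the
   window's lower bound for numerical stability and interpretable
   intercepts, and integer age at the person-year start is used. The
   optimizer is a step-halved Newton iteration on the analytic gradient
   and observed Hessian (gradient tolerance 1e-8, at most 100
   iterations); fits are deterministic given the data. Unconstrained
   partial proportional-odds models can produce crossing cumulative
   curves; after fitting, category probabilities are checked on the full
   age-by-profile grid, violations within -1e-8 are clamped to zero with
   row renormalization, and larger violations are an error.
   `test_extra_terms()` refits with a quadratic age term and an
   age-by-sex interaction and reports Wald tests with a keep/drop
   recommendation at the 0.05 level, mirroring the usual model-selection
   step of discarding non-significant curvature.

4. **Multistate life table** (`transition_matrices()`,
   `microsimulate()`, `occupancy_oracle()`). The fitted models yield a
   3x3 row-stochastic matrix per age and covariate profile (dead
   absorbing). The primary estimator microsimulates a synthetic cohort
   (100,000 individuals by default) drawn from the weighted observed
   baseline joint distribution of profile and initial state, stepping
   year by year across the window. Occupancy credit uses the standard
   half-year convention: a year without transition credits 1.0 to the
   origin state, a living-to-living transition credits 0.5 to each end,
   and a death year credits 0.5 to the origin state. Whether a death year
   should credit 0, 0.5, or 1 year cannot be resolved from published
   descriptions of comparable analyses, so it is an explicit
   `death_credit` flag (default 0.5) shared by the simulator and the
   oracle. `occupancy_oracle()` computes the exact expectation of the
   same quantities by propagating the baseline distribution through the
   matrices; it is the infinite-*n* limit of the microsimulation and the
   reference every simulation test compares against. Windows are
   inclusive at both ends: ages 80–89 mean ten annual steps, 100–105 six.

5. **Inference** (`bootstrap_dfle()`, `compare_cohorts()`). Confidence
   intervals come from a full-pipeline bootstrap: individuals (with all
   their waves) are resampled with replacement within cohort, and
   weights, expansion (transition placements re-drawn by default, so
   placement uncertainty propagates; a switch freezes them), model fits,
   and microsimulation are re-run per replicate — 499 replicates in the
   reference design. Intervals are the central 95% of the replicate
   distribution under the interpolated quantile rule (index
   1 + p(B−1)). Cohort differences pair replicates by index; the
   two-sided nonparametric p-value is 2·min(#{d≤0}, #{d≥0})/B capped at
   1, with a "< 0.001" label when one side is empty — a convention that
   reproduces the granularity of published tables at B = 499 (smallest
   resolvable p = 0.004). Replicates whose model fit fails are re-drawn
   up to 5 times, then dropped with a warning. The point estimate always
   uses the full sample.

6. **Sensitivity to end-of-life disability**
   (`end_of_life_adjustment()`). The Markov assumption implies that
   someone observed nondisabled who dies before the next wave spent no
   time disabled — unrealistic at these ages. The adjustment reclassifies
   a uniform random fraction of the final-year nondisabled credit as
   disabled for every simulated death out of the nondisabled state:
   totals are conserved exactly, DFLE falls and disabled LE rises by the
   same amount (about 0.25 x death-credit per such death in
   expectation).

## The synthetic-panel generator

`panel_config()`/`generate_panel()` simulate each individual's annual
state path from the configured true transition models, record states only
at the scheduled wave offsets, date deaths uniformly within the death
year, and apply missing-at-random dropout between waves via a logistic
model on covariates. Truth evolves on annual cycles — the estimator's own
model class — so parameter-recovery tests exercise the estimation code,
not model misspecification; note that two annual steps between waves can
still contain double transitions the estimator cannot see, which is
exactly the Markov coarsening the sensitivity analysis probes. An
optional auxiliary binary covariate ("frail") shifts both cumulative
logits of both origin models and feeds the dropout model but is hidden
from the transition model, creating informative attrition that only the
attrition weights can correct. `true_estimates()` returns the exact
life-table quantities a configuration implies (mixing over the auxiliary
covariate), which is the ground truth for bias and coverage experiments.

`default_study_configs()` encodes the paired-cohort design the package
targets: three age groups (80–89, 90–99, 100–105) each observed as an
earlier cohort (waves at +0/+2/+4 years) and a later cohort born ten
years afterwards (waves at +0/+3/+6), with age-group totals 7334, 7705,
and 5481 split near-evenly between the paired cohorts (the exact split is
unpublished, so an even split is assumed). Octogenarian baseline disabled
prevalence is 17.3% (earlier) versus 11.8% (later) as published;
nonagenarian (32%/26%) and centenarian (52%/45%) prevalences are assumed,
rising with age as observed in oldest-old surveys. The covariate mix (57%
women, 62% rural, schooling rarer among women and rural residents) is a
stated assumption in the same spirit. True-model coefficients were
calibrated once — by matching `true_estimates()` output to the published
partial-LE magnitudes (octogenarian totals near 6.4–6.6 years,
nonagenarian near 4, centenarian near 1.4), under plausibility
constraints (mortality higher from the disabled state, annual recovery
below 0.45) — and then frozen; they are calibration choices, not
estimates. Sampling weights default to 1, with a two-stratum
rural-oversampling option to exercise weighted fitting.

What the generator does *not* emulate: the geographic clustering of a
targeted random-sampling design, proxy responses and item missingness,
within-year (sub-annual) transition dynamics by default, and
state-duration dependence. Passing tests therefore demonstrate
correctness of the estimation machinery under the design's own
assumptions, not robustness to every feature of real survey data.

## Validation experiments and problem sizes

The test suite re-derives every stage's behaviour from independent
oracles: closed forms (constant-mortality occupancy
(1−q/2)(1−(1−q)^10)/q; uniform placement frequencies; the interpolated
quantile rule on 1..499), exhaustive enumeration (all 64 ADL item
patterns), reference implementations (`MASS::polr` for the
proportional-odds restriction, within 1e-6 in log-likelihood), and
derivative-free re-optimization on tiny data. Simulation-based checks use
sizes chosen to make their conclusions stable: parameter recovery fits
50,000 person-years on a balanced age-by-profile design with stratified
outcome draws (stratification removes simulation noise, so the check
verifies that fitting inverts the truth rather than re-measuring
multinomial sampling error); the attrition-correction experiment uses
cohorts of 100,000 so the weighted/unweighted error ordering is stable
across 20 seeds; bootstrap coverage uses 100 datasets of n = 2,000 with
B = 99 and 20,000-person microsimulations, a scaled-down design whose
coverage is expected between 88 and 99 of 100. The microsimulation is
checked against the exact oracle on 20 random matrix sets at n = 100,000
within 3 Monte-Carlo standard errors.

## Numerical and design choices

- **Reproducibility.** Every stochastic entry point takes an explicit
  integer seed and restores the caller's RNG state. Expansion,
  microsimulation, and bootstrap seeds are separate, derived from a
  master seed, and logged in estimates and the `run_analysis()`
  manifest. The microsimulation uses one seeded vectorized stream rather
  than per-individual substreams; results are reproducible given the
  seed, which we judged sufficient without a counter-based generator.
- **Degenerate inputs.** Empty outcome categories, perfect separation in
  the attrition model, zero-year observation gaps, observations after
  death, and crossing cumulative curves all raise informative errors
  rather than producing silent numbers. A panel with no dropout yields
  an identity attrition model with all weights 1.
- **Display conventions.** Differences and p-values are computed from
  unrounded estimates and rounded only for display (2 decimals); a
  rounded total may differ from the rounded sum of its parts by 0.01,
  which `cohort_table()` flags in a note rather than "fixing".
- **Resampling unit.** The bootstrap resamples individuals, never
  person-years, preserving within-person correlation.

## Limitations

Transition probabilities are not state-duration-dependent, and only one
transition per observation interval is recoverable; both are inherent to
the first-order annual Markov design. The partial proportional-odds
model treats death as the top of a single severity scale rather than a
competing risk (a multinomial fallback is deliberately out of scope for
the default analysis). Cross-sectional sampling weights are an imperfect
stand-in for cohort weights, so weighted estimates represent the study
cohort rather than the national population. Estimates of partial total
LE are less precise than dedicated survival models would give — the
design prioritizes the disability split.
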