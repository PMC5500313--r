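---
title: "Projecting disability and health expectancy with a ten-state Markov model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting disability and health expectancy with a ten-state Markov model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthproj)
```

## The model

`healthproj` implements a discrete-time, expected-value cohort model of a
national adult population. Every person aged 35–100 occupies one of ten
states: the eight combinations of cardiovascular disease (CVD), cognitive
impairment and moderate-to-severe ADL disability, plus two absorbing death
states (CVD and non-CVD causes). Dementia is not a separate flag: it is
*defined* as the coexistence of cognitive impairment and ADL disability, so
`DIS_DEM` and `DIS_CVD_DEM` are the dementia states. The four disabled
states map one-to-one onto four disability aetiologies (CVD-related,
dementia-related, both, other disease-related).

Each annual cycle, every (age, sex) occupancy vector is multiplied by its
own 10 × 10 row-stochastic transition matrix for the current calendar
year; survivors then age by one year, survivors at age 100 pool back into
age 100 (the cap age is open-ended and reuses its own matrix until death),
and a new cohort of entrants joins the disease-free state at age 35. Counts
are real-valued: Monte Carlo variation enters through parameter sampling,
never through demographic stochasticity.

Three conventions deserve emphasis because the published literature on such
models rarely states them:

* **Cycle order.** Transition first (with the current-age matrix), then age
  increment, then entrant injection. A person aged *a* therefore
  experiences the age-*a* hazards during the year. The order is fixed and
  documented rather than configurable.
* **Death bookkeeping.** New deaths are credited to the age the person had
  at the start of the fatal cycle and never move again, so every
  (age, death-state) cell is cumulative and monotone. This makes period
  death probabilities recoverable from any two consecutive trajectory
  years: `q_a` = death increment at age *a* / alive at age *a*.
* **Conservation.** Alive + cumulative deaths grows exactly by the
  entrants added; every step asserts this to 1 × 10⁻⁶ relative tolerance
  and refuses to continue otherwise.

## Transition schedules and masks

Schedules are stored as long delimited tables (`age, sex, year, from_state,
to_state, probability`), the finest-grained diffable representation, with
probabilities printed to 12 significant digits so a write → read cycle is a
fixed point byte for byte. Validation is strict and non-repairing: rows
must sum to 1 within 1 × 10⁻⁹, death rows must be identity, masked arcs
must be exactly zero; violations are reported with their coordinates, never
silently renormalised on load.

Which alive-to-alive arcs a model permits is an open design question — no
canonical arc list exists for this class of model — so the package ships
two presets and accepts any mask. `permissive` allows every alive-to-alive
move. `progressive`, the default, additionally forbids remission arcs:
established CVD is never lost, and the dementia states cannot lose
cognitive impairment. Disability-only remission stays open because ADL
limitation can be transient, and cognitive recovery without dementia
(`CIND → FREE`) stays open because single-wave misclassification is common
in practice. Both presets keep both death states reachable from every alive
state.

## Calendar trends

Trends act on four arc families derived from state attributes: dementia
incidence (alive non-dementia → dementia), CVD incidence (alive non-CVD →
CVD), CVD mortality and non-CVD mortality. A rate *r* maps year *y* to the
multiplier $(1-r)^{y-y_0}$. Defaults: dementia incidence declines 2.7% per
year (scenario presets `constant` = 0% and `fast` = 4% bracket it); CVD
incidence is tied to the CVD mortality decline, which is deliberately a
required argument with no default — the user must state it (synthetic
presets use 2%/year); non-CVD mortality is untrended by default because no
defensible default exists.

Scaling is multiplicative on probabilities, not hazards: the model is
discrete and annual, the trended arcs are small, and the distinction is
second order; a `scale_on = "hazard"` flag provides
$p' = 1-(1-p)^{f}$ scaling for sensitivity checks. After scaling, the
row's self-transition absorbs the entire residual — people who avoid an
incident event remain where they are; spreading the residual over other
arcs would invent flows. An arc that gains CVD and dementia in the same
cycle belongs to both incidence families and receives the product of both
factors. If scaling would drive a self-transition negative the operation
aborts naming the coordinate.

## Life tables and the Sullivan method

Period death probabilities and cross-sectional disability prevalence are
read from each calendar year of the trajectory; a life table with radix
100 000 is built with $a_x = 0.5$ at every age (there is no infant
correction to make from age 35), and remaining life expectancy at 65 is
split as

$$\mathrm{DFLE} = \frac{\sum_{a \ge 65}(1-\pi_a)L_a}{l_{65}}, \qquad
  \mathrm{DLE} = \frac{\sum_{a \ge 65}\pi_a L_a}{l_{65}},$$

which add to total life expectancy *exactly* by construction. The terminal
age is open-ended: $L_{100} = l_{100}/m_{100}$ with the central death rate
obtained from the terminal probability by $m = -\ln(1-q)$ (so $q=1$ closes
the interval with zero tail, and $q=0$ is rejected as unbounded). The
Sullivan method is period-based by definition, so each year's $q$ and
$\pi$ come from that year's cross-section, not from cohort follow-up.

An independent oracle guards this arithmetic: `expected_sojourn()` computes
the absorbing-Markov-chain expectation of years spent in any state subset
by forward recursion plus a closed-form geometric tail (fundamental matrix)
at the cap. Under start-of-interval counting the chain credits no part of
the death year while the life table credits half of it, so on toys with
state-independent mortality the two routes agree up to the $a_x$
convention: exactly on degenerate ($q \in \{0,1\}$) toys, within half a
year otherwise. The test suite asserts both.

Reporting conventions: counts in thousands, prevalence and proportions in
percent; all internal arithmetic is unrounded and rounding to one decimal
happens only at presentation, which is why a published relative change can
legitimately differ in the last digit from the same change recomputed from
rounded table entries.

## Age standardisation

Direct standardisation over the single-year (age, sex) grid:
$100 \sum w_{as}\,\mathrm{prev}_{as} / \sum w_{as}$. Single-year weights
are the finest faithful choice when the reference banding is unstated;
sex-combined figures standardise over the joint grid. An age with positive
weight but nobody alive has undefined prevalence; it is excluded from both
sums and logged, never imputed. The age band is an explicit argument, so
both a truncated-at-65 standard and a re-weighted full grid are
expressible.

## Uncertainty analysis

The probabilistic sensitivity analysis samples each (age, sex, year,
from-state) row from a Dirichlet distribution with concentration
`central × ESS`. The Dirichlet family is chosen because every draw is a
valid stochastic row and structural zeros (masked arcs, death-row
off-diagonals) remain exactly zero; the effective sample size is exposed in
configuration (default 1000) since no canonical dispersion exists for
synthetic data. Child seeds are derived from the master seed by a
counter-based splitting scheme, so iterations are order-insensitive and
replayable individually; a failed iteration aborts with its index and seed.
Intervals are 2.5th/97.5th linear-interpolation percentiles of 1000
iterations by default, and the reported point estimate is the central
(unsampled) run, not the iteration mean.

## The synthetic-data generator

No public transition-probability schedule exists for this class of model,
so the package generates coherent stand-ins with controllable ground truth.
Mortality hazards are Gompertz in age by sex and cause; incidence hazards
for CVD, cognitive impairment and disability are logistic in age, with
hazard-ratio links (CVD death × 4 given CVD; non-CVD death × 2.6 given
disability, × 3.6 given dementia; disability incidence × 1.5 given CVD,
× 2 given cognitive impairment). Hazards combine by competing-risk
arithmetic — death probabilities split proportionally to cause hazards,
attribute gains multiply conditionally on survival — so every generated row
sums to 1 exactly and probabilities can never exceed 1. Calendar trends are
applied through the same `apply_trends()` machinery the scenario layer
uses, which makes the construction identity exact: a dementia-incidence arc
at year $y_0+k$ equals its base value times $0.973^k$, and `recover_trend()`
(a probability-weighted log-linear fit with one intercept per arc cell;
weighting is what keeps tiny arcs from biasing the slope under sampling
noise) returns the planted rate to machine precision on noiseless
schedules.

Default shapes were chosen once so the synthetic world is demographically
recognisable: disability prevalence around 13% at ages 65–69 rising past
40% at 90+, a standardised ≥65 prevalence in the low twenties of percent,
life expectancy at 65 near two decades, and entry cohorts of 190 000 per
sex per year (the order of a national single-year cohort). The generator
emulates age gradients, sex differentials, state-linked mortality and
calendar trends; it does **not** emulate longitudinal-survey wave
structure, attrition, sampling weights, cohort-size waves (entrants are
constant, so it shows none of the ageing-bulge growth a real population
projection would), or migration. Tests passing on synthetic data therefore
demonstrate the *machinery* — conservation, additivity, trend recovery,
interval coverage — not agreement with any observed population.

## Problem sizes and performance

The shipped configuration runs 66 ages × 2 sexes × 20 years
(26 400 transition matrices) in well under a second per projection. The
test suite's full-size sensitivity analysis uses 1000 iterations on a
reduced grid (ages 60–100, with the Gompertz baselines rescaled so the
hazard level at 60 matches the full curve), which keeps a complete PSA
around twenty seconds; statistical checks (Dirichlet trend recovery at
ESS 10⁴) use fixed seed sets so they are exactly reproducible.

## Known limitations

* Entrants are exogenous and constant by default; the model has no
  fertility or migration above the entry age.
* The binary disability definition ignores severity grading.
* Counts are expectations; finite-population variance is not modelled.
* The `progressive` mask is a clinically motivated stand-in, not a claim
  about any estimated arc structure; rerun with `permissive` or a custom
  mask to test sensitivity.
* Trend recovery assumes log-linear decay; it will average, not detect,
  non-log-linear calendar structure.
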