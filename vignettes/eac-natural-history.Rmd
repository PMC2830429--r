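---
title: "Modeling and calibrating the natural history of esophageal adenocarcinoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and calibrating the natural history of esophageal adenocarcinoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eacsim)
```

## The disease model

`eacsim` implements a deterministic annual-cycle Markov cohort model of
esophageal adenocarcinoma (EAC) in U.S. white males. A birth cohort enters
the model at age 20 with all mass in the *Normal* state and moves through
seven ordered health states: Normal, GERD symptoms, Barrett's esophagus
(split into short-segment SSBE and long-segment LSBE), undetected cancer,
clinically detected cancer, and death. Transitions only move forward in
this order (no regression), with one shortcut: Normal can progress
directly to Barrett's esophagus, because a substantial share of BE
patients never report reflux symptoms. Death is absorbing; pre-cancer
states die at age-dependent all-cause rates, and both cancer states carry
cancer-specific mortality by default (a switch,
`eac_demography(cancer_mortality = c(undetected = NA, detected = ...))`,
keeps all-cause mortality in the unobservable undetected state instead —
clinically the more optimistic reading; we default to the more
conservative cancer-specific variant and expose the alternative).

Structural constants: incident BE is long-segment with probability 0.25
(a 1:3 LSBE:SSBE ratio), and SSBE progresses to cancer at half the LSBE
rate (a surface-area argument). These ratios are fixed, not calibrated.

The calibrated unknowns are: annual probabilities Normal→GERD,
Normal→BE, and GERD→BE, each piecewise-constant over the six ten-year age
groups 20–29 … 70–79 (one free value per group and transition — the
age-group resolution of the targets is the natural resolution for the
parameters); the base LSBE→undetected-cancer probability `r_lsbe_ca`
(anchored at calendar year 1973); the slope of a linear secular
multiplier `m(y) = max(0, 1 + slope * (y - 1973))` on that transition
(the only transition allowed a calendar-time trend: BE prevalence and the
cancer-detection rate are assumed stable, so the rising incidence must
enter between them); and the mean sojourn time of undetected cancer,
bounded to its literature range of 4–9 years and converted to an annual
detection probability under an exponential waiting-time convention,
`p = 1 - exp(-1 / T)`.

Ages above 79 reuse the oldest group's transition probabilities; cohorts
leave the reporting population after age 79, matching the 20–79 span of
the targets.

### Numerical conventions

* Cycle length is one year with no half-cycle correction, matching the
  annual-probability granularity of the inputs.
* Cohorts are propagated as expected fractions (a deterministic cohort
  model, not a microsimulation): the reported outputs are population
  rates, for which expectations are sufficient, and a noise-free
  objective makes calibration far better behaved.
* Competing risks within a cycle resolve death first, then distribute
  disease transitions among survivors in proportion to their annual
  probabilities, rescaled proportionally if they sum above one.
* Calendar-year cross-sections stack one unit-mass birth cohort per entry
  year (a stationary population); prevalences are percentages of the
  alive mass at the start of the year, incidence is detections during the
  year per 100,000 alive at the start of the year.
* Two independent code paths exist for propagation — explicit 7×7
  transition matrices for single cohorts, and a vectorized multi-cohort
  stepper for population runs — and the test suite holds them to
  agreement at 1e-10 against matrix-power oracles.

## Calibration targets

The built-in `representative_year_targets()` carries the representative-year (1986)
targets: age-specific EAC incidence per 100,000, BE prevalence, and
GERD-symptom prevalence for the six age groups. The prevalence targets
are treated as constant over calendar time; the incidence row is anchored
to 1986. Users with a SEER-style extract can supply the full 1973–2000
incidence grid via `load_incidence_csv()` and calibrate over the whole
window, reserving 2001–2005 for hold-out validation.

Because a single representative year cannot separate the secular slope
from the base progression rate (only their product is observed), the
default bounds freeze the slope at zero in representative-year mode;
multi-year targets free it.

## Goodness of fit

Model-target discrepancy is a Pearson-style chi-squared score per
endpoint, `sum((O - M)^2 / max(O, eps))`, summed over every (year, age
group) cell, with endpoint weights defaulting to 1. The denominator floor
`eps = 0.5` (in the endpoint's own units) keeps the score defined at the
printed zero target (incidence 0.0 at ages 20–29); it only affects
targets below 0.5. Time-constant prevalence targets are expanded to one
entry per calibration year, so in multi-year calibrations each year
contributes.

## Search: simulated annealing

The parameter search is a simulated-annealing minimizer over box bounds,
recording every evaluation. Design choices, all configurable through
`sa_config()`:

* **Bounds.** Derived from the target magnitudes: GERD prevalence near
  18% by the mid-20s implies a youngest-group Normal→GERD probability
  around 4%/yr, capped at 0.10; BE prevalences of 2–6% accumulated over
  six adult decades imply feeder transitions of order 0.1%/yr, capped at
  0.01; incidence of order 10 per 100,000 from a ~5% BE pool implies
  progression rates of order 1%/yr, capped at 0.05; sojourn time 4–9
  years.
* **Proposals.** A mixture kernel: single-parameter uniform steps of
  half-width `proposal_width` × the bound width, reflected at the bounds
  (optionally shrinking with the square root of the relative temperature,
  `adapt_width`); with probability `jump_prob` a full-range uniform
  redraw of the chosen parameter; with probability `vector_prob` a joint
  small step in every free parameter. The redraw component is essential
  to the bound-narrowing step below: a parameter the current endpoint
  does not constrain accepts redraws freely and keeps a wide
  best-fraction envelope, while a constrained parameter rejects them and
  narrows honestly. Without it, the envelope of an autocorrelated chain
  freezes unconstrained parameters at arbitrary values.
* **Schedule.** The evaluation budget is split into independent annealing
  segments (restarts), each starting from a fresh uniform draw with the
  temperature reset; multi-start keeps the retained best fraction
  representative of every solution family the search finds. Within a
  segment, the initial temperature is `"AUTO"` (median absolute score
  difference among 50 random parameter pairs) and cools geometrically by
  0.9 over 100 steps per segment, so the schedule is invariant to the run
  length. An optional temperature floor (`floor_frac` × (1 + best score
  so far)) stops a converged chain from freezing at a point: it keeps
  sampling the shell of near-optimal fits, which is what makes the
  retained best fraction a spread of comparable fits rather than one
  chain endpoint. A vector of floors is cycled across segments (a floor
  ladder) to sample shells of several widths.
* **Two working profiles.** Calibration for a *best fit* (the
  representative-year runs) uses the optimizer profile: fixed proposal
  width, no temperature floor, 20% redraws; the score is what matters and
  the ensemble is a by-product. Calibration for *ensemble inference*
  (the parameter-recovery experiments, where the scientific claim is
  about the ensemble envelope) uses the sampler profile: adaptive width,
  floor around 2, 80% redraws — deep enough to reach the near-optimal
  basin, hot enough to keep wandering it. Both are `sa_config()`
  settings, not different algorithms.
* **Determinism.** A fixed seed reproduces the evaluation sequence
  bit-for-bit; ties in best-fraction selection break by evaluation order.

## Three-phase sequential calibration

The three endpoints differ greatly in sample size and data quality, so
they are fitted sequentially. Each phase runs a full annealing search;
after phases 1 and 2 the bounds are narrowed to the min–max envelope of
the best 10% of that phase's evaluations. After phase 3, all its
evaluations are re-ranked on the combined three-endpoint score and the
best 1% retained as the calibrated ensemble (1,000 sets at the full
10^5-evaluation scale); the ensemble's min–max parameter spread is the
model's expression of parameter uncertainty.

Two design points deserve explanation:

* **Accumulating phase objectives.** Phase *k* scores the endpoints
  introduced so far rather than its endpoint alone. In our experiments,
  single-endpoint phase objectives let the final phase undo the earlier
  endpoints' fits wherever the narrowed bounds left room, and made the
  final ranking (combined score) a quantity no phase had optimized;
  accumulation removes both problems at identical cost. The final phase
  runs with fewer restarts (`final_restarts`, default 2) than the first
  two: early phases need breadth so the envelopes are representative,
  the last needs depth on the score that decides the ensemble.
* **Endpoint order.** Both the biological *forward* order (GERD → BE →
  EAC) and the *reverse* order (EAC → BE → GERD) are implemented; running
  both and keeping the better combined score is part of the method. The
  package recommends reverse for the representative-year targets on
  structural grounds: with an age-constant BE→cancer rate, the incidence
  age profile is tied to the BE prevalence age profile, and the incidence
  targets rise thirty-fold over age while the BE targets rise
  three-and-a-half-fold. Whichever of the two coupled endpoints is fitted
  *first* claims the shared parameters, and fitting incidence first while
  letting the weakly coupled GERD endpoint come last distributes the
  compromise far better than the converse (in our runs, by roughly an
  order of magnitude in combined score). `scripts/acceptance.R` and the
  desk-scale tests therefore calibrate in reverse order; forward remains
  the function default.

### What the structure can and cannot fit

The age-constant progression rate is a deliberate dimensionality limit.
Its consequence is a structural ceiling: the model cannot reproduce both
the BE prevalence age profile and the full steepness of the incidence age
profile simultaneously, and the combined optimum settles on Barrett's
prevalences below the targets in the youngest groups. Correspondingly the
calibrated overall adult BE prevalence lands below the weighted average
of the age-specific targets. We report this as a known limitation rather
than freeing the progression rate by age, which the target resolution
could not support without overfitting.

A second, arithmetical caveat: the published overall BE prevalence figure
of 4.2% is not reachable as a weighted average of the published
age-specific values (1.7–5.8%) under any plausible adult age structure
(equal weights give 3.73%; the survivorship weights below give ~3.6%).
The overall figure evidently descends from the literature average that
anchored the age-specific regression, not from weighting its outputs.

## Demography and reporting defaults

All demographic inputs are deterministic fixtures, each overridable with
empirical data:

* Life table: Gompertz–Makeham, `q(a) = 1 - exp(-(A + B e^{theta a}))`
  with `A = 5e-4`, `B = 3e-5`, `theta = 0.09` per year — about 0.2%/yr
  mortality at 40 and 2%/yr at 70, a plausible adult white-male profile.
* Cancer mortality: 0.35/yr in both cancer states.
* Standard weights for age adjustment: equal across the six groups.
* Population counts: a stationary 1,000,000 men per single year of age,
  which makes absolute case counts interpretable and deterministic.
* Overall (all-adult) prevalence summaries use the stationary-population
  age distribution implied by the life table, restricted to ages 20–79
  (`adult_age_weights()`); substitute census weights if you have them.

## Hold-out validation

`validate_calibration()` re-simulates every ensemble member over the
calibration and validation year ranges, divides each combined score by
the number of years in its period (the two periods are unequal), and
averages over the ensemble. The model validates when the mean adjusted
validation score is strictly below 150% of the mean adjusted calibration
score.

## The aspirin counterfactual

A chemoprevention program is specified by a five-year cumulative risk
reduction `R5` (base case 50%), a start year (1960, a run-in before the
1973 analysis window) and a start age (40). Under a constant-hazard
assumption the annual reduction is `1 - (1 - R5)^{1/5}` — 0.12945 for the
base case, the "13%" figure. The reduction multiplies the BE→undetected
cancer transition (both segments equally) for every person-year with age
≥ 40 and year ≥ 1960, with full adherence and no cessation.
`run_counterfactual()` simulates each ensemble member with and without
the program, converts incidence to national case counts via the
population counts, and accounts prevented cases per five-year reporting
period (means with ensemble min–max ranges); `sensitivity_sweep()` spans
`R5` from 30% to 70%. Absolute case counts match published national
figures only when historical population counts are supplied; the percent
reductions are scale-free.

## Synthetic targets and what the tests show

`generate_synthetic_targets()` runs the model under a known truth and
emits its outputs as targets, optionally with multiplicative lognormal
noise (mean 1, chosen coefficient of variation — rates are positive and
registry sampling error scales roughly with the rate). With zero noise
the truth scores exactly zero, which anchors the parameter-recovery
tests: a three-age-group, ten-year world (entry ages 20–49, calibration
years 1973–1982, truth with a positive secular slope) calibrated at 5,000
evaluations per phase across five seeds must bracket every true parameter
within the final ensemble's min–max envelope in at least four of the five
seeds. This is a demanding coverage property at desk scale: the retained
ensemble holds only fifty sets (1% of 5,000), and bracketing requires all
twelve marginals of the near-optimal region to be spanned simultaneously;
weakly identified compensation ridges (base progression rate against
sojourn time, the two Barrett's feeder routes) are the coordinates an
undersized ensemble misses first. At the full 10^5-evaluation scale the
ensemble is a thousand sets and coverage is far less binding.

The generator emulates the statistical *structure* of the real targets —
constant prevalences, linearly rising incidence, age-group resolution —
under the same stationary demography the model itself uses. It does not
emulate SEER's sampling design, demographic shifts, cohort effects, or
any age-dependence of progression; passing recovery tests therefore
demonstrates that the calibration machinery can invert the model, not
that the model is true.

Problem sizes in the shipped tests are the package's chosen desk scale:
10,000 annealing evaluations per phase for the representative-year
calibration and 5,000 for the recovery experiments, against the paper-
scale 10^5; the machinery is identical and the counts are configuration,
not code.

## Known limitations

* Single-sex, single-race model; no dysplasia grades, cancer staging,
  costs, or quality-of-life weights. All are deliberate scope limits.
* Age-constant BE→cancer progression bounds the achievable incidence age
  profile (see above).
* The secular trend is a reduced-form linear multiplier, not a
  mechanistic cohort model; it is anchored at 1.0 in 1973 and clamped at
  zero.
* The deterministic engine provides no Monte-Carlo uncertainty; all
  reported ranges derive from the calibrated parameter ensemble.
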