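---
title: "Multistate life tables for disability-free life expectancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate life tables for disability-free life expectancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mslife)
```

## The estimation problem

Ageing surveys observe disability the hard way. A community-dwelling
cohort aged 60+ is interviewed at baseline and again at a couple of
follow-up waves years apart; between interviews the health state is
unobserved. Deaths are ascertained exactly from a civil registry up to an
administrative cut-off, and subjects who are known (from the registry) to
be alive at the cut-off but were not interviewed at the last wave are
right-censored in a specific sense: alive, state unknown. Estimating how
many remaining years are lived with and without disability — and how that
split differs by gender or body-mass-index category — requires a model
that treats all three observation types coherently.

`mslife` implements the standard tool for this design: a continuous-time
three-state Markov ("illness–death with recovery") model with
proportional-hazards covariate effects, followed by integration of the
fitted occupancy probabilities into state-specific life expectancies.

## Model and likelihood

States are 1 = healthy, 2 = functionally limited, 3 = dead (absorbing);
transitions 1→2 (disability incidence), 2→1 (recovery), 1→3 and 2→3
(mortality from each living state). Intensities are log-linear in the
covariates,

$$q_{rs}(z, a) = \exp\!\big(\theta_{rs} + \beta_{\text{age},rs}(a - 70) +
\beta_{\text{f},rs}\,\text{female} + \beta_{\text{ow},rs}\,\text{ow} +
\beta_{\text{ob},rs}\,\text{ob}\big),$$

so each covariate has one hazard ratio $e^\beta$ per transition. Age is a
time-dependent covariate measured in years and centred at 70; the
centring constant is stored with the fit so baseline intensities always
refer to a 70-year-old man of normal BMI.

The functional-limitation state is the composite criterion used for
Chilean older populations: difficulty in at least one of six ADL items,
at least two of five IADL items, or at least three of eleven
mobility-function items. BMI uses the WHO cut-offs with half-open
intervals (lower bound inclusive, so 30.0 is obese). Subjects with
missing baseline anthropometry are excluded first; the underweight
category is then excluded from model fitting entirely — it is far too
sparse (about 1.6% of subjects) to support transition-specific effects,
and excluding it from fitting (not merely from reporting) keeps the
analysis sample consistent across the hazard-ratio and life-expectancy
tables. Both rules are applied by `apply_exclusions()`, which logs counts
and is idempotent.

Within an observation interval $[a_0, a_1]$ the generator is held
constant at its value at $a_0$ (the usual panel-model convention; the
interval matrix exponential is then exact). The three record types
contribute:

* interview at $a_1$ in living state $s$: $P_{rs}(a_0, a_1)$;
* exact death at $a_1$: $\sum_{s \in \{1,2\}} P_{rs}(a_0, a_1)\,
  q_{s3}$, with $q_{s3}$ also evaluated at the interval start for
  consistency with the piecewise-constant approximation;
* censored alive, state unknown: $\sum_{s \in \{1,2\}} P_{rs}(a_0, a_1)$.

Because state 3 is absorbing, the living-state block of the matrix
exponential has a closed form: its $2\times 2$ generator block has real
eigenvalues $m \pm d$ with
$d = \sqrt{((a_{11}-a_{22})/2)^2 + q_{12}q_{21}} \ge 0$, giving
$e^{tA} = e^{mt}\left[\cosh(dt)I + \tfrac{\sinh(dt)}{d}(A - mI)\right]$,
with the series limit $\sinh(x)/x \to 1$ used when $dt < 10^{-6}$. This
is vectorised over all observation intervals, which is what makes the
replicate fits of the recovery benchmark affordable without compiled
code. A test verifies the closed form against a dense Padé matrix
exponential to $10^{-10}$, and the whole likelihood against an
independent discrete-time forward algorithm (0.01-year steps,
second-order per-step matrices) to $10^{-3}$ per subject.

Maximisation is quasi-Newton (BFGS) with numeric derivatives, from
crude-rate initial values (observed transitions over person-time, floored
at $10^{-4}$; covariate effects start at 0). The covariance matrix is the
inverse of the numerically differenced observed information; if that is
singular — which legitimately happens when a covariate–transition
combination has essentially no events — a Moore–Penrose pseudo-inverse is
used with a warning, and the affected hazard ratio is reported with its
(huge) standard error rather than suppressed.

## From fit to life expectancies

`occupancy()` computes $P(a_0, a)$ along an age grid, refreshing the
age-dependent generator at every grid point; `state_expectancies()`
integrates the living-state occupancies by the trapezoidal rule,
$e_{rs} = \int_{a_0}^{a_{\max}} P_{rs}(a_0, a)\,da$. Defaults are a
0.25-year grid up to age 115. The truncation error is monitored: if the
living occupancy at `max_age` exceeds $10^{-3}$ a warning asks for a
larger `max_age`. Sensitivity to the grid is small and testable: on
constant-rate toys a 0.01-year grid reproduces $e_{11} = 1/\mu$ to
$10^{-6}$, and the conservation identities below hold at any step. Users
can pass `grid_step` of 0.1, 0.25 or 0.5 to check their own fits; under
the default truth parameters, total life expectancy at 60 moves by about
0.06 years between the 0.1 and 0.25 grids and about 0.16 years between
0.1 and 0.5 (a test keeps these differences below 0.2 years), so the
0.25-year default trades a ~0.05-year bias for a four-fold speed-up over
0.1.

Published life expectancies of this kind are population (marginal)
quantities, not healthy-start conditionals, so the state-conditional
rows are weighted by the probability of being disabled at the starting
age. That prevalence model is a binary log-odds regression on centred
age and the covariate dummies, fitted to baseline records by direct
Newton maximisation of the Bernoulli likelihood inside the package (a
test checks it against `stats::glm` to $10^{-5}$). Then

$$\text{DFLE} = w_1 e_{11} + w_2 e_{21},\quad
\text{DLE} = w_1 e_{12} + w_2 e_{22},\quad
\text{LE} = \text{DFLE} + \text{DLE},$$

with $w_2 = \pi(\text{age}, z)$. `marginal_life_expectancies(...,
conditional = TRUE)` exposes the healthy-start alternative. The
conservation identity LE = DFLE + DLE and
$\%\text{disabled} = 100\,\text{DLE}/\text{LE}$ hold exactly,
pre-rounding, for point estimates and for every simulation draw — they
are identities of the arithmetic, and the tests enforce them at
$10^{-12}$.

Confidence intervals: `simulate_cis()` draws parameter vectors from
$N(\hat\eta, \hat\Sigma)$, recomputes every quantity per draw, and
reports empirical 2.5/97.5 percentiles (1000 draws by default, matching
common practice for these models). The % disabled interval is formed
per draw as a ratio, not by the delta method. Draws that produce
numerical overflow are rejected and redrawn, with an error if rejections
exceed 10%. The prevalence coefficients are held at their MLE across
draws; their sampling noise is secondary to the transition-parameter
uncertainty at these sample sizes, and keeping the weights fixed makes
the intervals attributable to the multistate fit alone.

## The synthetic cohort

`observe_cohort()` emulates the survey design: baseline ages drawn from
per-sex decade weights (60–69/70–79/80+, the 80+ band uniform up to a
configurable top, default 96), sex and BMI-category frequencies set to
the published baseline composition, two follow-up waves at offsets 4.5
and 9.5 years with per-subject uniform ±0.5-year jitter (interview dates
within a wave are not published; the jitter width is a modelling
choice), administrative censoring at 10.5 years, and per-wave
non-response probabilities (0.42, 0.53) calibrated so the
interviewed/dead/alive-unknown flow resembles the published follow-up
counts. Item counts (ADL/IADL/MF) are drawn consistently with the
latent state at each interview, so the phenotype module can re-derive
the state from raw counts.

Trajectories are simulated forward from the age-dependent generator,
approximated piecewise-constant over 0.1-year micro-steps (bias is
O(step) and the step is configurable); each subject starts healthy five
years before baseline and is conditioned on being alive at baseline, so
baseline disability prevalence rises with age endogenously rather than
being imposed. Each subject owns an independent L'Ecuyer RNG substream:
enlarging a cohort never changes existing subjects, and identical
configurations are byte-identical.

The generating covariate log-hazard-ratios default to the published
point estimates for the Santiago cohort
(`reference_hazard_ratios()`). The four baseline log-intensities are not
published; they were calibrated once so that simulated life expectancy
at 60 lands in the vicinity of the published values (our defaults give
men 16.5 and women 19.1 years against published 16.4 and 20.4), and are
not otherwise tuned — exact reproduction of cohort-level values is not
claimed, nor possible without the microdata.

What the generator deliberately does not emulate: the three-stage
cluster sampling design and survey weights, within-wave interview-date
distributions, item-level response correlation beyond the composite
criterion, BMI drift over follow-up (baseline BMI is a fixed covariate,
as in the published analysis), and misclassification of the interview
state. Passing tests therefore demonstrate correctness of the machinery
and recoverability of effects under the stated design — not robustness
to design features the generator omits.

## Parameter-recovery benchmark

`recovery_study()` generates replicate cohorts of 4000 subjects
(baseline ages 60–90) from the truth above, refits the model, and
summarises recovered hazard ratios by their replicate median. With 25
replicates the well-identified probes — the female and age effects on
disability incidence and the female effect on mortality of the disabled
— come back within a few percent of truth (e.g. 1.789 vs 1.82, 1.0562 vs
1.06, 0.636 vs 0.64 in the seed-1 run of `scripts/acceptance.R`). Effects
resting on almost no events (female and obese effects on healthy→dead,
whose generating hazard ratios are 0.15 and 0.10 on a small baseline
intensity) are not recoverable at this design and drift towards zero
with enormous standard errors; the fit reports them honestly rather than
constraining them.

Problem sizes used in the shipped tests were chosen to exercise each
property at the smallest scale that demonstrates it: ten subjects
against the brute-force likelihood oracle, 150–1216 subjects for fit
properties and pipeline patterns, 1000 vs 8000 subjects for the
error-shrinkage probe, and 25 × 4000 for the recovery benchmark.

## Design choices that were genuinely open

* **Age handling.** Whether the original analysis used age as the time
  scale or as a time-dependent covariate is not stated; we use a
  piecewise-constant time-dependent covariate evaluated at the interval
  start, the common panel-model convention. The exact-death density uses
  the same convention for consistency.
* **Underweight exclusion.** Published tables are consistent with the
  underweight category being excluded from fitting (their n matches the
  post-exclusion count), so the exclusion applies to fitting, not only
  to reporting.
* **Marginal vs conditional totals.** Published totals are treated as
  prevalence-weighted (marginal); the conditional variant is an option.
* **Gender table under a single adjusted fit.** The by-gender table
  averages the six sex × BMI profiles over the sex-specific baseline BMI
  distribution, per draw; the by-BMI table evaluates profiles directly.
  A `stratified` option refits per BMI category for comparison instead
  of relying on proportional covariate effects.
* **All covariates on all transitions.** The published hazard-ratio
  table reports every covariate for every transition, so no effect is
  constrained out.

## Known limitations

Interval estimation is Wald/percentile-based and degrades for effects
with few events; there is no hidden-Markov misclassification layer, no
frailty, no survey-design variance inflation, and no Sullivan-method
cross-check. The piecewise-constant age approximation biases intensities
slightly downward over long intervals (absorbed almost entirely by the
baseline parameters, as the recovery benchmark shows). Life expectancies
are truncated at `max_age`; the truncation diagnostic should be heeded
when modelling low-mortality populations.
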