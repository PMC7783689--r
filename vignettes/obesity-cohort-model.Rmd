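---
title: "Methods: a Markov cohort model of BMI class dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model of BMI class dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmicohort)
```

## The model

`bmicohort` simulates a closed birth cohort moving annually between six health
states — NW1 ("always normal weight"), NW2 ("normal weight, previously
heavier"), overweight (OW), obese grade 1 (OB1), obese grade 2 (OB2) and dead —
from age 2 to age 100. NW1 and NW2 share all parameters (transition
probabilities, costs, mortality); the split exists so that future analyses can
distinguish people who have never been heavier from those who have regressed.
Weight classes are BMI bands: the adult WHO thresholds 25/30/35 kg/m²
(lower-inclusive, so "35+" is OB2), with age- and sex-specific child cutoffs at
ages 2–17. The model has no underweight state; adult BMI below 18 is treated as
NW.

Only one-class moves exist per annual cycle: three progressions (NW→OW,
OW→OB1, OB1→OB2) and three regressions (OB2→OB1, OB1→OW, OW→NW), plus death
from every live state. OW regression feeds NW2, never NW1. Within a cycle,
death is applied first and the surviving mass is split among the BMI moves;
the stay-probability absorbs the remainder so every row of the transition
matrix sums to one exactly. The ordering is a modelling choice (the mortality
rate applies to the state held at cycle start); it is not identified by the
data.

## Transition probabilities from survival curves

The six transition intensities are estimated by parametric survival analysis
of longitudinal height/weight records, in three age bands — childhood
(estimation ages 2–13), adolescence (13–30) and adulthood (20+) — spliced into
one annual schedule: child fit at ages 2–12, adolescent fit at 13–19, adult
fit from 20. Each band has its own survival clock with origin at the band
entry age (2, 13, 20). The annual transition probability at age $a$ is the
conditional one-cycle event probability

$$p(a) = \frac{S(t) - S(t+1)}{S(t)}, \qquad t = a - \text{entry age},$$

where $S$ is the fitted survival function. Six families are supported —
exponential, Weibull, log-normal, log-logistic, Gompertz and generalized
gamma — with parameters on their natural scales (see `?parametric_model`).
Family choice is by AIC or BIC on the pooled two-sex records; the selected
family is then refitted per sex, so both sexes always share a specification.

Raw survey records are sparse (roughly annual visits in childhood, 4–11 year
gaps later), so height and weight are first interpolated to every integer age:
weight linearly between measurements, height linearly up to a plateau age
(default 18) and constant after. The annual class series is then restructured
into left-truncated, right-censored spells per transition: a spell opens at
the first age a person is seen in the origin class (delayed entry — the
likelihood conditions on survival to the entry time), closes with an event at
the first age in the destination class, and is censored at the end of
follow-up or when the person exits to a non-destination class (cause-specific
censoring; the data cannot distinguish this choice from dropping such spells,
and censoring is the standard treatment). A two-or-more-class jump between
consecutive ages — possible in raw data though not in the model graph — is
decomposed into one-class moves and counted. Spells crossing a band boundary
are split there; because the earlier part is censored at the boundary and the
later part re-enters with delayed entry, the split is exactly
likelihood-neutral.

### Interval-censored events

Annually interpolated series locate an event only within a one-year cycle.
`log_likelihood()` and `fit_parametric()` therefore offer two event
contributions: the density form $\ln f(t)$ (exact for continuously observed
times, and the default of the low-level functions, whose closed-form test
oracles assume it) and the interval form $\ln[S(t-1) - S(t)]$. The estimation
pipeline `estimate_transition_models()` defaults to the interval form: in
simulation, fitting the density form to annual-grid events biases the
log-normal scale parameter downward by roughly 0.18 at childhood-band sample
sizes, while the interval form is unbiased. Fits are always per sex — pooled
fits are biased relative to either sex's truth whenever the sexes differ.

### Default parameter table

The packaged `transition_model_parameters.csv` carries published point
estimates per sex, transition and band. Two caveats, both documented in the
table's help page:

* The four adult log-logistic cells are calibrated rather than copied: the
  published tuples are not interpretable as log-time location/scale pairs (a
  scale of 0.04 implies a near-step survival curve, contradicting the
  published band-average probabilities of 1.6–3.9% per year). We fix the
  scale at 1 and solve the location so the 80-year band-average annual
  probability equals the published average (`data-raw/make_fixtures.R`).
* Parameter order for Weibull (log-rate, shape) and Gompertz (shape, rate)
  follows the natural forms above; only the log-normal interpretation is
  independently confirmed by the published worked child-band values, so the
  table is configuration a user can replace.

## Mortality

Per-state death probabilities combine a national life table with BMI-class
mortality hazard ratios on the rate scale:
$q = 1 - \exp(-m(\text{age},\text{sex}) \cdot HR(\text{class},\text{age}))$.
Scaling rates (not probabilities) is what a hazard ratio means and keeps
$q < 1$. With all HRs at 1, every state shares the life-table survivorship
exactly — a telescoping identity the tests assert to 1e-12. The packaged life
table is a synthetic Gompertz–Makeham fixture
($m = 2\cdot10^{-4} + \lambda e^{0.0955\,\text{age}}$, $\lambda$ tuned by
bisection against the engine so life expectancy at age 2 is 83.5/80.5 years
for women/men); the packaged hazard ratios are plausible synthetic values with
attenuation after 65. Both are stand-ins for national data, clearly labelled,
and replaceable via delimited text files.

## Costs

Incremental annual health-care costs versus NW come from a two-part model:
logistic regression for any use, gamma GLM with log link for positive costs,
with weight class, age, smoking and marital status as covariates, stratified
by sex. `marginal_incremental_cost()` computes average marginal effects by
observed-sample averaging: the estimation sample is counterfactually assigned
the target class and NW, age is set to the evaluation age, and predictions are
averaged. The cost schedule covers ages 20–80 from the model; ages above 80
are held at the age-80 value, and ages 2–19 default to a zero increment (the
under-20 rule is configurable and logged — the published 2–30-year cost share
of 2–3% cannot distinguish the choices). Negative point estimates (men's OW)
are used as-is. Cohort costs are survival-adjusted (occupancy × increment),
reported per person by dividing by the starting cohort size, and discounted at
4% per year with age 2 as the base year (the base year is a convention; the
source does not state one).

## Base case, PSA and scenarios

The base case simulates 26,458 girls and 28,662 boys (48/52% of a 55,120
birth cohort) from the initial distribution 89.83/8.98/0.86/0.33%
(NW/OW/OB1/OB2), initial NW mass in NW1. Life expectancy is `start age + sum
of annual alive fractions`, horizon-truncated at 100 (survivors are retained,
not force-killed); a trapezoid half-cycle correction is available but off by
default, since the reference results do not mention one.

The probabilistic sensitivity analysis redraws, per iteration: survival
coefficient blocks as mean + L·z with L the lower Cholesky factor of the
block covariance (on the unconstrained scale — log-scale for
positivity-bounded parameters — so draws always respect the family's domain);
hazard ratios log-normally, with spread from the 95% CI when provided;
cost increments from gammas matched to mean and variance, negated
sign-preservingly for negative means (a gamma is positive-only; the source
does not address this case). Published covariance matrices are not available,
so synthetic diagonal covariances with a configurable relative standard error
are the default — they are inputs, not constants. Every block has its own
deterministic substream derived from the iteration seed, so adding a block
never perturbs other blocks' draws. Confidence bounds are the empirical
2.5%/97.5% order statistics (the ⌈0.025n⌉-th and ⌈0.975n⌉-th sorted values,
no interpolation) of 1000 iterations.

Six scenarios: (1) eliminate OB1→OB2 (initial OB2 mass joins OB1); (2)
eliminate OW→OB1 (initial OB1+OB2 mass joins OW, giving 89.83/10.17/0/0);
(3–6) start the whole cohort in one class at age 30 and simulate forward with
the standard adult dynamics. Years of life lost are life-expectancy
differences, reported as positive years lost and scaled to cohort totals by
the per-sex starting sizes. One subtlety the test suite documents: scenario
1's OB1 occupancy exceeds the base case at every adult age, but not
necessarily at ages 13–19, where the base case's strong adolescent OB2→OB1
regression refills OB1 from an OB2 pool the scenario no longer has.

## The synthetic-data generator

`simulate_longitudinal_cohort()` emulates linked growth-survey data: a latent
annual class path per person driven by known hazards (one-class moves only,
band-entry clocks — exactly the estimator's model, so estimation on generated
data is consistent by construction), observed only at sparse visits
(independent attendance tuned to an average of 2.84 observations per person;
persons with fewer than two visits are kept so exclusion rules are
exercised). Observed BMI is drawn uniformly inside the class band for the
person's age and sex and converted to weight through a deterministic growth
curve. The generator therefore validates classification, restructuring and
estimation — it does not emulate continuous BMI dynamics, measurement error,
informative dropout (a switch exists) or secular trends, so passing tests
demonstrate internal consistency of the pipeline, not external realism.

## Numerical choices and problem sizes

Optimization is deterministic multi-start Nelder–Mead with BFGS polish on
unconstrained reparameterizations, moment-based starting values, covariance
from the inverse observed information via the delta method. Family-selection
ties break toward fewer parameters, then a fixed family order. Probabilities
are clipped to [0,1]; an exhausted survival curve ($S(t)=0$) yields a
transition probability of 1 with a warning. The test suite validates the
cohort engine against a 200,000-agent microsimulation (3 Monte-Carlo standard
errors at every age), recovers generator parameters end-to-end from 10,000
synthetic persons (~5,000 female childhood spells), checks AIC family
recovery over 50 replicates of 5,000 Weibull records, and runs a 1,000
iteration full-model PSA — sizes chosen to keep Monte-Carlo noise well inside
the asserted tolerances.

## Known limitations

Secular trends are whatever the fitted hazards imply; there is no
recalibration machinery. Costs use a health-care perspective only. The
packaged life table, hazard ratios, child cutoff table (beyond the published
age-2 girl anchors) and survival covariances are synthetic stand-ins; results
from the packaged defaults illustrate the machinery and should not be read as
national estimates. Treatment effects that keep a person within OB2 (common
in severe-obesity care) are invisible to a class-based state space.
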