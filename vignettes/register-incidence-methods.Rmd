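---
title: "Counting incident hip fractures from raw admission registers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting incident hip fractures from raw admission registers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

National inpatient registers record *care events*, not *injuries*. A single
hip fracture typically generates several admission rows: the acute index
admission, one or more transfers to another department or hospital dated the
same or the next day, and — weeks to months later — readmissions for
complications or continued care that are re-coded with the fracture
diagnosis. A register with no "index event" flag therefore badly overstates
incidence if every fracture-coded row is taken at face value, and it
overstates second-fracture risk even more, because the spurious rows cluster
shortly after a real fracture.

`fractrace` implements a complete, testable pipeline for this ascertainment
problem:

1. **Episode chaining.** Admissions of one person whose gap
   (next admit − previous discharge) is ≤ 1 day are merged into one care
   episode, applied as a transitive closure. The rule is deliberately
   date-only — no hospital-identity logic — and both 0 and 1 day gaps count
   as transfers, with ties inside a chain broken by discharge date and then
   admission id.
2. **Readmission classification.** Each fracture-coded episode
   (ICD-10 S720/S721/S722, age > 50) is scored by a logistic model of
   P(readmission) from age, sex, acute vs elective admission, time since the
   previous injury admission, whether the first four ICD-10 positions of the
   main diagnoses coincide, and admission to a rehabilitation department. An
   episode is accepted as an incident fracture iff P(readmission) < 0.4932,
   with ties going to readmission (conservative against double counting).
   An episode with no previous injury admission at all is always incident.
3. **Comparison counters.** The naive count (every qualifying admission), the
   official-statistics count (at most one case per person and calendar year,
   any diagnosis position, presented as a centered 3-year moving average with
   2-year means at the endpoints), and the naive count excluding admissions
   dated ≤ 1 day after a prior case's discharge.
4. **Trends.** Stratified annual counts (age bands 50–64, 65–69, …, 90–94,
   95+), direct standardization to a reference year, and percentile bootstrap
   confidence intervals resampling *persons*.
5. **Competing risks.** Aalen–Johansen cause-specific cumulative incidence of
   a second fracture with death as a competing event.
6. **Projections.** Stratum rates continued at the estimated average annual
   percent change (AAPC), frozen, or continued-then-frozen, applied to a
   projected population.

## Design choices in detail

**The one-day rule.** "Within one day" is implemented inclusively
(gap ∈ {0, 1}); admissions that *overlap* in time are also chained, since an
overlap for the same person can only be a recording artifact of a transfer,
and the package reports them as a data-quality warning rather than failing.

**The classifier.** The cut-off 0.4932 is a fixed operating point of a
validated model whose published coefficients are not reproduced here; the
package therefore ships the model *structure* — a named coefficient vector
over interpretable design columns, with `"a:b"` interaction terms — plus
`fit_readmission_model()`, so the pipeline always runs with coefficients
refit on labelled data. The time-since-previous-injury covariate enters as
banded categories (none, 1–90, 91–365, > 365 days) because register
readmission risk is strongly nonlinear in time; linear and log transforms
are available as alternative design columns. The default fitting formula is
additive: the exact interaction set of the original model is not public,
and in data whose covariate cells are nearly separated (almost all incident
fractures are acute admissions) free interaction terms absorb main effects
unstably without improving held-out discrimination. The fit excludes
episodes with no previous injury admission — they are incident by rule and
carry no signal about readmissions. Only the episodes' *first* admission
label defines the episode label: transfer rows are already merged away by
chaining.

**Episode calendar year** is the year of the episode's start date: the index
event is the acute admission. The interval to the previous injury episode is
measured from that episode's *end* to the current start (a configuration
switch allows start-to-start; the choice is not fixed by the problem).

**Age bands.** The opening stratum is implemented as 50–64 so the bands
partition ages above 50 without overlap. Age is age in whole years at
admission, derived from birth year.

**Standardization and the bootstrap.** The standardized count for
(year, sex) is the sum over bands of the observed stratum rate times the
reference-year population of that band. The bootstrap resamples persons with
replacement, keeping each person's full case history together, because
first and second fractures of one person are dependent; population
denominators are fixed. Degenerate replicates (a zero base-year count) are
dropped and counted. Internally the replicates are computed from a sparse
person × stratum incidence matrix, so a thousand replicates cost about as
much as a handful of tabulations. With only case-bearing persons in the
resampling universe the intervals are mildly anti-conservative when one
stratum holds a large share of all cases; across realistic many-stratum
cohorts empirical coverage in our simulations is 90–95% at the nominal 95%
level.

**Competing risks.** The estimator is the Aalen–Johansen cause-specific
cumulative incidence: at each event time the cause-k increment is
S(t−) · d_k/n(t), with S the all-cause Kaplan–Meier. In the absence of
covariates this coincides with the subdistribution cumulative incidence, so
no regression machinery is needed; an independent competing-risks package
serves as a cross-check in the tests, never as the implementation. Ties
between events and censorings at one time treat events first. A second case
under the official definition is the person's first case in a *later*
calendar year, because that definition admits at most one case per year.
Index events with less than the full horizon of possible follow-up are
administratively censored at the register end, as the design forces.

**AAPC and projections.** The AAPC is exp(slope) − 1 from OLS of log(rate)
on calendar year per stratum — the standard operationalization, exact for
geometric series. Strata with a zero-rate year fall back to the pooled-sex
estimate for the band (summed events over summed denominators); a stratum
degenerate even after pooling gets an AAPC of 0 with a message. Projections
use the tabulation bands — the finest stratification available — rather than
re-aggregating to coarser bands.

## The synthetic register

Real national-register extracts cannot be shared, so the package ships a
generator that emulates the statistical structure the analysis relies on,
with per-admission ground-truth labels (incident / transfer / readmission).
Its defaults were fixed once and define the package's reference world — a
desk-scale emulation of the Swedish setting over 1998–2019:

* **Incidence.** Age- and sex-specific first-fracture rates (roughly
  0.05%–5.5% per person-year from the opening band to the oldest women)
  declining by 1.64% per year — the value that compounds to the ≈ 29%
  standardized decline documented in that setting over 21 years. Incident counts are binomial
  draws per stratum-year against the population table.
* **Demography.** Population counts grow geometrically, faster for men 75+
  (≈ +1.65%/yr, i.e. ≈ 41% over the study period) than for women 75+
  (≈ +0.6%/yr, ≈ 13%), which is what turns an equal rate decline into a
  falling absolute count in women but a flat one in men.
* **Transfers.** An incident episode generates a 0–1-day onward transfer
  with probability 0.18 (women) / 0.24 (men), each transfer continuing with
  probability 0.62. Fewer-but-longer chains reconcile the two reported
  register signatures simultaneously: the total naive overcount (≈ 56% in
  women, 72% in men, driven by the *expected number* of extra rows) and the
  naive 10-year "second fracture" risk (≈ 35%, driven by the *probability of
  at least one* extra row).
* **Readmissions.** With probability 0.20 (women) / 0.24 (men) an episode is
  followed by a fracture-coded readmission at a triangular(10, 60, 540)-day
  gap; half carry the fracture code as main diagnosis, half as a secondary
  code under a complication main diagnosis, exercising the
  diagnosis-position sensitivity modes. Readmissions are mostly elective
  (5% acute) and 30% are coded to rehabilitation departments. Long gaps make
  a sizable share cross a calendar-year boundary, which is exactly what
  inflates the official-statistics counter.
* **Deaths and second fractures.** After the index event each person carries
  a constant death hazard by sex and age band (≈ 0.05–0.65 per year) and a
  second-fracture hazard of 0.030 per year. The pair was chosen from the
  closed form for competing exponentials so the 10-year outcome is ≈ 80%
  dead and ≈ 11% refractured.
* **Burn-in and lookback.** The simulation starts at the beginning of the
  lookback window (11 years before the study), so the study years see a
  steady-state pool of earlier fracture patients: refractures, transfers and
  readmissions crossing into the window (including the turn-of-the-year
  transfers the official counter miscounts). Pre-study rows form the
  lookback table. 35% of patients additionally have an earlier non-fracture
  injury admission, so the previous-injury interval covariate is exercised
  from the first study year.
* **Surgery codes.** Incident admissions carry a hip-surgery procedure code
  (TNX40, NFJ09–NFJ99 or NFB09–NFB99) with a missingness proportion
  declining geometrically from 14.2% to 5.3% (women) and 15.6% to 6.9%
  (men) over the study period.

Dates are integer day offsets from 1970-01-01 and calendar years are derived
arithmetically; identical seed and configuration give byte-identical tables.
The default `scale = 0.1` yields roughly 1,500 incident fractures per year
(about a tenth of the real Swedish volume); the analysis scripts run at this
scale, the acceptance script at `scale = 0.25` (so that single-year count
comparisons carry only ≈ 2–3% Monte-Carlo error), and the heaviest test (a
≈ 55,000-person cohort for held-out classifier performance) uses
`scale = 0.17`.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data — includes coding-error noise in diagnoses,
regional and seasonal structure, secular change in transfer practice,
hazards that vary with time since fracture, and any correlation between
frailty, readmission propensity and death. The classifier's near-ceiling
performance on synthetic data (≈ 99.9% sensitivity, ≈ 95–96% specificity
held out; the specificity ceiling is real, set by elective same-diagnosis
readmissions that are genuinely indistinguishable from early true second
fractures in the covariates) says the *pipeline* is correct, not that any
particular real-world model achieves those figures.

## Numerical conventions and degenerate inputs

* Probabilities are computed with `plogis`; a score exactly at the cut-off
  classifies as readmission.
* A logistic fit requires both classes, a minimum number of episodes
  (default 50) and convergence; all-extreme fitted probabilities raise a
  perfect-separation error. The end-to-end driver falls back to an
  all-incident model (intercept −20) when a register contains no
  readmissions at all, which keeps the zero-artifact limit well defined.
* `percent_change(a, b)` requires a > 0; the standardized-change series
  reports NA for a sex with no base-year events rather than failing.
* An empty case set tabulates to all-zero counts; a case in a stratum
  missing from the population table names the stratum in the error.
* Bootstrap and generator randomness are seeded independently (the pipeline
  fans a single seed out to named substreams), so every stage is
  independently reproducible.

## Problem sizes

The analysis scripts simulate ≈ 65,000 study admissions (≈ 46,000 fracture
patients over 22 years), fit the classifier on half the fracture episodes,
and run 1,000 bootstrap replicates; this completes in well under a minute.
The test suite's property checks use cohorts between `scale = 0.02` and
`scale = 0.3`, and the bootstrap-coverage study uses 100 simulated
two-year cohorts of ≈ 1,600 events with 200 replicates each. These sizes
were chosen so that Monte-Carlo error is small relative to the tolerances
being asserted while the whole suite stays fast.

## Known limitations

* The shipped coefficients are always refit on synthetic labels; the
  package does not contain the original model's published coefficient
  values, only its structure and operating point.
* The official-statistics counter defines a person's second fracture as the
  first case in a later calendar year; within-year second fractures are
  invisible to that definition by construction.
* Person-level bootstrap of the case cohort slightly understates sampling
  variation relative to binomial draws from the full population (see above).
* Projections inherit the base-year rate estimates including their noise; a
  noisy small stratum propagates multiplicatively to the horizon.
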