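# fractrace

Counting incident hip fractures from raw hospital-admission registers.

National inpatient registers record care events, not injuries: one hip
fracture produces an acute index admission, transfers to other departments
or hospitals dated the same or the next day, and later readmissions for
complications that are re-coded with the fracture diagnosis (ICD-10
S720/S721/S722). Taking every fracture-coded row as a new fracture inflates
incidence by half or more and triples the apparent risk of a second
fracture. `fractrace` is for register epidemiologists who need
incident-event ascertainment from such data, and for anyone who wants to
quantify how badly naive counting misleads.

The package implements, as plain R functions over `data.table`s:

* **Care-episode chaining** — admissions of one person with gap
  `admit − previous discharge ≤ 1` day are one episode (transitive closure).
* **A readmission classifier** — logistic model
  `P(readmission) = logit⁻¹(β₀ + β·x)` on age, sex, acute admission, banded
  time since the previous injury admission, 4-position main-diagnosis
  similarity and rehabilitation department; an episode is an incident case
  iff `P(readmission) < 0.4932`, and an episode with no previous injury is
  always incident. Coefficients are refit on labelled data
  (`fit_readmission_model()`); the cut-off is a fixed operating point.
* **Comparison counters** — naive (every qualifying admission),
  official-statistics (≤ 1 case per person-year, 3-year moving averages),
  and naive-excluding-adjacent counting.
* **Trends** — direct age standardization
  `N*(y,s) = Σ_b rate(y,s,b) · pop_ref(s,b)` over bands
  50–64, 65–69, …, 95+, with person-resampling percentile bootstrap CIs.
* **Competing risks** — Aalen–Johansen cumulative incidence of a second
  fracture with death as a competing event,
  `ΔCIF_k(t) = S(t−) · d_k(t)/n(t)`.
* **Projections** — stratum rates continued at the log-linear average
  annual percent change, frozen, or continued-then-frozen, applied to
  projected populations.

Because real register extracts are confidential, the package ships a
synthetic-register generator (`cohort_config()`, `generate_population()`,
`generate_admissions()`) that emulates the relevant structure — declining
age/sex-specific incidence, transfer chains, re-coded readmissions, second
fractures, death as a competing event, a pre-study lookback window — with
per-admission ground-truth labels, so the whole pipeline is testable end to
end. See the methods vignette
(`vignettes/register-incidence-methods.Rmd`) for the model, the generator's
assumptions and the design decisions.

## Worked example

The repository is organised as a numbered workflow under `analysis/`;
each step is a thin driver over the package and writes its tables under
`results/`:

```sh
Rscript analysis/01_simulate.R        # synthetic register + ground truth
Rscript analysis/02_identify.R       # chain, classify, count (4 methods)
Rscript analysis/03_trends.R         # standardized trends + bootstrap CI
Rscript analysis/04_second_fracture.R# competing-risks cumulative incidence
Rscript analysis/05_project.R        # scenario projections to 2050
```

Output of a run at the default desk scale (~1/10 of national volume,
seed 20240106):

```
simulated 65276 study admissions for 46502 fracture patients (+39076 lookback rows)
ground truth: 69090 incident, 25483 transfer, 9779 readmission admissions

65276 admissions chained into 48362 episodes (37764 fracture episodes)
held-out classifier performance: sensitivity 99.9%, specificity 96.2%
naive counting overstates the algorithm by 58%; official statistics by 11%

observed algorithm cases: 1786 in 1998, 1459 in 2019 (-18% change)
age-standardized change 1998->2019, F: -32.2% (95% CI -37.5 to -26.6)
age-standardized change 1998->2019, M: -27.9% (95% CI -36.6 to -18.3)

algorithm            10-year risks: second fracture 11.6%, death 76.1%
naive                10-year risks: second fracture 35.9%, death 55.2%
naive_excl_adjacent  10-year risks: second fracture 19.7%, death 69.2%

2034: 1322 fractures if the decline continues, 1689 with constant rates, 1434 in between
2050: 1199 fractures if the decline continues, 1983 with constant rates, 1683 in between
```

Reading this: the naive counter sees ~58% more "fractures" than the
episode-chaining classifier, because transfers and readmissions are counted
as new events; those same spurious rows turn an 11.6% true 10-year
second-fracture risk into an apparent 35.9%. After removing the effect of
an ageing population by standardizing to the 2019 population structure, the
fracture burden falls by roughly 30% in both sexes over the study period —
and whether that decline continues, stops, or stops in 2029 changes the
2050 projection by a factor of 1.7.

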