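---
title: "Phenotyping opioid-use cohorts in primary care records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping opioid-use cohorts in primary care records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opicohort)
library(dplyr)
```

## The problem

People who use illicit opioids such as heroin have high and broad health
needs, but they are poorly represented in survey-based epidemiology. UK
primary-care databases (CPRD GOLD and AURUM style extracts) record millions
of patients longitudinally, so an *EHR phenotype* — an algorithmic
definition built from codelists and rules — can assemble a large cohort of
patients with a recorded history of illicit opioid use and follow their
health over decades.

`opicohort` implements such a phenotyping pipeline end to end:

1. **Codelists** (`codelist()`, `keyword_search()`, `match_patient_codes()`)
   — clinical codes that indicate a history of illicit opioid use, split
   into *definite* (e.g. "heroin dependence") and *probable* (e.g.
   injecting drug use) classes, plus prescription product codes for opioid
   agonist therapy (OAT: methadone and buprenorphine used to treat
   dependence). The default phenotype uses definite codes and OAT products
   only, prioritising specificity; `include_probable = TRUE` trades
   specificity for sensitivity.
2. **The product screen** (`first_prescriptions()`, `summarize_products()`,
   `screen_products()`) — methadone and buprenorphine are also licensed for
   pain, so a product code alone is ambiguous. Populations in OAT are
   predominantly young and male; analgesic users are predominantly older
   and female. The screen excludes a product when, among patients at their
   first prescription of it, more than half are female, the lower age
   quartile is under 18, or the upper age quartile is over 64.
3. **Cohort assembly** (`build_cohort()`) — entry/exit dates, region and
   age eligibility, and a flow-chart exclusion tally.
4. **Baseline characterisation** (`baseline_table()`,
   `entry_age_trend()`, `smoking_status()`, `history_flags()`).
5. **Mortality validation** (`expand_person_time()`, `expected_deaths()`,
   `smr()`, `crude_rate()`, `smr_table()`) — indirect standardisation
   against a reference rate table with exact Poisson intervals.
6. **Hospital cross-check** (`validation_summary()`) — sensitivity of the
   phenotype among patients hospitalised with an ICD-10 F11
   (opioid-disorder) diagnosis.
7. **A synthetic EHR generator** (`simulate_ehr()`) — the whole pipeline is
   testable without access to licence-restricted data.

Everything is tibble-in, tibble-out and composes with the pipe; fitted
summaries provide `tidy()`/`glance()` and `autoplot()` methods.

## Entry, exit and person-time

Cohort entry is the **latest** of the study start, the patient's first date
of good-quality data, and their first phenotype code; codes recorded before
registration still count as history, the patient simply enters when
observation begins. Exit is the **earliest** of the end of data collection
and death, capped at the study end. Follow-up is the half-open interval
`[entry, exit)`. Members need 18 ≤ age ≤ 64 at entry and positive
follow-up; exclusions are tallied in a fixed order (no code → region → no
follow-up → age) so the tally plus the final cohort always reconstructs the
number of phenotype-positive patients.

Registries supply only a year of birth, so ages are computed against an
imputed birth date of **1 July** of the birth year; mid-year imputation
bounds the error at six months either way and keeps every age computation in
the package (cohort, product screen, Lexis expansion, simulator) on one
convention.

`expand_person_time()` distributes every follow-up day into a (sex, single
year of attained age, calendar year) stratum. Using *attained* age matters:
a cohort restricted to under-65s at entry still accrues person-time and
deaths in a 65+ band as members age. The implementation splits each
member-year at 1 January and at the imputed birthday rather than looping
over days, and asserts exact day conservation on every run; a day-by-day
loop is kept in the test suite as an independent oracle. For decedents the
death day itself is included (exit is extended one day past the death),
since an event must contribute its own risk time.

Death-registration lag — common for drug-related deaths because a coroner
is involved — is handled by `truncate_follow_up()`: exits are capped some
months before the end of mortality linkage, and deaths on or after the cap
are uncounted. The default rule is calendar-month subtraction from the
linkage end; a direct `cap_date` override exists because published analyses
sometimes state the cap date itself, and month arithmetic can differ from a
stated date by a day or two.

## Indirect standardisation and exact Poisson intervals

Expected deaths are
$E = \sum_{s} \frac{d_s}{D_{y(s)}}\, \lambda_s$
over strata $s$, where $d_s$ is stratum person-days, $D_{y}$ is 365 or 366
for calendar year $y$, and $\lambda_s$ is the reference rate (deaths per
person-year) for the stratum's sex, age and year. Every stratum with
positive person-time must have a rate; missing cells are a hard error
listing every missing key, because silently dropping person-time biases the
SMR upward.

The SMR is $O/E$ with the observed count treated as Poisson. Exact
95% bounds use the chi-square representation of the Poisson tails:

$$\text{lower} = \tfrac{1}{2}\chi^2_{\alpha/2}(2O)/E, \qquad
  \text{upper} = \tfrac{1}{2}\chi^2_{1-\alpha/2}(2O+2)/E,$$

with a lower bound of 0 when $O = 0$. The crude rate (`crude_rate()`) uses
the same bounds on the count, over person-years; person-days convert at
365.25 days/year for this headline denominator, while expected deaths use
exact per-year day counts as above — the standardisation is defined at day
level, the crude conversion is a convention.

## Numerical and design choices

* **Quantiles** everywhere (product screen, baseline medians/IQRs) use
  linear interpolation between order statistics (`stats::quantile()` type
  7), the common default.
* **Product-screen boundaries are strict**: exactly half female, lower
  quartile exactly 18, upper quartile exactly 64 all *pass*. Products with
  fewer than `min_patients` patients are flagged `REVIEW` rather than
  auto-classified, and a named `overrides` vector models the final review
  by a prescribing clinician, applied last and logged.
* **Same-day smoking ties** resolve `CURRENT` > `EX` > `NEVER`; smoking
  status uses the most recent record anywhere in the patient's history by
  default (a `before =` cut-off is available). History flags
  (homelessness, prison, alcohol dependence) are lifetime: any record ever.
* **Hospital timing windows**: a same-day primary-care code counts as day 0
  of the 30-day post-admission window, and ICD-10 matching is by prefix so
  `F11`, `F11.2` and `F112` dialects all match.
* **Degenerate inputs** fail loudly: zero follow-up members reaching the
  expansion, zero person-time rates, unknown codelist categories and
  duplicate codes or patient ids are all hard errors; unknown terminologies
  and unknown patients in prescriptions are skipped with counted warnings.

## What the synthetic generator emulates

`simulate_ehr()` draws a two-subpopulation extract under a single seed
(each table uses a named substream, so regenerating one table does not
perturb the others):

* **Phenotype positives**: 69% male; age at first recorded use log-normal
  with median 35 years and spread matched to an interquartile range of
  roughly 29–43; ages drift upward by 0.5 years per calendar year of first
  use (the population is ageing); IMD quintile weights 6.6/11.0/15.9/24.2/
  42.3% (deprivation-skewed); smoking 76/10/6/8%
  current/ex/never/no-record; mortality hazard 6.6× the reference rates
  from first use onward. Every surviving positive receives an index record
  dated exactly at first use (a definite clinical code with probability
  0.85, otherwise an OAT prescription), so cohort entry aligns with the
  start of the elevated hazard and the hazard ratio is recoverable without
  immortal-time artefacts.
* **Background patients**: majority female (55%), older (mean 50 years),
  at reference mortality. They receive the planted *confusable* product —
  a transdermal-patch-like buprenorphine analgesic prescribed 80% to women
  centred on age 62 — which the product screen must reject.
* **Hospital cases**: a configured number of F11 admissions, of which a
  configured fraction (default 88%) belongs to patients who also hold a
  primary-care phenotype code, with a realistic mix of code-before /
  shortly-after / later timings.
* **Reference rates**: Gompertz-type, $\lambda = \lambda_0
  e^{\beta(a-40)}$ with a female multiplier and a mild calendar decline,
  calibrated so a 40-year-old man has roughly 2 deaths per 1,000
  person-years. Coverage spans ages 15–110 across the study window.
* **Deaths** follow a daily Bernoulli process with probability
  (annual rate × hazard multiplier)/days-in-year, a good approximation to
  the exponential hazard at these magnitudes. Sampling is by inverse CDF
  over the piecewise-constant segments (geometric within a segment), which
  is distributionally identical to literal day-by-day draws but vectorised.

Parameters that no published description fixes — overall prevalence in the
extract (default 0.2, far above the real ~1% so that tests are not
dominated by background patients), registration windows (start uniform over
the study period, exponential duration with mean 8 years, giving median
cohort follow-up of a few years), and the event-count distributions — were
chosen once as field-plausible values and are not tuned.

What passing simulation tests show — and what they do not: the generator
emulates the *structure* of a primary-care extract (two subpopulations,
codes, prescriptions, admissions, deaths under known hazards), so tests
demonstrate that the pipeline recovers known ground truth under that
structure. Real extracts add practice-level clustering, coding-practice
drift, free text, regional rate variation and linkage eligibility, none of
which are modelled; performance on real data is a matter of external
validation, not of these tests.

## Simulation scale

The validation suite uses 200 replicate cohorts of 2,000 patients for the
null-coverage check of the exact intervals (binomial tolerance at 200
replicates; exact Poisson intervals are conservative, so only coverage
*below* nominal is evidence of error), 60 replicates for hazard-ratio
recovery at 6.6, ~2,000 planted first prescriptions for the product screen
and 5,000 hospital cases for the sensitivity check. These sizes put the
Monte-Carlo error comfortably below the effects being checked while keeping
a full run in a few minutes.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_ehr(sim_config(seed = 1, n_patients = 5000))

cohort <- build_cohort(sim$patients, sim$events, sim$prescriptions,
                       sim$codelist)
exclusion_tally(cohort)
glance(cohort)

screen <- sim$prescriptions |>
  first_prescriptions(sim$patients) |>
  summarize_products() |>
  screen_products()

mortality <- smr_table(cohort, sim$rates)
glance(mortality)
autoplot(mortality)
```

## Known limitations

* The bundled codelist is illustrative; real analyses must supply curated,
  database-specific codelists (the CSV format and `keyword_search()` aid
  exist for that purpose).
* Linkage eligibility is reduced to "use the patients you pass in";
  practice-level data quality ("up-to-standard" dates) is taken as given in
  `data_start`.
* One death date per patient; no adjudication between primary-care and
  national mortality sources.
* The simulator does not generate clinical events for background patients
  beyond the confusable prescriptions, so specificity of the phenotype on
  synthetic data is 1 by construction and is not a measurable property.
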