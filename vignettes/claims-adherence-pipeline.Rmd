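---
title: "Methods: claims-based OAAP adherence, treatment patterns and costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based OAAP adherence, treatment patterns and costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oaapflow)
```

`oaapflow` analyzes treatment patterns for people with schizophrenia newly
started on an oral atypical antipsychotic (OAAP), from administrative
claims alone. This vignette is the package's own account of the methods:
the measurement model and its assumptions, the parameters that matter, what
the bundled synthetic-data generator does and does not emulate, and the
numerical and design choices made where conventions genuinely diverge in
the field.

## The measurement model

### Incident-user anchoring

Every quantity is anchored to the patient's *index date* — the first OAAP
fill inside the identification window — with day offsets: baseline is days
−182..−1 (six months) and follow-up is days 0..364 (twelve months,
leap days ignored so the adherence denominator is always 365). The
incident-user design gives all patients a common observation clock starting
at drug initiation; patients already on antipsychotics during baseline are
excluded (washout), so exposure histories start clean.

### Coverage and PDC

A pharmacy fill on day $d$ with days supply $s$ is assumed to be consumed
one day at a time from the day of dispensing: it covers days
$d, \dots, d+s-1$, truncated to follow-up. Same-drug fills are **unioned**,
not shifted end-to-end ("no stockpiling"): a refill picked up early does
not extend the episode beyond its own supply window. Concurrent different
OAAPs count a covered day once. Adherence is the hospitalization-adjusted
proportion of days covered,

$$\mathrm{PDC} \;=\; \frac{\lvert \text{covered} \setminus \text{hospital}
\rvert}{365 - \lvert \text{hospital} \rvert},$$

with adherent defined by the closed bound $\mathrm{PDC} \ge 0.8$. Days in
hospital are removed from the numerator as well as the denominator — the
institution, not the pharmacy benefit, supplies medication during a stay —
which also guarantees PDC ≤ 1 without ad-hoc capping. Two PDCs are
reported: the index product alone, and all OAAPs as a class (a patient who
switches but stays on *some* OAAP is covered under the class measure).

### Switch and augmentation

Let $E$ be the last covered day of the index drug's unioned supply. A
patient **switched** iff a different OAAP was dispensed in the half-open
window $(E, E+30]$ and the index drug was not refilled on or after that
fill day. A patient **augmented** iff the index drug was refilled (≥ 2
fills) and a single other OAAP's coverage overlaps the index drug's
coverage on ≥ 60 days. The two labels are assessed independently — a
patient can augment mid-year and switch later; the proportions are reported
separately and nothing forces exclusivity.

### Comorbidity

The Charlson comorbidity index uses Quan's ICD-10 coding algorithm for the
17 categories with the original 1/2/3/6 weights, computed from
baseline-window diagnoses only (it is a baseline severity measure).
Hierarchy rules keep the more severe member of conflicting pairs
(complicated over uncomplicated diabetes, moderate/severe over mild liver
disease, metastatic over non-metastatic malignancy). Matching is
dot-insensitive prefix matching in any diagnosis position. The map ships as
`inst/extdata/quan_charlson_icd10.csv`; an alternative map (e.g. Quan-2011
weights) can be supplied by path. Severe-mental-illness flags (bipolar F31,
major depression F32/F33, schizoaffective F25) use baseline **and**
follow-up diagnoses, matching how comorbid SMI is usually reported in this
literature.

### Utilization and expenditures

Inpatient claims merge into stays when they overlap or touch (an admission
on, or the day after, a prior discharge continues the same stay — exactly
what a day-sweep over hospitalized days yields). Length of stay is
inclusive (`discharge − admission + 1`), clipped to follow-up. ED visits
are distinct service dates; outpatient utilization counts claim rows
("visits/services" — a date can hold several billed services). The
schizophrenia-related scope keeps claims carrying an F20.x code in any
position; its drug bucket is OAAP fills. ED claims inside a merged stay are
*not* rolled up into the hospitalization. Expenditures are paid amounts
summed by setting within follow-up; totals satisfy
`total_medical = inpatient + ED + outpatient` and
`total = total_medical + prescriptions` by construction, and the suite
asserts both to 1e-6.

## Statistical comparisons

Categorical variables: Pearson chi-square on the contingency table, no
continuity correction. Continuous variables: two-sided
Mann-Whitney-Wilcoxon (normal approximation, midrank ties) for two groups,
Kruskal-Wallis H for more. Significance is per-test at α = 0.05 with no
multiplicity adjustment, matching common practice for descriptive cohort
tables. A contingency table with an all-zero row or column is reported
without a test and flagged rather than erroring.

## The synthetic generator

The generator exists so that every downstream rule has a testable ground
truth; it is a *stated world*, not an estimate of any real cohort.

* **Refill persistence** is a per-patient two-state process: at each supply
  exhaustion the patient refills with probability $p_i$ (drawn once per
  patient from Beta(1.70, 0.45)) after a geometric gap (mean 7 days); 20%
  of patients are "tight" refillers with zero gap, producing the point
  mass at PDC = 1 that real cohorts show. These defaults were fixed once by
  matching the closed-form expected all-OAAP PDC
  (`expected_all_oaap_pdc()`, an exact renewal recursion over the 365
  follow-up days integrated over the Beta by quantile-transform quadrature)
  to 0.50 — the all-OAAP mean PDC scale reported for Medicaid OAAP
  cohorts — and were not revisited.
* **Index drug mix** follows the published market shares of the top
  products (quetiapine 25.6%, risperidone 24.8%, olanzapine 19.7%,
  aripiprazole 13.7%, remainder spread over five minor products).
* **Events**: switching (16.3% intent, realized on discontinuation),
  augmentation (3.2% intent, realized when the index drug is refilled long
  enough; the second agent starts at the first index refill and is
  co-refilled with it), LAI use (20.7%), baseline typical-AP use (5%),
  dual eligibility (8%), enrollment gaps (4%). Hospitalization counts are
  negative binomial (mean 0.97 stays/patient-year, size 0.45 so ~40% of
  patients have ≥ 1 stay), stay length 1 + Poisson(6); ED and outpatient
  visit counts are negative binomial with means 3.5 and 43.2. Costs are
  lognormal per claim, right-skewed so means sit far above medians, in
  2020 USD.
* **Ground truth** is computed by an independent per-day boolean-array
  route inside the generator (coverage, hospital days, PDC, pattern label,
  inclusion status with the first failing criterion), never by calling the
  pipeline.

What the generator does **not** emulate: seasonality and secular trends,
dose/strength, claim reversals and negative payments, transfers between
Medicaid plans, miscoded fields, correlated visit/cost processes beyond the
patient level, and realistic diagnosis co-occurrence structure. A green
test therefore establishes that the pipeline implements its stated rules
exactly and recovers known truth under a plausible claims-shaped world —
not that it would reproduce any particular real cohort's numbers.

`inject_edge_cases()` appends eleven hand-built fixture patients at the
rule boundaries (duplicate and overlapping fills, a fill straddling day
364, hospital-overlapping supply, switch at exactly 30 vs 31 days, overlap
of exactly 60 vs 59 days, PDC exactly 0.8, a dual-eligible and an LAI
exclusion) with hand-computed ground truth.

## Numerical choices and degenerate inputs

* Windows: baseline 182 days, follow-up 365 days, both fixed; the
  denominator convention is why leap days are ignored.
* A patient hospitalized all 365 days has an empty PDC denominator; PDC is
  defined as 1 (fully institutionalized) and such patients are countable.
* Schizophrenia evidence counts *claim rows*, not distinct dates (two
  same-day outpatient claims qualify), and ED claims count with outpatient
  claims; the alternative readings are noted in the ledger of open calls.
* Continuous enrollment tolerates zero gap days.
* Patients with two distinct OAAP products on the index date cannot be
  assigned a single index product and are excluded, logged as their own
  attrition sub-row (`single_product`).
* Missing birth dates or enrollment fail the relevant criterion; they never
  crash the cascade. Non-positive days supply, discharge-before-admission
  and negative paid amounts are rejected row-wise with warnings and
  counted.
* Ties in rank tests use the standard midrank convention via R's `stats`
  implementations; `wilcox.test` runs with `exact = FALSE` so identical
  samples give p = 1 deterministically.
* Display rounding: percentages and means to 1 decimal (PDC to 2), dollars
  to whole units — matching the printed precision conventions of cohort
  tables in this literature.

## Design choices that were genuinely open

* **30-day switch window origin**: taken from the end of the index supply
  (last covered day), not the last fill date, and half-open $(E, E+30]$ —
  supply end is what "end of the medication window" denotes operationally.
* **"Not refilled"** in the switch rule is read as *not refilled on or
  after the candidate fill*; an index refill before the new drug's fill
  does not veto a later switch (it just moves $E$).
* **Stockpiling**: union semantics, because concurrent-possession days are
  explicitly counted once in the medication-days measure; a shift-based
  episode construction is a deliberate non-default alternative.
* **ED roll-up**: none; ED visits inside a stay window remain ED visits.
* **Chi-square variant**: Pearson, uncorrected.

## Known limitations

Dose and strength are not modeled (days supply is the sole exposure
metric); PDC is possession, not ingestion. Discontinuation episodes with
grace periods are out of scope — patterns are limited to the
switch/augmentation definitions above. No ICD-9 support; no Elixhauser
index; no cost-year inflation adjustment (synthetic amounts are a single
currency-year). Cohort-level results from any real claims extract will
depend on local coding practice in ways the synthetic world cannot
anticipate.
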