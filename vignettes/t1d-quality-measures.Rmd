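---
title: "Measuring pediatric T1D care quality from CDM extracts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pediatric T1D care quality from CDM extracts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1dqm)
library(dplyr)
```

# The problem

Benchmarking the quality of care for children and adolescents with type 1
diabetes (T1D) has traditionally required manual chart review or
registry-style self-report. When health systems map their electronic health
records into a common data model (CDM), the same measure specification can
instead be executed automatically against every site's extract. That only
works if the computable phenotype and the measure logic are explicit,
deterministic, and validated: coded EHR data contain systematic errors
(results locked in outside-lab systems, diagnosis codes attached to
admissions for unrelated reasons, inconsistent visit labelling), and an
automated measure inherits all of them.

`t1dqm` implements that pipeline end to end: terminology code sets, a
four-table CDM subset (demographic, encounter, diagnosis, lab result), a
computable T1D phenotype over a 365-day lookback window, five quality
measures aggregated to site-level benchmark tables, and validation of the
automated results against reference ("chart") outcomes via positive and
negative predictive value. Because real pediatric EHR extracts cannot be
distributed, the package also contains a first-class synthetic CDM
generator that plants known per-patient truth, so every claim the package
makes about itself is testable.

# Cohort phenotype

A patient is in the cohort at anchor date $t$ if all of the following hold
over the window $W = [t - 364, t]$:

1. **Age** — younger than 21 years at $t$, by birthday arithmetic (floored
   completed years), not division by 365.25.
2. **Persistent diagnosis** — at least one T1D-classified diagnosis inside
   $W$ *and* at least one in the preceding 365-day block
   $[t-729, t-365]$. We read the requirement of a diagnosis "a year for
   more than 1 year" as one code in each of the two most recent year-blocks;
   calendar-year and total-span readings exist, and the block reading was
   chosen because it uses only the data the measures already window.
   Incident patients — first T1D diagnosis inside $W$ — cannot have a
   prior-block code by definition, so they bypass this criterion; they are
   retained in the cohort, flagged `newly_diagnosed`, and excluded only
   from the DKA measure denominator (their diagnostic presentation is not
   a care-quality failure of the measurement year).
3. **Engagement** — two or more T1D-related ambulatory visits in $W$: AV
   or TH encounters carrying a T1D diagnosis on the encounter itself,
   counted as distinct admit dates.
4. **No competing diabetes type** — no diagnosis ever classified into the
   excluded set (type 2, secondary/CF-related, drug-induced, gestational,
   MODY). Exclusion is lifetime: such a code reclassifies the patient,
   not the year.

Every rejected patient gets a logged reason
(`age_ge_21`, `no_t1d_dx_in_window`, `single_year_t1d_dx`,
`insufficient_t1d_visits`, `excluded_diabetes_dx`), which the test suite
asserts patient by patient.

# Code sets

Diagnosis matching is exact on normalized strings: ICD codes are
uppercased and dot-stripped (`E10.10` → `E1010`) on both sides, because
CDM extracts differ in dot conventions; SNOMED and LOINC codes are matched
verbatim. There is deliberately no prefix or hierarchy matching — wildcard
families must be enumerated in the code-set file — because silent
over-matching across ICD revisions is the classic way phenotype counts
drift between sites. The shipped `default_codesets.csv` enumerates
ICD-10-CM E10.\*, ICD-9-CM 250.x1/250.x3, DKA codes
(E10.10/E10.11, 250.11/250.13, one SNOMED concept), the excluded-type
families, and HbA1c LOINC codes 4548-4/17856-6. These are editable
implementer defaults, not a canonical terminology release; a deployment
should review them against its local coding practice.

# The five measures

All measures are assessed over the same window $W$; internal arithmetic is
full precision, rounding to 0.1 happens only in the report layer.

| Measure | Definition | Denominator |
|---|---|---|
| `TWO_A1C_GT9` | ≥ 2 in-window HbA1c results strictly > 9 % | full cohort |
| `FOUR_VISITS` | ≥ 4 distinct-date T1D ambulatory visits | full cohort |
| `LAST_A1C` | most recent in-window HbA1c (site median reported) | cohort with ≥ 1 in-window A1c |
| `A1C_IMPROVE` | previous-minus-last of the two most recent A1c ≥ 0.5 | cohort with ≥ 2 in-window A1c |
| `DKA_ADMIT` | ≥ 1 IP/EI admission in $W$ with a DKA code on the encounter | cohort minus incident patients |

Conventions worth stating explicitly:

* **Strict `>` at 9 %** for the poor-control measure and **inclusive
  `≥ 0.5`** for improvement, both configurable. Comparisons on the 0.1 %
  A1c grid carry a `1e-9` guard so that, e.g., `9.6 − 9.1` (which is not
  exactly 0.5 in floating point) evaluates the inclusive boundary
  correctly.
* Patients with no in-window A1c stay in the `TWO_A1C_GT9` denominator
  with a negative outcome (the denominator equals the cohort), but are
  ineligible for `LAST_A1C` and `A1C_IMPROVE`. This asymmetry mirrors how
  such measures are reported in practice and is why the improvement
  denominator is smaller than the cohort.
* Same-date A1c duplicates are averaged (then rounded to 0.1): unbiased
  and independent of row order, unlike max/min.
* DKA requires the code **on the admission encounter itself**, not merely
  anywhere in the window: "hospitalized for DKA" semantics, and the
  configuration under which the surgery-admission false-positive mechanism
  is observable.
* The `Overall` row pools patients across sites; it is not an average of
  site rates, and the tests assert it always lies within the span of the
  site rates.

Site proportions get exact Clopper–Pearson 95 % intervals (beta-quantile
form). The exact interval was chosen over Wald/Wilson because chart-review
cells are small and `k = n` rows (printed as "100 %" without an interval)
are routine; the independent test oracle inverts the binomial tails
numerically instead of using beta quantiles.

# Validation against chart outcomes

`validate_measures()` pairs automated outcomes with reference outcomes on
(site, patient, measure); pairs where either side is ineligible are
dropped and per-site contingency tables are built. PPV = tp/(tp+fp),
NPV = tn/(tn+fn); empty denominators are reported as undefined, never as
zero. The pooled overall row sums contingency cells across sites (the
alternative — averaging site-level predictive values — weights small
review samples equally with large ones; pooling was chosen and the pooled
table equals the element-wise sum of the per-site tables by construction).
For the continuous `LAST_A1C` measure the statistic is percent agreement
within ±0.05 (equality at the one-decimal reporting precision of the
assay), with a binomial interval on the agreement count.

# The synthetic network generator

`generate_network()` is not a test fixture; it is the package's model of
how the error mechanisms act on CDM data. Per site it synthesizes exactly
`n_patients` phenotype-positive patients whose planted outcomes realize
each scenario rate exactly (`round(rate × n)` positives), so the engine's
recovery of the planted rates is an equality check, not a statistical one:

* ages uniform over 2–20 completed years; first T1D diagnosis in the
  prior year-block for established patients, inside the window for the
  `frac_newly_diagnosed` incident fraction (default 0.10);
* 2–3 T1D ambulatory visits for visit-measure-negative patients, 4–8 for
  positives, at distinct uniform dates; 0–3 non-T1D primary-care visits
  (mislabeling targets); a non-DKA inpatient admission for ~20 % of
  patients (overcoding targets);
* 2–6 A1c results per patient on the 0.1 grid: the last value is drawn
  from Normal(median target, sd 1) truncated to [4, 16], the previous
  value realizes the planted improvement flag (delta ≥ 0.5 down for
  improvers, < 0.5 otherwise), and earlier values are constrained so the
  count of values > 9 matches the planted poor-control flag;
* decoy patients (10 % of n, at least 4) cycle through the four rejection
  rules — over-age, excluded-type code, single visit, single-year
  diagnoses — so every phenotype path is exercised with its expected
  rejection reason;
* each site draws from its own stream seeded by (master seed, site id),
  so adding or reordering sites never changes another site's bytes.

The default `benchmark_scenarios()` network has 12 sites with cohort sizes
26–1,776 and per-site rate spans of roughly 3–47 % (two A1c > 9),
23–88 % (four visits), 1.6–32 % (DKA), 1–27 % (improvement), and site
median last A1c 7.9–10.2 — the scale and heterogeneity of a real national
pediatric T1D network. Because every cohort patient receives at least two
in-window A1c results, all A1c measures share the full-cohort denominator
in synthetic data; real networks have single-A1c patients and hence a
visibly smaller improvement denominator. Other real-data features the
generator deliberately does not emulate: longitudinal disease dynamics,
demographic confounding, transfers between sites, free text. Passing the
fidelity tests therefore demonstrates the correctness of the measure
logic, not the field accuracy of the phenotype.

Three corruption operators perturb the CDM tables while leaving the gold
standard untouched:

* `apply_external_lab_loss()` removes `floor(fraction × n)` A1c rows —
  one-sided by construction: the poor-control measure can only lose
  positives, so its validation PPV stays exactly 1 while NPV drops;
* `apply_dka_overcoding()` adds a DKA code to non-DKA admissions — the
  mirrored signature, PPV < 1 with NPV exactly 1;
* `apply_visit_mislabeling()` strips T1D labels from true visits and
  attaches them to an equal number of non-T1D visits — errors in both
  directions.

These directional signatures are asserted in the acceptance suite at
n = 800 per scenario.

# Numerical and degenerate-input choices

* Dates are dates, not datetimes; same-day ties are resolved by the
  distinct-date visit rule and the same-date A1c mean.
* HbA1c rows outside [3, 20] % are quarantined at load with a reason (unit
  confusion with glucose mg/dL is the usual cause), never silently
  dropped; the quarantine report is part of the pipeline output.
* Empty cohorts, empty sites, and zero-eligible summaries are valid
  results (n = 0 rows, absent rates), not errors.
* `round()` half-even behaviour only touches display values; planted
  counts use `round(rate × n)` once, at generation.

# Problem sizes

The test suite runs the full 12-site benchmark once (~10,000 patients,
about 150,000 generated rows, a few seconds), the corruption signatures at
n = 800, 1,000 random contingency tables against the brute-force oracle,
and the cross-measure invariants across 20 generator seeds at n ≈ 100 per
seed — sizes chosen so the whole suite exercises every code path at
network scale while remaining fast enough to run on every change.

# Known limitations

* The phenotype's "diagnosis a year for more than 1 year" operationalization
  is one of several defensible readings (see above); it is configurable in
  principle via the window machinery but the block reading is the tested
  default.
* Chart truth is accepted in the same file format the generator emits;
  real chart-review ingestion (forms, adjudication, sampling weights) is
  out of scope.
* The package handles the four-table CDM subset only — no medications,
  procedures, or device data, and no database connectivity; extracts
  arrive as CSV.
* Predictive values are the only validation statistics (plus agreement for
  the continuous measure); sensitivity/specificity and reviewer
  reliability are out of scope.
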