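# t1dqm

Automated quality-of-care measurement for pediatric type 1 diabetes (T1D)
from electronic-health-record extracts held in a PCORnet-style Common Data
Model (CDM), with validation against chart-review outcomes.

Health systems that map their EHRs into a shared CDM can run a single
measure specification against every site and benchmark the results —
replacing manual chart abstraction — but only if the computable phenotype
is explicit and the automated results are validated against a reference
standard. `t1dqm` is for biostatisticians and informaticists building or
auditing such a pipeline. It provides:

* **Code sets** — ICD-9-CM / ICD-10-CM / SNOMED / LOINC terminology
  handling with dot-stripping normalization and exact matching
  (editable defaults shipped in `inst/extdata/default_codesets.csv`);
* **CDM I/O** — read/validate/write the four-table subset
  (`demographic`, `encounter`, `diagnosis`, `lab_result_cm`) with
  row-level quarantine instead of silent drops;
* **Cohort phenotype** — patients < 21 years with T1D diagnoses in each of
  the two most recent 365-day blocks (incident patients bypass the
  prior-block rule and are flagged), ≥ 2 T1D ambulatory visits in the
  window, and no excluded diabetes type (T2D, secondary, steroid-induced,
  gestational, MODY), with per-patient rejection reasons;
* **Five measures** over the 365-day window ending at the anchor date:

  | id | definition |
  |---|---|
  | `TWO_A1C_GT9` | % patients with ≥ 2 HbA1c results > 9 % |
  | `FOUR_VISITS` | % patients with ≥ 4 T1D clinic visits |
  | `LAST_A1C` | median of each patient's most recent HbA1c |
  | `DKA_ADMIT` | % patients hospitalized for diabetic ketoacidosis (incident patients excluded from the denominator) |
  | `A1C_IMPROVE` | % patients whose two most recent HbA1c differ by ≥ 0.5 downward |

  aggregated per site and pooled overall with exact Clopper–Pearson 95 %
  intervals, rendered as performance-ordered benchmark tables;
* **Validation** — PPV, NPV and percent agreement of the CDM-derived
  measures against chart (or synthetic gold-standard) outcomes, per site
  and pooled;
* **A synthetic multi-site CDM generator** with planted per-patient truth
  and three configurable error mechanisms (external-lab loss, DKA
  overcoding, visit mislabeling), so the whole pipeline is testable
  without any real patient data.

## Worked example

Three synthetic sites, one of which loses 30 % of its A1c results to
external labs:

```r
library(t1dqm)
library(dplyr)

scenarios <- bind_rows(
  site_scenario("A", 300, rate_two_a1c_gt9 = 0.40, median_last_a1c_target = 8.9),
  site_scenario("B", 500, rate_two_a1c_gt9 = 0.10, median_last_a1c_target = 8.0),
  site_scenario("C", 150, rate_two_a1c_gt9 = 0.25, external_lab_loss = 0.3))

res <- run_pipeline(list(mode = "scenario", scenarios = scenarios,
                         seed = 42, out_dir = "demo_out"))

filter(res$site_summary, measure == "TWO_A1C_GT9")
#> # A tibble: 4 × 6
#>   site_id measure     n_eligible result ci_low ci_high
#>   <chr>   <chr>            <int>  <dbl>  <dbl>   <dbl>
#> 1 A       TWO_A1C_GT9        300   40    34.4     45.8
#> 2 B       TWO_A1C_GT9        500   10     7.51    13.0
#> 3 C       TWO_A1C_GT9        150   13.3   8.34    19.8
#> 4 Overall TWO_A1C_GT9        950   20    17.5     22.7
```

Sites A and B reproduce their planted rates exactly (40 % and 10 %); the
result is the per-site percentage with its exact binomial interval, and
`Overall` pools all 950 patients rather than averaging site rates. Site C
planted 25 % but reports 13.3 %: withheld lab results can only hide
positives. Validation against the planted gold standard shows exactly that
one-sided signature — among patients the CDM flagged, the chart always
agrees (PPV 1), while flagged-negative patients are sometimes truly
positive (NPV < 1):

```r
filter(res$validation, measure == "TWO_A1C_GT9",
       site_id %in% c("C", "Overall")) |>
  select(site_id, n_reviewed, ppv, npv)
#> # A tibble: 2 × 4
#>   site_id n_reviewed   ppv   npv
#>   <chr>        <int> <dbl> <dbl>
#> 1 C              150     1 0.862
#> 2 Overall        950     1 0.976
```

`run_pipeline()` also writes all artifacts (cohort, rejection log,
patient-level measures, site summaries, validation, Markdown benchmark
tables, run log) to `out_dir`. A thin command-line wrapper lives at
`inst/cli/t1dqm.R` (`run-all`, `generate`, `report` subcommands over a
JSON config).

The methods vignette (`vignettes/t1d-quality-measures.Rmd`) documents the
phenotype operationalization, the measure conventions, the generator's
design and its limitations.

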