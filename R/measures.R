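MEASURES <- c("TWO_A1C_GT9", "FOUR_VISITS", "LAST_A1C", "DKA_ADMIT",
              "A1C_IMPROVE")
# comparisons on the 0.1 % A1c grid need a float guard
EPS <- 1e-9

#' In-window HbA1c series for one patient
#'
#' HbA1c-classified lab results with `result_date` inside the window,
#' ascending by date. Same-date duplicates are collapsed to their mean and
#' values are rounded to 0.1 after averaging (the reporting precision of
#' the assay).
#'
#' @param labs One patient's lab rows.
#' @param window An [analysis_window()].
#' @param codesets Loaded code sets (the `hba1c_lab` LOINC set is used).
#' @return Tibble `(date, value)` ascending by date.
#' @export
a1c_series <- function(labs, window, codesets) {
  a1c_loincs <- codeset_entries(codesets, "hba1c_lab")$code
  labs |>
    filter(.data$lab_loinc %in% a1c_loincs,
           in_window(.data$result_date, window)) |>
    group_by(date = .data$result_date) |>
    summarise(value = round(mean(.data$result_num), 1), .groups = "drop") |>
    arrange(.data$date)
}

#' Two or more HbA1c results above 9 %
#'
#' Poor-glycemic-control flag: `TRUE` iff the in-window series contains at
#' least two values strictly greater than 9.0 (set `strict = FALSE` for an
#' inclusive threshold). Patients with no in-window A1c remain eligible
#' with a negative outcome, so the measure's denominator is the full cohort.
#'
#' @param series Result of [a1c_series()].
#' @param threshold A1c threshold in % units (default 9).
#' @param strict Use strict `>` (default) or `>=`.
#' @return Logical outcome.
#' @export
flag_two_a1c_gt9 <- function(series, threshold = 9, strict = TRUE) {
  hits <- if (strict) series$value > threshold + EPS
          else series$value >= threshold - EPS
  sum(hits) >= 2L
}

#' Four or more T1D clinic visits in the window
#' @param n_t1d_visits Visit count from the cohort stage.
#' @return Logical outcome: `n_t1d_visits >= 4`.
#' @export
flag_four_visits <- function(n_t1d_visits) n_t1d_visits >= 4L

#' Most recent in-window HbA1c
#' @param series Result of [a1c_series()].
#' @return The latest value, or `NA` (ineligible) when the series is empty.
#' @export
last_a1c <- function(series) {
  if (!nrow(series)) NA_real_ else series$value[nrow(series)]
}

#' HbA1c improvement of at least 0.5 percentage points
#'
#' Compares the two most recent in-window results: with `v_prev` the
#' earlier and `v_last` the later, the outcome is
#' `v_prev - v_last >= delta` (inclusive, default 0.5). Patients with fewer
#' than two in-window results are ineligible, which shrinks this measure's
#' denominator relative to the cohort.
#'
#' @param series Result of [a1c_series()].
#' @param delta Improvement threshold in percentage points (default 0.5).
#' @return Logical outcome, or `NA` (ineligible) with fewer than 2 results.
#' @export
flag_a1c_improvement <- function(series, delta = 0.5) {
  n <- nrow(series)
  if (n < 2L) return(NA)
  (series$value[n - 1L] - series$value[n]) >= delta - EPS
}

#' Hospitalization for diabetic ketoacidosis in the window
#'
#' `TRUE` iff the patient has at least one inpatient or
#' emergency-to-inpatient encounter (`enc_type` IP or EI) admitted inside
#' the window that carries a DKA-classified diagnosis on that encounter
#' (code-on-admission semantics; a same-window DKA code on an outpatient
#' encounter does not count). Newly diagnosed patients are ineligible:
#' their diagnostic DKA presentation is not a care-quality failure of the
#' measurement year.
#'
#' @param encounters,diagnoses One patient's encounter and diagnosis rows.
#' @param window An [analysis_window()].
#' @param codesets Loaded code sets.
#' @param newly_diagnosed Incident-patient flag from the cohort stage.
#' @return Logical outcome, or `NA` (ineligible) when `newly_diagnosed`.
#' @export
flag_dka_admission <- function(encounters, diagnoses, window, codesets,
                               newly_diagnosed = FALSE) {
  if (isTRUE(newly_diagnosed)) return(NA)
  dxc <- classify_dx_tbl(diagnoses, codesets)
  dka_encs <- unique(dxc$encounterid[dxc$is_dka & !is.na(dxc$encounterid)])
  any(encounters$enc_type %in% c("IP", "EI") &
        in_window(encounters$admit_date, window) &
        encounters$encounterid %in% dka_encs)
}

#' Compute all five patient-level measures for a site's cohort
#'
#' @param ds A `cdm_dataset`.
#' @param cohort Result of [eligible_cohort()] on the same dataset.
#' @param window An [analysis_window()].
#' @param codesets Loaded code sets.
#' @param a1c_threshold,strict_gt9 Threshold convention for the
#'   two-A1c measure (see [flag_two_a1c_gt9()]).
#' @param improve_delta Improvement threshold (see [flag_a1c_improvement()]).
#' @return Long tibble `(site_id, patid, measure, eligible, outcome)`:
#'   `outcome` is 0/1 for binary measures, the A1c value for `LAST_A1C`,
#'   and `NA` when ineligible.
#' @export
compute_patient_measures <- function(ds, cohort, window, codesets,
                                     a1c_threshold = 9, strict_gt9 = TRUE,
                                     improve_delta = 0.5) {
  stopifnot(inherits(ds, "cdm_dataset"))
  if (!nrow(cohort)) {
    return(tibble::tibble(site_id = character(), patid = character(),
                          measure = character(), eligible = logical(),
                          outcome = double()))
  }
  a1c_loincs <- codeset_entries(codesets, "hba1c_lab")$code
  # all patients' in-window A1c series at once (same-date mean, 0.1 rounding)
  series_all <- ds$labs |>
    filter(.data$patid %in% cohort$patid,
           .data$lab_loinc %in% a1c_loincs,
           in_window(.data$result_date, window)) |>
    group_by(.data$patid, date = .data$result_date) |>
    summarise(value = round(mean(.data$result_num), 1), .groups = "drop") |>
    arrange(.data$patid, .data$date)

  a1c_stats <- series_all |>
    group_by(.data$patid) |>
    summarise(
      n_a1c = dplyr::n(),
      n_gt9 = if (strict_gt9) sum(.data$value > a1c_threshold + EPS)
              else sum(.data$value >= a1c_threshold - EPS),
      v_last = dplyr::last(.data$value),
      v_prev = dplyr::nth(.data$value, -2L, default = NA_real_),
      .groups = "drop")

  # DKA admissions: IP/EI encounters in window carrying a DKA code
  dxc <- classify_dx_tbl(ds$diagnoses, codesets)
  dka_encs <- unique(dxc$encounterid[dxc$is_dka & !is.na(dxc$encounterid)])
  dka_pats <- ds$encounters |>
    filter(.data$enc_type %in% c("IP", "EI"),
           in_window(.data$admit_date, window),
           .data$encounterid %in% dka_encs) |>
    distinct(.data$patid) |>
    mutate(dka = TRUE)

  base <- cohort |>
    left_join(a1c_stats, by = "patid") |>
    left_join(dka_pats, by = "patid") |>
    mutate(n_a1c = ifelse(is.na(.data$n_a1c), 0L, .data$n_a1c),
           n_gt9 = ifelse(is.na(.data$n_gt9), 0L, .data$n_gt9),
           dka = !is.na(.data$dka))

  pm <- dplyr::bind_rows(
    transmute(base, site_id = .data$site_id, patid = .data$patid,
              measure = "TWO_A1C_GT9", eligible = TRUE,
              outcome = as.numeric(.data$n_gt9 >= 2L)),
    transmute(base, site_id = .data$site_id, patid = .data$patid,
              measure = "FOUR_VISITS", eligible = TRUE,
              outcome = as.numeric(.data$n_t1d_visits >= 4L)),
    transmute(base, site_id = .data$site_id, patid = .data$patid,
              measure = "LAST_A1C", eligible = .data$n_a1c >= 1L,
              outcome = .data$v_last),
    transmute(base, site_id = .data$site_id, patid = .data$patid,
              measure = "A1C_IMPROVE", eligible = .data$n_a1c >= 2L,
              outcome = ifelse(.data$n_a1c >= 2L,
                               as.numeric((.data$v_prev - .data$v_last) >=
                                            improve_delta - EPS),
                               NA_real_)),
    transmute(base, site_id = .data$site_id, patid = .data$patid,
              measure = "DKA_ADMIT", eligible = !.data$newly_diagnosed,
              outcome = ifelse(.data$newly_diagnosed, NA_real_,
                               as.numeric(.data$dka)))
  )
  arrange(pm, .data$measure, .data$patid)
}

#' Aggregate patient-level measures to site and overall summaries
#'
#' Proportion measures get `100 * k / n` with an exact Clopper--Pearson
#' 95 % interval (also on the percentage scale); `LAST_A1C` gets the median
#' of the eligible patients' values (midpoint of the two central values for
#' even counts) and no interval. The `Overall` row pools patients across
#' sites -- it is not an average of site rates. Internal arithmetic is full
#' precision; rounding happens only in the report layer.
#'
#' @param pm Patient-level measures from [compute_patient_measures()].
#' @param conf_level Confidence level for the intervals (default 0.95).
#' @return Tibble `(site_id, measure, n_eligible, result, ci_low, ci_high)`
#'   with `result` a percentage for proportion measures and a median %
#'   A1c for `LAST_A1C`; one `Overall` row per measure. Sites with zero
#'   eligible patients get `n_eligible = 0` and `NA` results.
#' @export
summarize_sites <- function(pm, conf_level = 0.95) {
  summarise_group <- function(d) {
    measure <- d$measure[1]
    el <- d[d$eligible & !is.na(d$outcome), ]
    n <- nrow(el)
    if (n == 0L) {
      return(tibble::tibble(n_eligible = 0L, result = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_))
    }
    if (measure == "LAST_A1C") {
      tibble::tibble(n_eligible = n,
                     result = stats::median(el$outcome),
                     ci_low = NA_real_, ci_high = NA_real_)
    } else {
      k <- sum(el$outcome > 0)
      ci <- clopper_pearson_ci(k, n, conf_level)
      tibble::tibble(n_eligible = n, result = 100 * k / n,
                     ci_low = 100 * ci[1], ci_high = 100 * ci[2])
    }
  }
  per_site <- pm |>
    group_by(.data$site_id, .data$measure) |>
    group_modify(~ summarise_group(mutate(.x, measure = .y$measure))) |>
    ungroup()
  overall <- pm |>
    group_by(.data$measure) |>
    group_modify(~ summarise_group(mutate(.x, measure = .y$measure))) |>
    ungroup() |>
    mutate(site_id = "Overall")
  dplyr::bind_rows(per_site, overall) |>
    select("site_id", "measure", "n_eligible", "result", "ci_low",
           "ci_high") |>
    arrange(.data$measure, .data$site_id == "Overall", .data$site_id)
}
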