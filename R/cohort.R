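#' Define the measurement window
#'
#' All measures are assessed over a lookback window ending at the anchor
#' date: the closed interval `[anchor - (lookback_days - 1), anchor]`,
#' containing exactly `lookback_days` distinct days. The preceding block of
#' the same length (used by the multi-year diagnosis criterion) is also
#' carried.
#'
#' @param anchor_date Anchor (reference) date, `Date` or ISO string.
#' @param lookback_days Window length in days (default 365).
#' @return A list of class `analysis_window` with `anchor`, `start`, `end`,
#'   `prior_start`, `prior_end`, `lookback_days`.
#' @export
#' @examples
#' w <- analysis_window("2018-12-31")
#' w$start  # 2018-01-01
analysis_window <- function(anchor_date, lookback_days = 365L) {
  anchor <- as.Date(anchor_date)
  stopifnot(!is.na(anchor), lookback_days >= 1)
  lookback_days <- as.integer(lookback_days)
  structure(list(
    anchor = anchor,
    start = anchor - (lookback_days - 1L),
    end = anchor,
    prior_start = anchor - (2L * lookback_days - 1L),
    prior_end = anchor - lookback_days,
    lookback_days = lookback_days
  ), class = "analysis_window")
}

in_window <- function(dates, window) {
  dates >= window$start & dates <= window$end
}
in_prior_block <- function(dates, window) {
  dates >= window$prior_start & dates <= window$prior_end
}

#' Age in completed years at a date
#'
#' Birthday arithmetic (floored year difference), not division by 365.25:
#' a patient is `n` years old from their n-th birthday up to the day before
#' their (n+1)-th.
#'
#' @param birth_date,at Date vectors (recycled).
#' @return Integer vector of completed years.
#' @export
age_at <- function(birth_date, at) {
  birth_date <- as.Date(birth_date); at <- as.Date(at)
  b <- as.POSIXlt(birth_date); a <- as.POSIXlt(at)
  yrs <- a$year - b$year
  before_birthday <- (a$mon < b$mon) | (a$mon == b$mon & a$mday < b$mday)
  as.integer(yrs - before_birthday)
}

#' Earliest T1D diagnosis date for a patient
#'
#' @param diagnoses Diagnosis tibble (one patient's rows) with `dx`,
#'   `dx_type`, `dx_date`.
#' @param codesets Loaded code sets.
#' @return The earliest `dx_date` among T1D-classified rows, or `NA` if none.
#' @export
first_t1d_date <- function(diagnoses, codesets) {
  dxc <- classify_dx_tbl(diagnoses, codesets)
  d <- dxc$dx_date[dxc$is_t1d]
  if (!length(d)) as.Date(NA) else min(d)
}

# T1D-related ambulatory visit dates for all patients at once.
# A visit is an AV/TH encounter carrying >= 1 T1D-classified diagnosis on
# that encounter; same-day encounters collapse to one visit date.
t1d_visit_dates <- function(encounters, diagnoses, codesets) {
  dxc <- classify_dx_tbl(diagnoses, codesets)
  t1d_encs <- unique(dxc$encounterid[dxc$is_t1d & !is.na(dxc$encounterid)])
  encounters |>
    filter(.data$enc_type %in% c("AV", "TH"),
           .data$encounterid %in% t1d_encs) |>
    distinct(.data$patid, date = .data$admit_date)
}

#' Count T1D-related ambulatory visits in the window
#'
#' Number of distinct admit dates, inside the window, of ambulatory or
#' telehealth encounters (`enc_type` AV or TH) carrying at least one
#' T1D-classified diagnosis on the encounter itself. Two same-day
#' encounters count once; inpatient stays contribute nothing.
#'
#' @param encounters,diagnoses One patient's encounter and diagnosis rows.
#' @param window An [analysis_window()].
#' @param codesets Loaded code sets.
#' @return Integer count of distinct visit dates.
#' @export
count_t1d_visits <- function(encounters, diagnoses, window, codesets) {
  v <- t1d_visit_dates(encounters, diagnoses, codesets)
  sum(in_window(v$date, window))
}

#' Apply the T1D computable phenotype to one site
#'
#' A patient enters the cohort iff, at the anchor date, they are
#' (a) younger than 21 years (completed years), (b) have at least one
#' T1D-classified diagnosis in the lookback window and at least one in the
#' preceding 365-day block -- incident patients, whose first T1D diagnosis
#' falls inside the window, bypass the prior-block requirement --
#' (c) have two or more T1D-related ambulatory visits in the window, and
#' (d) carry no excluded-diabetes diagnosis (type 2, secondary,
#' steroid-induced, gestational, MODY) at any time. The `newly_diagnosed`
#' flag marks incident patients; they stay in the cohort but are excluded
#' from the DKA measure denominator.
#'
#' @param ds A `cdm_dataset`.
#' @param window An [analysis_window()].
#' @param codesets Loaded code sets.
#' @return Tibble of cohort members `(site_id, patid, age_at_anchor,
#'   first_t1d_date, n_t1d_visits, newly_diagnosed)`, sorted by `patid`.
#'   The per-patient rejection log (columns `patid`, `reasons`,
#'   semicolon-separated failed criteria) is attached as attribute
#'   `"rejections"`; see [cohort_rejections()].
#' @export
eligible_cohort <- function(ds, window, codesets) {
  stopifnot(inherits(ds, "cdm_dataset"), inherits(window, "analysis_window"))
  demo <- ds$demographics
  if (!nrow(demo)) {
    out <- tibble::tibble(site_id = character(), patid = character(),
                          age_at_anchor = integer(),
                          first_t1d_date = as.Date(character()),
                          n_t1d_visits = integer(),
                          newly_diagnosed = logical())
    attr(out, "rejections") <- tibble::tibble(patid = character(),
                                              reasons = character())
    return(out)
  }
  dxc <- classify_dx_tbl(ds$diagnoses, codesets)

  per_pat_dx <- dxc |>
    group_by(.data$patid) |>
    summarise(
      first_t1d = if (any(.data$is_t1d)) min(.data$dx_date[.data$is_t1d])
                  else as.Date(NA),
      t1d_in_window = any(.data$is_t1d & in_window(.data$dx_date, window)),
      t1d_in_prior = any(.data$is_t1d & in_prior_block(.data$dx_date, window)),
      any_excluded = any(.data$is_excluded),
      .groups = "drop")

  visits <- t1d_visit_dates(ds$encounters, ds$diagnoses, codesets) |>
    filter(in_window(.data$date, window)) |>
    count(.data$patid, name = "n_t1d_visits")

  cand <- demo |>
    left_join(per_pat_dx, by = "patid") |>
    left_join(visits, by = "patid") |>
    mutate(
      n_t1d_visits = ifelse(is.na(.data$n_t1d_visits), 0L, .data$n_t1d_visits),
      t1d_in_window = !is.na(.data$t1d_in_window) & .data$t1d_in_window,
      t1d_in_prior = !is.na(.data$t1d_in_prior) & .data$t1d_in_prior,
      any_excluded = !is.na(.data$any_excluded) & .data$any_excluded,
      age = age_at(.data$birth_date, window$anchor),
      newly_diagnosed = !is.na(.data$first_t1d) &
        in_window(.data$first_t1d, window),
      ok_age = .data$age < 21L,
      ok_dx = .data$t1d_in_window &
        (.data$t1d_in_prior | .data$newly_diagnosed),
      ok_visits = .data$n_t1d_visits >= 2L,
      ok_not_excluded = !.data$any_excluded,
      eligible = .data$ok_age & .data$ok_dx & .data$ok_visits &
        .data$ok_not_excluded)

  reasons <- function(row) {
    r <- character()
    if (!row$ok_age) r <- c(r, "age_ge_21")
    if (!row$t1d_in_window) r <- c(r, "no_t1d_dx_in_window")
    else if (!row$ok_dx) r <- c(r, "single_year_t1d_dx")
    if (!row$ok_visits) r <- c(r, "insufficient_t1d_visits")
    if (!row$ok_not_excluded) r <- c(r, "excluded_diabetes_dx")
    paste(r, collapse = ";")
  }
  rejected <- cand[!cand$eligible, ]
  rejections <- tibble::tibble(
    patid = rejected$patid,
    reasons = vapply(seq_len(nrow(rejected)),
                     function(i) reasons(rejected[i, ]), character(1)))

  members <- cand |>
    filter(.data$eligible) |>
    transmute(site_id = ds$site_id, patid = .data$patid,
              age_at_anchor = .data$age,
              first_t1d_date = .data$first_t1d,
              n_t1d_visits = as.integer(.data$n_t1d_visits),
              newly_diagnosed = .data$newly_diagnosed) |>
    arrange(.data$patid)
  attr(members, "rejections") <- arrange(rejections, .data$patid)
  members
}

#' Rejection log of a cohort
#'
#' @param cohort Result of [eligible_cohort()].
#' @return Tibble `(patid, reasons)`; `reasons` is a semicolon-separated
#'   list of failed phenotype criteria.
#' @export
cohort_rejections <- function(cohort) attr(cohort, "rejections")
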