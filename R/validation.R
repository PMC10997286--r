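#' Exact (Clopper--Pearson) binomial confidence interval
#'
#' Computed from beta-distribution quantiles:
#' lower `= qbeta(alpha/2, k, n - k + 1)` (0 when `k = 0`),
#' upper `= qbeta(1 - alpha/2, k + 1, n - k)` (1 when `k = n`).
#' At the boundaries this reduces to the closed forms
#' `upper = 1 - (alpha/2)^(1/n)` for `k = 0` and its mirror for `k = n`.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param conf_level Confidence level (default 0.95).
#' @return Numeric `c(low, high)` on the proportion scale.
#' @export
#' @examples
#' clopper_pearson_ci(0, 10)   # c(0, 0.3085)
#' clopper_pearson_ci(10, 10)
clopper_pearson_ci <- function(k, n, conf_level = 0.95) {
  stopifnot(length(k) == 1L, length(n) == 1L, n >= 1, k >= 0, k <= n)
  alpha <- 1 - conf_level
  low <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  high <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(low, high)
}

#' Build a 2x2 contingency table from paired binary outcomes
#'
#' @param cdm_outcome,chart_outcome Paired logical (or 0/1) vectors: the
#'   automated CDM-derived outcome and the chart-review outcome for the
#'   same patients, in the same order.
#' @return A list of class `t1d_contingency` with counts `tp` (both
#'   positive), `fp` (CDM positive, chart negative), `tn` (both negative),
#'   `fn` (CDM negative, chart positive) and `n`.
#' @export
build_contingency <- function(cdm_outcome, chart_outcome) {
  stopifnot(length(cdm_outcome) == length(chart_outcome))
  cdm <- as.logical(cdm_outcome); chart <- as.logical(chart_outcome)
  keep <- !is.na(cdm) & !is.na(chart)
  cdm <- cdm[keep]; chart <- chart[keep]
  structure(list(
    tp = sum(cdm & chart), fp = sum(cdm & !chart),
    tn = sum(!cdm & !chart), fn = sum(!cdm & chart),
    n = length(cdm)
  ), class = "t1d_contingency")
}

#' Positive and negative predictive value of a contingency table
#'
#' PPV = tp / (tp + fp): among patients the automated measure flagged
#' positive, the fraction the chart confirmed. NPV = tn / (tn + fn),
#' likewise for negatives. An empty denominator yields `NA` (undefined),
#' never 0.
#'
#' @param contingency A `t1d_contingency` from [build_contingency()].
#' @return Named list `ppv`, `npv`.
#' @export
predictive_values <- function(contingency) {
  stopifnot(inherits(contingency, "t1d_contingency"))
  pos <- contingency$tp + contingency$fp
  neg <- contingency$tn + contingency$fn
  list(
    ppv = if (pos == 0) NA_real_ else contingency$tp / pos,
    npv = if (neg == 0) NA_real_ else contingency$tn / neg
  )
}

#' Percent agreement between CDM-derived and chart last-A1c values
#'
#' Fraction of paired values agreeing within `tolerance` (default 0.05,
#' i.e. equality at the one-decimal reporting precision).
#'
#' @param cdm_values,chart_values Paired numeric vectors.
#' @param tolerance Absolute agreement tolerance in % A1c units.
#' @return Fraction in `[0, 1]`, or `NA` with zero pairs.
#' @export
percent_agreement_last_a1c <- function(cdm_values, chart_values,
                                       tolerance = 0.05) {
  stopifnot(length(cdm_values) == length(chart_values))
  keep <- !is.na(cdm_values) & !is.na(chart_values)
  if (!any(keep)) return(NA_real_)
  mean(abs(cdm_values[keep] - chart_values[keep]) <= tolerance + EPS)
}

#' Validate CDM-derived measures against chart-review outcomes
#'
#' Pairs the automated patient-level outcomes with chart (or synthetic
#' gold-standard) records on `(site_id, patid, measure)`; pairs where
#' either side is ineligible or missing are dropped. Binary measures get
#' per-site and pooled-overall PPV and NPV with exact binomial intervals;
#' `LAST_A1C` gets percent agreement at `tolerance`. Sites present in the
#' measures but absent from the chart records are emitted with
#' `n_reviewed = 0` and `NA` statistics (the benchmark tables print these
#' as N/A). The overall row pools contingency counts across sites, not
#' site-level averages.
#'
#' @param pm Patient-level measures from [compute_patient_measures()].
#' @param chart Tibble `(site_id, patid, measure, eligible, outcome)` --
#'   the format written by [write_gold_standard()] / chart abstraction.
#' @param per_site Emit per-site rows in addition to the overall row.
#' @param tolerance Agreement tolerance for `LAST_A1C`.
#' @param conf_level Confidence level for the intervals.
#' @return Tibble with columns `site_id`, `measure`, `n_reviewed`, `tp`,
#'   `fp`, `tn`, `fn`, `ppv`, `ppv_low`, `ppv_high`, `npv`, `npv_low`,
#'   `npv_high`, `agreement`, `agreement_low`, `agreement_high`.
#' @export
validate_measures <- function(pm, chart, per_site = TRUE, tolerance = 0.05,
                              conf_level = 0.95) {
  chart <- tibble::as_tibble(chart)
  if (!"eligible" %in% names(chart)) chart$eligible <- TRUE
  pairs <- pm |>
    filter(.data$eligible, !is.na(.data$outcome)) |>
    inner_join(
      chart |>
        filter(.data$eligible, !is.na(.data$outcome)) |>
        select("site_id", "patid", "measure", chart_outcome = "outcome"),
      by = c("site_id", "patid", "measure"))

  na_row <- function(site, measure, n = 0L) tibble::tibble(
    site_id = site, measure = measure, n_reviewed = n,
    tp = NA_integer_, fp = NA_integer_, tn = NA_integer_, fn = NA_integer_,
    ppv = NA_real_, ppv_low = NA_real_, ppv_high = NA_real_,
    npv = NA_real_, npv_low = NA_real_, npv_high = NA_real_,
    agreement = NA_real_, agreement_low = NA_real_, agreement_high = NA_real_)

  one_group <- function(d, site, measure) {
    n <- nrow(d)
    if (n == 0L) return(na_row(site, measure))
    out <- na_row(site, measure, n)
    if (measure == "LAST_A1C") {
      agree <- abs(d$outcome - d$chart_outcome) <= tolerance + EPS
      k <- sum(agree)
      ci <- clopper_pearson_ci(k, n, conf_level)
      out$agreement <- k / n
      out$agreement_low <- ci[1]; out$agreement_high <- ci[2]
    } else {
      ct <- build_contingency(d$outcome > 0, d$chart_outcome > 0)
      pv <- predictive_values(ct)
      out$tp <- ct$tp; out$fp <- ct$fp; out$tn <- ct$tn; out$fn <- ct$fn
      out$ppv <- pv$ppv; out$npv <- pv$npv
      if (!is.na(pv$ppv)) {
        ci <- clopper_pearson_ci(ct$tp, ct$tp + ct$fp, conf_level)
        out$ppv_low <- ci[1]; out$ppv_high <- ci[2]
      }
      if (!is.na(pv$npv)) {
        ci <- clopper_pearson_ci(ct$tn, ct$tn + ct$fn, conf_level)
        out$npv_low <- ci[1]; out$npv_high <- ci[2]
      }
    }
    out
  }

  measures_present <- unique(pm$measure)
  sites_present <- unique(pm$site_id)
  rows <- list()
  if (per_site) {
    for (m in measures_present) {
      for (s in sites_present) {
        d <- pairs[pairs$measure == m & pairs$site_id == s, ]
        rows[[length(rows) + 1L]] <- one_group(d, s, m)
      }
    }
  }
  for (m in measures_present) {
    d <- pairs[pairs$measure == m, ]
    rows[[length(rows) + 1L]] <- one_group(d, "Overall", m)
  }
  dplyr::bind_rows(rows) |>
    arrange(.data$measure, .data$site_id == "Overall", .data$site_id)
}
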