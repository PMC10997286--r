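#' Describe one synthetic site
#'
#' A scenario fixes a site's cohort size, the planted per-measure rates,
#' the target median last A1c, the share of newly diagnosed (incident)
#' patients, and the strength of the three error mechanisms observed when
#' CDM-derived measures are checked against charts: HbA1c results held in
#' external lab systems and absent from the CDM, DKA codes attached to
#' admissions that were primarily for another reason, and T1D visit-label
#' misclassification.
#'
#' @param site_id Site identifier.
#' @param n_patients Number of cohort (phenotype-positive) patients.
#' @param rate_two_a1c_gt9,rate_four_visits,rate_dka,rate_improvement
#'   Planted outcome rates, fractions in `[0, 1]`. The DKA rate applies to
#'   the DKA-eligible denominator (cohort minus incident patients).
#' @param median_last_a1c_target Target site median of the last A1c (%).
#' @param frac_newly_diagnosed Fraction of incident patients.
#' @param external_lab_loss Fraction of CDM A1c rows withheld (chart keeps
#'   them).
#' @param dka_overcode Fraction of non-DKA inpatient admissions given a
#'   DKA code.
#' @param visit_mislabel Fraction of true T1D visits whose label is
#'   swapped with a non-T1D visit.
#' @return One-row tibble of scenario parameters.
#' @export
site_scenario <- function(site_id, n_patients,
                          rate_two_a1c_gt9 = 0.25,
                          rate_four_visits = 0.50,
                          rate_dka = 0.05,
                          rate_improvement = 0.20,
                          median_last_a1c_target = 8.5,
                          frac_newly_diagnosed = 0.10,
                          external_lab_loss = 0,
                          dka_overcode = 0,
                          visit_mislabel = 0) {
  fr <- c(rate_two_a1c_gt9, rate_four_visits, rate_dka, rate_improvement,
          frac_newly_diagnosed, external_lab_loss, dka_overcode,
          visit_mislabel)
  stopifnot(n_patients >= 1, all(fr >= 0 & fr <= 1))
  tibble::tibble(site_id = as.character(site_id),
                 n_patients = as.integer(n_patients),
                 rate_two_a1c_gt9 = rate_two_a1c_gt9,
                 rate_four_visits = rate_four_visits,
                 rate_dka = rate_dka,
                 rate_improvement = rate_improvement,
                 median_last_a1c_target = median_last_a1c_target,
                 frac_newly_diagnosed = frac_newly_diagnosed,
                 external_lab_loss = external_lab_loss,
                 dka_overcode = dka_overcode,
                 visit_mislabel = visit_mislabel)
}

#' A 12-site benchmark network
#'
#' Scenario set emulating a realistic multi-site pediatric T1D network:
#' cohort sizes from 26 to 1,776 and per-site rate spans of roughly
#' 3--47 % for two A1c results above 9, 23--88 % for four or more visits,
#' 1.6--32 % for DKA admissions, 1--27 % for A1c improvement, and site
#' median last A1c between 7.9 and 10.2 %. All corruption fractions are 0;
#' set them per site to study the error mechanisms.
#'
#' @return Tibble of 12 [site_scenario()] rows.
#' @export
benchmark_scenarios <- function() {
  dplyr::bind_rows(
    site_scenario("A", 824,  0.443, 0.339, 0.083, 0.267, 8.8),
    site_scenario("C", 1554, 0.295, 0.594, 0.049, 0.238, 8.3),
    site_scenario("D", 1769, 0.053, 0.500, 0.071, 0.127, 9.1),
    site_scenario("E", 1171, 0.365, 0.500, 0.059, 0.251, 8.5),
    site_scenario("F", 289,  0.470, 0.502, 0.059, 0.260, 9.0),
    site_scenario("G", 646,  0.029, 0.444, 0.072, 0.011, 9.8),
    site_scenario("I", 1165, 0.373, 0.440, 0.049, 0.246, 8.5),
    site_scenario("K", 1776, 0.347, 0.454, 0.020, 0.238, 8.4),
    site_scenario("M", 117,  0.264, 0.282, 0.316, 0.078, 10.2),
    site_scenario("N", 200,  0.079, 0.321, 0.077, 0.086, 7.9),
    site_scenario("O", 335,  0.059, 0.883, 0.016, 0.146, 8.1),
    site_scenario("P", 26,   0.461, 0.230, 0.042, 0.111, 9.6)
  )
}

# deterministic 32-bit seed from (master seed, site_id); adding a site
# never perturbs the stream of another
site_seed <- function(seed, site_id) {
  h <- 0
  for (u in utf8ToInt(site_id)) h <- (h * 131 + u) %% 1000000007
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629 + 1)
}

rnd01 <- function(x) round(x, 1)  # 0.1 % A1c grid

# Sample k distinct day-offsets in [lo, 364] for each patient (vectorized
# over patients); returns a list of integer vectors.
sample_offsets <- function(lo, k) {
  mapply(function(l, kk) l + sample.int(365L - l, kk) - 1L, lo, k,
         SIMPLIFY = FALSE)
}

generate_site <- function(sc, window, seed, decoy_frac = 0.10) {
  set.seed(site_seed(seed, sc$site_id))
  n <- sc$n_patients
  anchor <- window$anchor
  wstart <- window$start
  patid <- sprintf("%s-P%05d", sc$site_id, seq_len(n))

  pick <- function(rate, from = seq_len(n)) {
    k <- round(rate * length(from))
    flags <- logical(n)
    if (k > 0) flags[from[sample.int(length(from), k)]] <- TRUE
    flags
  }
  newly <- pick(sc$frac_newly_diagnosed)
  two9 <- pick(sc$rate_two_a1c_gt9)
  four <- pick(sc$rate_four_visits)
  improve <- pick(sc$rate_improvement)
  dka <- pick(sc$rate_dka, from = which(!newly))

  # demographics: ages 2-20 completed years at anchor
  age_years <- sample(2:20, n, replace = TRUE)
  birth_date <- anchor - (age_years * 365L + sample(5:300, n, replace = TRUE))
  demo <- tibble::tibble(
    patid = patid, birth_date = birth_date,
    sex = sample(c("F", "M"), n, replace = TRUE),
    race = sample(c("White", "Black or African American", "Asian",
                    "Other", "Multiple race"), n, replace = TRUE,
                  prob = c(0.68, 0.10, 0.05, 0.12, 0.05)),
    hispanic = sample(c("Y", "N"), n, replace = TRUE, prob = c(0.13, 0.87)))

  # first T1D diagnosis: incident patients inside the window (leaving room
  # for subsequent visits/labs), established patients in the prior block
  first_off <- ifelse(newly, sample(0:244, n, replace = TRUE), 0L)
  first_t1d <- as.Date(ifelse(newly, wstart + first_off,
                              anchor - sample(380:720, n, replace = TRUE)),
                       origin = "1970-01-01")

  enc_rows <- list(); dx_rows <- list(); lab_rows <- list()
  enc_ctr <- 0L; dx_ctr <- 0L; lab_ctr <- 0L
  eid <- function(k) sprintf("%s-E%07d", sc$site_id, enc_ctr + seq_len(k))
  did <- function(k) sprintf("%s-X%07d", sc$site_id, dx_ctr + seq_len(k))
  lid <- function(k) sprintf("%s-L%07d", sc$site_id, lab_ctr + seq_len(k))

  # standalone first-diagnosis record for every patient
  dx_rows[[1]] <- tibble::tibble(
    diagnosisid = did(n), patid = patid, encounterid = NA_character_,
    dx = "E10.9", dx_type = "ICD10CM", dx_date = first_t1d)
  dx_ctr <- dx_ctr + n

  t1d_dx_pool <- tibble::tibble(
    dx = c("E10.9", "E10.65", "E10.8", "250.01", "46635009"),
    dx_type = c("ICD10CM", "ICD10CM", "ICD10CM", "ICD9CM", "SNOMED"),
    w = c(0.62, 0.15, 0.08, 0.10, 0.05))

  # T1D ambulatory visits (outcome-positive patients get >= 4)
  n_vis <- ifelse(four, sample(4:8, n, replace = TRUE),
                  sample(2:3, n, replace = TRUE))
  vis_off <- sample_offsets(first_off, n_vis)
  vdates <- as.Date(wstart + unlist(vis_off), origin = "1970-01-01")
  nv <- length(vdates)
  vpat <- rep(patid, n_vis)
  vid <- eid(nv); enc_ctr <- enc_ctr + nv
  pool_i <- sample.int(nrow(t1d_dx_pool), nv, replace = TRUE,
                       prob = t1d_dx_pool$w)
  enc_rows[[1]] <- tibble::tibble(
    encounterid = vid, patid = vpat, admit_date = vdates,
    discharge_date = as.Date(NA),
    enc_type = sample(c("AV", "TH"), nv, replace = TRUE,
                      prob = c(0.9, 0.1)))
  dx_rows[[2]] <- tibble::tibble(
    diagnosisid = did(nv), patid = vpat, encounterid = vid,
    dx = t1d_dx_pool$dx[pool_i], dx_type = t1d_dx_pool$dx_type[pool_i],
    dx_date = vdates)
  dx_ctr <- dx_ctr + nv

  # non-T1D ambulatory visits (primary care etc.) -- mislabeling targets
  n_extra <- sample(0:3, n, replace = TRUE)
  ne <- sum(n_extra)
  if (ne > 0) {
    edates <- as.Date(wstart + sample(0:364, ne, replace = TRUE),
                      origin = "1970-01-01")
    epat <- rep(patid, n_extra)
    xid <- eid(ne); enc_ctr <- enc_ctr + ne
    other_dx <- sample(c("Z00.129", "J45.909", "R10.9"), ne, replace = TRUE,
                       prob = c(0.6, 0.25, 0.15))
    enc_rows[[2]] <- tibble::tibble(
      encounterid = xid, patid = epat, admit_date = edates,
      discharge_date = as.Date(NA), enc_type = "AV")
    dx_rows[[3]] <- tibble::tibble(
      diagnosisid = did(ne), patid = epat, encounterid = xid,
      dx = other_dx, dx_type = "ICD10CM", dx_date = edates)
    dx_ctr <- dx_ctr + ne
  }

  # DKA admissions for outcome-positive patients
  nd <- sum(dka)
  if (nd > 0) {
    dpat <- patid[dka]
    ddates <- as.Date(wstart + sample(0:364, nd, replace = TRUE),
                      origin = "1970-01-01")
    iid <- eid(nd); enc_ctr <- enc_ctr + nd
    dka_code <- sample(c("E10.10", "E10.11", "250.13"), nd, replace = TRUE,
                       prob = c(0.7, 0.15, 0.15))
    enc_rows[[3]] <- tibble::tibble(
      encounterid = iid, patid = dpat, admit_date = ddates,
      discharge_date = ddates + sample(1:4, nd, replace = TRUE),
      enc_type = sample(c("IP", "EI"), nd, replace = TRUE,
                        prob = c(0.8, 0.2)))
    dx_rows[[4]] <- tibble::tibble(
      diagnosisid = did(nd), patid = dpat, encounterid = iid,
      dx = dka_code,
      dx_type = ifelse(dka_code == "250.13", "ICD9CM", "ICD10CM"),
      dx_date = ddates)
    dx_ctr <- dx_ctr + nd
  }

  # non-DKA inpatient admissions (eg, surgery) -- overcoding targets
  ip_extra <- which(stats::runif(n) < 0.20)
  ni <- length(ip_extra)
  if (ni > 0) {
    ipat <- patid[ip_extra]
    idates <- as.Date(wstart + sample(0:364, ni, replace = TRUE),
                      origin = "1970-01-01")
    iid <- eid(ni); enc_ctr <- enc_ctr + ni
    enc_rows[[4]] <- tibble::tibble(
      encounterid = iid, patid = ipat, admit_date = idates,
      discharge_date = idates + sample(1:3, ni, replace = TRUE),
      enc_type = "IP")
    dx_rows[[5]] <- tibble::tibble(
      diagnosisid = did(ni), patid = ipat, encounterid = iid,
      dx = sample(c("K35.80", "S52.501A", "J18.9"), ni, replace = TRUE),
      dx_type = "ICD10CM", dx_date = idates)
    dx_ctr <- dx_ctr + ni
  }

  # A1c trajectories: last and previous values carry the planted
  # improvement / poor-control outcomes; earlier values fill the series
  target <- sc$median_last_a1c_target
  v_last <- rnd01(pmin(pmax(stats::rnorm(n, target, 1), 4), 16))
  v_last <- ifelse(improve & !two9, pmin(v_last, 8.4), v_last)
  d_imp <- rnd01(stats::runif(n, 0.5, 1.5))
  d_non <- rnd01(stats::runif(n, -1.5, 0.44))
  v_prev <- rnd01(v_last + ifelse(improve, d_imp, d_non))
  v_prev <- pmax(v_prev, 3.5)
  clash <- !two9 & !improve & v_prev > 9 & v_last > 9
  if (any(clash)) v_prev[clash] <- rnd01(stats::runif(sum(clash), 7, 8.9))

  m_lab <- ifelse(two9, sample(4:6, n, replace = TRUE),
                  sample(2:5, n, replace = TRUE))
  lab_off <- lapply(sample_offsets(first_off, m_lab), sort)
  lab_list <- vector("list", n)
  for (i in seq_len(n)) {
    m <- m_lab[i]
    vals <- numeric(m)
    vals[m] <- v_last[i]
    vals[m - 1L] <- v_prev[i]
    n_earlier <- m - 2L
    if (n_earlier > 0) {
      if (two9[i]) {
        need <- max(0L, 2L - (v_prev[i] > 9) - (v_last[i] > 9))
        earlier <- rnd01(pmin(pmax(stats::rnorm(n_earlier, target, 1), 4),
                              16))
        if (need > 0) earlier[seq_len(need)] <- rnd01(
          stats::runif(need, 9.2, 12))
        vals[seq_len(n_earlier)] <- earlier
      } else {
        vals[seq_len(n_earlier)] <- rnd01(stats::runif(n_earlier, 6.5, 9.0))
      }
    } else if (two9[i]) {
      # m == 2: force both values above threshold, keep planted delta
      if (v_last[i] <= 9) {
        shift <- 9.1 - v_last[i]
        v_last[i] <- rnd01(v_last[i] + shift)
        v_prev[i] <- rnd01(v_prev[i] + shift)
        vals[m] <- v_last[i]; vals[m - 1L] <- v_prev[i]
      }
      if (v_prev[i] <= 9) v_prev[i] <- vals[m - 1L] <- 9.1
    }
    lab_list[[i]] <- vals
  }
  lvals <- unlist(lab_list)
  ldates <- as.Date(wstart + unlist(lab_off), origin = "1970-01-01")
  nl <- length(lvals)
  lab_rows[[1]] <- tibble::tibble(
    lab_result_cm_id = lid(nl), patid = rep(patid, m_lab),
    lab_loinc = sample(c("4548-4", "17856-6"), nl, replace = TRUE,
                       prob = c(0.8, 0.2)),
    result_num = lvals, result_date = ldates)
  lab_ctr <- lab_ctr + nl

  # decoy patients: one per phenotype rule, cycled
  n_decoy <- if (decoy_frac > 0) max(4L, ceiling(decoy_frac * n)) else 0L
  if (n_decoy > 0) {
    dtype <- rep_len(c("age", "excluded", "one_visit", "single_year"),
                     n_decoy)
    dpatid <- sprintf("%s-D%04d", sc$site_id, seq_len(n_decoy))
    dbirth <- ifelse(dtype == "age",
                     anchor - (21L * 365L + 30L +
                                 sample(0:1500, n_decoy, replace = TRUE)),
                     anchor - (sample(3:19, n_decoy, replace = TRUE) * 365L +
                                 sample(5:300, n_decoy, replace = TRUE)))
    dbirth <- as.Date(dbirth, origin = "1970-01-01")
    dfirst <- as.Date(ifelse(dtype == "single_year",
                             anchor - sample(740:900, n_decoy, replace = TRUE),
                             anchor - sample(400:700, n_decoy, replace = TRUE)),
                      origin = "1970-01-01")
    demo <- dplyr::bind_rows(demo, tibble::tibble(
      patid = dpatid, birth_date = dbirth,
      sex = sample(c("F", "M"), n_decoy, replace = TRUE),
      race = "White", hispanic = "N"))
    dx_rows[[length(dx_rows) + 1L]] <- tibble::tibble(
      diagnosisid = did(n_decoy), patid = dpatid,
      encounterid = NA_character_, dx = "E10.9", dx_type = "ICD10CM",
      dx_date = dfirst)
    dx_ctr <- dx_ctr + n_decoy
    # visits: 2 for most, 1 for the one-visit decoy
    dnvis <- ifelse(dtype == "one_visit", 1L, 2L)
    dvoff <- sample_offsets(rep(0L, n_decoy), dnvis)
    dvd <- as.Date(wstart + unlist(dvoff), origin = "1970-01-01")
    dvpat <- rep(dpatid, dnvis)
    nv2 <- length(dvd)
    vid2 <- eid(nv2); enc_ctr <- enc_ctr + nv2
    enc_rows[[length(enc_rows) + 1L]] <- tibble::tibble(
      encounterid = vid2, patid = dvpat, admit_date = dvd,
      discharge_date = as.Date(NA), enc_type = "AV")
    dx_rows[[length(dx_rows) + 1L]] <- tibble::tibble(
      diagnosisid = did(nv2), patid = dvpat, encounterid = vid2,
      dx = "E10.9", dx_type = "ICD10CM", dx_date = dvd)
    dx_ctr <- dx_ctr + nv2
    # excluded-diabetes decoys carry a lifetime exclusion code
    excl <- which(dtype == "excluded")
    if (length(excl)) {
      exdx <- sample(c("E11.9", "E08.9", "E09.9", "O24.419", "E13.9"),
                     length(excl), replace = TRUE)
      dx_rows[[length(dx_rows) + 1L]] <- tibble::tibble(
        diagnosisid = did(length(excl)), patid = dpatid[excl],
        encounterid = NA_character_, dx = exdx, dx_type = "ICD10CM",
        dx_date = as.Date(wstart + sample(0:364, length(excl),
                                          replace = TRUE),
                          origin = "1970-01-01"))
      dx_ctr <- dx_ctr + length(excl)
    }
    dlab <- as.Date(wstart + sample(0:364, n_decoy, replace = TRUE),
                    origin = "1970-01-01")
    lab_rows[[length(lab_rows) + 1L]] <- tibble::tibble(
      lab_result_cm_id = lid(n_decoy), patid = dpatid,
      lab_loinc = "4548-4",
      result_num = rnd01(stats::runif(n_decoy, 6.5, 9.5)),
      result_date = dlab)
    lab_ctr <- lab_ctr + n_decoy
  }

  ds <- cdm_dataset(
    sc$site_id,
    demographics = demo,
    encounters = dplyr::bind_rows(enc_rows),
    diagnoses = dplyr::bind_rows(dx_rows),
    labs = dplyr::bind_rows(lab_rows))

  gold <- dplyr::bind_rows(
    tibble::tibble(site_id = sc$site_id, patid = patid,
                   measure = "TWO_A1C_GT9", eligible = TRUE,
                   outcome = as.numeric(two9)),
    tibble::tibble(site_id = sc$site_id, patid = patid,
                   measure = "FOUR_VISITS", eligible = TRUE,
                   outcome = as.numeric(four)),
    tibble::tibble(site_id = sc$site_id, patid = patid,
                   measure = "LAST_A1C", eligible = TRUE, outcome = v_last),
    tibble::tibble(site_id = sc$site_id, patid = patid,
                   measure = "A1C_IMPROVE", eligible = TRUE,
                   outcome = as.numeric(improve)),
    tibble::tibble(site_id = sc$site_id, patid = patid,
                   measure = "DKA_ADMIT", eligible = !newly,
                   outcome = ifelse(newly, NA_real_, as.numeric(dka)))
  )
  list(dataset = ds, gold = gold)
}

#' Generate a multi-site synthetic CDM network with planted truth
#'
#' For each scenario, synthesizes one site's four CDM tables containing
#' exactly `n_patients` phenotype-positive patients whose per-measure
#' outcomes realize the planted rates exactly (`round(rate * n)` positives),
#' plus decoy patients failing each phenotype rule in turn. The returned
#' gold standard records each cohort patient's true eligibility and
#' outcome -- the "chart" before any corruption. When a scenario's
#' corruption fractions are nonzero (and `apply_corruptions` is `TRUE`),
#' the corresponding error mechanisms are applied to the CDM tables only;
#' the gold standard always describes the uncorrupted truth. Output is
#' deterministic in `(seed, site_id)`: adding or reordering sites does not
#' change another site's data.
#'
#' @param scenarios Tibble of [site_scenario()] rows (unique `site_id`s).
#' @param seed Master integer seed.
#' @param anchor_date Anchor date of the measurement window.
#' @param lookback_days Window length (default 365).
#' @param decoy_frac Decoy patients as a fraction of `n_patients`
#'   (default 0.10, minimum 4 per site; 0 disables decoys).
#' @param apply_corruptions Apply each scenario's error mechanisms.
#' @return List with `datasets` (named list of `cdm_dataset`), `gold`
#'   (tibble `site_id, patid, measure, eligible, outcome`), and `window`.
#' @export
generate_network <- function(scenarios, seed = 1L,
                             anchor_date = "2018-12-31",
                             lookback_days = 365L, decoy_frac = 0.10,
                             apply_corruptions = TRUE) {
  scenarios <- tibble::as_tibble(scenarios)
  if (anyDuplicated(scenarios$site_id)) {
    stop("duplicate site_id in scenarios", call. = FALSE)
  }
  window <- analysis_window(anchor_date, lookback_days)
  datasets <- list()
  gold <- list()
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    g <- generate_site(sc, window, seed, decoy_frac)
    ds <- g$dataset
    if (apply_corruptions) {
      s <- site_seed(seed, sc$site_id)
      if (sc$external_lab_loss > 0) {
        ds <- apply_external_lab_loss(ds, sc$external_lab_loss, seed = s + 1L)
      }
      if (sc$dka_overcode > 0) {
        ds <- apply_dka_overcoding(ds, sc$dka_overcode, seed = s + 2L)
      }
      if (sc$visit_mislabel > 0) {
        ds <- apply_visit_mislabeling(ds, sc$visit_mislabel, seed = s + 3L)
      }
    }
    datasets[[sc$site_id]] <- ds
    gold[[i]] <- g$gold
  }
  list(datasets = datasets, gold = dplyr::bind_rows(gold), window = window)
}

#' Withhold A1c results from the CDM (external-lab loss)
#'
#' Emulates HbA1c results that exist in the chart (eg, outside-lab reports)
#' but never reach the CDM as discrete data: removes
#' `floor(fraction * n)` of the HbA1c lab rows, chosen uniformly at random.
#' The gold standard is untouched, so downstream validation sees false
#' negatives but never false positives on the poor-control measure.
#'
#' @param ds A `cdm_dataset`.
#' @param fraction Fraction of A1c rows to withhold, in `[0, 1]`.
#' @param seed Integer seed for the removal draw.
#' @param codesets Code sets identifying HbA1c rows.
#' @return The corrupted `cdm_dataset`.
#' @export
apply_external_lab_loss <- function(ds, fraction, seed = 1L,
                                    codesets = default_codesets()) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0) return(ds)
  set.seed(as.integer(seed))
  a1c_loincs <- codeset_entries(codesets, "hba1c_lab")$code
  idx <- which(ds$labs$lab_loinc %in% a1c_loincs)
  k <- floor(fraction * length(idx))
  if (k > 0) {
    drop <- idx[sample.int(length(idx), k)]
    ds$labs <- ds$labs[-drop, ]
  }
  ds
}

#' Attach DKA codes to non-DKA admissions (overcoding)
#'
#' Emulates admissions that were primarily for another reason (eg,
#' surgery) but acquired a DKA diagnosis code: adds a DKA diagnosis to
#' `floor(fraction * n)` of the inpatient admissions not already carrying
#' one. The gold standard is untouched, so validation sees false positives
#' but never false negatives on the DKA measure.
#'
#' @inheritParams apply_external_lab_loss
#' @param fraction Fraction of non-DKA inpatient admissions to overcode.
#' @return The corrupted `cdm_dataset`.
#' @export
apply_dka_overcoding <- function(ds, fraction, seed = 1L,
                                 codesets = default_codesets()) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0) return(ds)
  set.seed(as.integer(seed))
  dxc <- classify_dx_tbl(ds$diagnoses, codesets)
  dka_encs <- unique(dxc$encounterid[dxc$is_dka & !is.na(dxc$encounterid)])
  cand <- ds$encounters |>
    filter(.data$enc_type %in% c("IP", "EI"),
           !.data$encounterid %in% dka_encs)
  k <- floor(fraction * nrow(cand))
  if (k > 0) {
    hit <- cand[sample.int(nrow(cand), k), ]
    ds$diagnoses <- dplyr::bind_rows(ds$diagnoses, tibble::tibble(
      diagnosisid = sprintf("%s-OC%06d", ds$site_id, seq_len(k)),
      patid = hit$patid, encounterid = hit$encounterid,
      dx = "E10.10", dx_type = "ICD10CM", dx_date = hit$admit_date))
  }
  ds
}

#' Swap T1D visit labels (visit misclassification)
#'
#' Emulates variation in visit labelling between systems: strips the T1D
#' diagnoses from `floor(fraction * n)` of the true T1D ambulatory visits
#' (missed visits) and attaches a T1D diagnosis to an equal number of
#' non-T1D ambulatory encounters (falsely labelled visits). The gold
#' standard is untouched, so the four-visit measure acquires both false
#' positives and false negatives.
#'
#' @inheritParams apply_external_lab_loss
#' @param fraction Fraction of true T1D visits to mislabel.
#' @return The corrupted `cdm_dataset`.
#' @export
apply_visit_mislabeling <- function(ds, fraction, seed = 1L,
                                    codesets = default_codesets()) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0) return(ds)
  set.seed(as.integer(seed))
  dxc <- classify_dx_tbl(ds$diagnoses, codesets)
  t1d_encs <- unique(dxc$encounterid[dxc$is_t1d & !is.na(dxc$encounterid)])
  amb <- ds$encounters[ds$encounters$enc_type %in% c("AV", "TH"), ]
  true_vis <- amb$encounterid[amb$encounterid %in% t1d_encs]
  k <- floor(fraction * length(true_vis))
  if (k > 0) {
    strip <- true_vis[sample.int(length(true_vis), k)]
    keep <- !(ds$diagnoses$encounterid %in% strip &
                classify_dx_tbl(ds$diagnoses, codesets)$is_t1d)
    ds$diagnoses <- ds$diagnoses[keep, ]
    non_t1d <- amb$encounterid[!amb$encounterid %in% t1d_encs]
    k2 <- min(k, length(non_t1d))
    if (k2 > 0) {
      add <- non_t1d[sample.int(length(non_t1d), k2)]
      hit <- ds$encounters[match(add, ds$encounters$encounterid), ]
      ds$diagnoses <- dplyr::bind_rows(ds$diagnoses, tibble::tibble(
        diagnosisid = sprintf("%s-ML%06d", ds$site_id, seq_len(k2)),
        patid = hit$patid, encounterid = hit$encounterid,
        dx = "E10.9", dx_type = "ICD10CM", dx_date = hit$admit_date))
    }
  }
  ds
}

#' Write / read a gold-standard outcome table
#'
#' CSV with columns `site_id, patid, measure, eligible, outcome` -- the
#' same shape [validate_measures()] accepts as chart-review input.
#'
#' @param gold Gold-standard tibble from [generate_network()].
#' @param path Output CSV path.
#' @return `write_gold_standard()`: the path, invisibly;
#'   `read_gold_standard()`: the tibble.
#' @export
write_gold_standard <- function(gold, path) {
  readr::write_csv(gold, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_gold_standard
#' @export
read_gold_standard <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    site_id = "c", patid = "c", measure = "c", eligible = "l",
    outcome = "d"), progress = FALSE)
}
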