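test_that("the analysis window is closed and spans exactly 365 days", {
  w <- analysis_window("2018-12-31")
  expect_equal(w$start, as.Date("2018-01-01"))
  expect_equal(w$end, as.Date("2018-12-31"))
  expect_equal(as.integer(w$end - w$start) + 1L, 365L)
  expect_equal(w$prior_end, as.Date("2017-12-31"))
  expect_equal(w$prior_start, as.Date("2017-01-01"))
})

test_that("age uses birthday arithmetic with a hard <21 boundary", {
  anchor <- as.Date("2018-12-31")
  expect_equal(age_at(as.Date("1997-12-31"), anchor), 21L)  # birthday today
  expect_equal(age_at(as.Date("1998-01-01"), anchor), 20L)
  expect_equal(age_at(as.Date("2010-07-04"), anchor), 8L)
})

test_that("first T1D diagnosis date is the minimum over T1D codes only", {
  dx <- dplyr::bind_rows(
    dx_row("P1", "E10.9", "2018-02-01"),
    dx_row("P1", "E10.9", "2016-03-01"),
    dx_row("P1", "E11.9", "2015-01-01"))  # excluded code must not count
  expect_equal(first_t1d_date(dx, CS), as.Date("2016-03-01"))
  expect_true(is.na(first_t1d_date(dx[3, ], CS)))
  expect_equal(first_t1d_date(dx[1, ], CS), as.Date("2018-02-01"))
})

test_that("visit counting uses distinct ambulatory dates with a T1D code", {
  enc <- dplyr::bind_rows(
    enc_row("P1", "e1", "2018-02-01"),
    enc_row("P1", "e2", "2018-02-01"),        # same-day duplicate
    enc_row("P1", "e3", "2018-05-01", "TH"),
    enc_row("P1", "e4", "2018-06-01", "IP"),  # inpatient never counts
    enc_row("P1", "e5", "2018-07-01"))        # no T1D dx attached
  dx <- dplyr::bind_rows(
    dx_row("P1", "E10.9", "2018-02-01", "e1"),
    dx_row("P1", "E10.9", "2018-02-01", "e2"),
    dx_row("P1", "E10.9", "2018-05-01", "e3"),
    dx_row("P1", "E10.9", "2018-06-01", "e4"),
    dx_row("P1", "J45.909", "2018-07-01", "e5"))
  expect_equal(count_t1d_visits(enc, dx, W, CS), 2L)
})

test_that("phenotype accepts a qualifying patient and rejects variants", {
  ok <- patient_dataset(basic_patient("P1"))
  co <- eligible_cohort(ok, W, CS)
  expect_equal(co$patid, "P1")
  expect_equal(co$n_t1d_visits, 2L)
  expect_false(co$newly_diagnosed)

  # one added excluded-diabetes code disqualifies
  excl <- patient_dataset(basic_patient("P1"))
  excl$diagnoses <- dplyr::bind_rows(excl$diagnoses,
                                     dx_row("P1", "E11.9", "2014-01-01"))
  co2 <- eligible_cohort(excl, W, CS)
  expect_equal(nrow(co2), 0L)
  expect_equal(cohort_rejections(co2)$reasons, "excluded_diabetes_dx")

  # exactly 21 at anchor is out
  old <- patient_dataset(basic_patient("P1"))
  old$demographics$birth_date <- as.Date("1997-12-31")
  expect_equal(nrow(eligible_cohort(old, W, CS)), 0L)
})

test_that("incident patients enter the cohort and are flagged", {
  p <- basic_patient("P1")
  # first (and only) T1D dxs all inside the window
  p$diagnoses <- dplyr::bind_rows(
    dx_row("P1", "E10.9", "2018-03-01", "P1-e1"),
    dx_row("P1", "E10.9", "2018-09-15", "P1-e2"))
  co <- eligible_cohort(patient_dataset(p), W, CS)
  expect_equal(nrow(co), 1L)
  expect_true(co$newly_diagnosed)
  expect_equal(co$first_t1d_date, as.Date("2018-03-01"))
})

test_that("diagnoses confined to the current year reject non-incident patients", {
  p <- basic_patient("P1")
  # earliest dx before the prior block, none inside it
  p$diagnoses <- dplyr::bind_rows(
    dx_row("P1", "E10.9", "2016-06-01"),
    dx_row("P1", "E10.9", "2018-03-01", "P1-e1"),
    dx_row("P1", "E10.9", "2018-09-15", "P1-e2"))
  co <- eligible_cohort(patient_dataset(p), W, CS)
  expect_equal(nrow(co), 0L)
  expect_equal(cohort_rejections(co)$reasons, "single_year_t1d_dx")
})

test_that("cohort membership is invariant to input row order", {
  net <- generate_network(site_scenario("ORD", 60), seed = 5)
  ds <- net$datasets$ORD
  co1 <- eligible_cohort(ds, net$window, CS)
  set.seed(99)
  shuf <- ds
  shuf$demographics <- shuf$demographics[sample(nrow(shuf$demographics)), ]
  shuf$encounters <- shuf$encounters[sample(nrow(shuf$encounters)), ]
  shuf$diagnoses <- shuf$diagnoses[sample(nrow(shuf$diagnoses)), ]
  shuf$labs <- shuf$labs[sample(nrow(shuf$labs)), ]
  co2 <- eligible_cohort(shuf, net$window, CS)
  expect_equal(co2, co1, ignore_attr = TRUE)
})

test_that("adding a T1D visit never removes a member; an excluded code always does", {
  ds <- patient_dataset(basic_patient("P1"))
  base <- eligible_cohort(ds, W, CS)
  expect_equal(nrow(base), 1L)

  more <- ds
  more$encounters <- dplyr::bind_rows(more$encounters,
                                      enc_row("P1", "e9", "2018-11-01"))
  more$diagnoses <- dplyr::bind_rows(more$diagnoses,
                                     dx_row("P1", "E10.9", "2018-11-01", "e9"))
  co_more <- eligible_cohort(more, W, CS)
  expect_true("P1" %in% co_more$patid)
  expect_equal(co_more$n_t1d_visits, 3L)

  worse <- ds
  worse$diagnoses <- dplyr::bind_rows(worse$diagnoses,
                                      dx_row("P1", "O24.419", "2018-06-01"))
  expect_false("P1" %in% eligible_cohort(worse, W, CS)$patid)
})

test_that("generated cohorts equal the planted cohort; decoys are rejected for the right rule", {
  net <- generate_network(site_scenario("DC", 80), seed = 21)
  co <- eligible_cohort(net$datasets$DC, net$window, CS)
  planted <- sort(unique(net$gold$patid))
  expect_identical(sort(co$patid), planted)
  rej <- cohort_rejections(co)
  expect_true(all(grepl("-D", rej$patid)))
  expected <- c("age_ge_21", "excluded_diabetes_dx",
                "insufficient_t1d_visits", "single_year_t1d_dx")
  got <- rej$reasons[order(rej$patid)]
  expect_identical(got, rep_len(expected, length(got)))
})
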