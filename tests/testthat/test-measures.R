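test_that("A1c series is windowed, date-ordered, and averages same-date duplicates", {
  labs <- dplyr::bind_rows(
    lab_row("P1", 9.5, "2018-06-01"),
    lab_row("P1", 8.1, "2018-02-01"),
    lab_row("P1", 7.0, "2019-01-01"),            # after anchor: out
    lab_row("P1", 6.5, "2017-12-31"),            # before window: out
    lab_row("P1", 12.0, "2018-06-01", loinc = "2345-7"))  # not an A1c
  s <- a1c_series(labs, W, CS)
  expect_equal(s$value, c(8.1, 9.5))
  expect_equal(s$date, as.Date(c("2018-02-01", "2018-06-01")))

  dup <- dplyr::bind_rows(lab_row("P1", 9.0, "2018-03-01"),
                          lab_row("P2", 9.4, "2018-03-01"))
  dup$patid <- "P1"
  expect_equal(a1c_series(dup, W, CS)$value, 9.2)  # mean then 0.1 rounding
})

test_that("two-A1c-above-9 uses a strict threshold and counts whole series", {
  expect_true(flag_two_a1c_gt9(series_tbl(c(9.4, 9.1), c("2018-01-01", "2018-02-01"))))
  expect_false(flag_two_a1c_gt9(series_tbl(c(9.0, 9.0, 8.2),
                                           c("2018-01-01", "2018-02-01", "2018-03-01"))))
  expect_false(flag_two_a1c_gt9(series_tbl(numeric(), as.Date(character()))))
  # inclusive variant
  expect_true(flag_two_a1c_gt9(series_tbl(c(9.0, 9.0), c("2018-01-01", "2018-02-01")),
                               strict = FALSE))
})

test_that("visit and last-A1c flags follow their boundaries", {
  expect_true(flag_four_visits(4L))
  expect_false(flag_four_visits(3L))
  expect_equal(last_a1c(series_tbl(c(8.1, 9.5), c("2018-01-01", "2018-06-01"))), 9.5)
  expect_equal(last_a1c(series_tbl(7.2, "2018-01-01")), 7.2)
  expect_true(is.na(last_a1c(series_tbl(numeric(), as.Date(character())))))
})

test_that("improvement is inclusive at 0.5 and robust to the 0.1 grid", {
  # 9.6 - 9.1 is not exactly 0.5 in floating point; must still count
  expect_true(flag_a1c_improvement(series_tbl(c(7.0, 9.6, 9.1),
                                              c("2018-01-01", "2018-05-01", "2018-09-01"))))
  expect_false(flag_a1c_improvement(series_tbl(c(8.0, 8.0),
                                               c("2018-01-01", "2018-06-01"))))
  expect_false(flag_a1c_improvement(series_tbl(c(9.5, 9.1),
                                               c("2018-01-01", "2018-06-01"))))
  expect_true(is.na(flag_a1c_improvement(series_tbl(8.0, "2018-01-01"))))
})

test_that("DKA requires an in-window inpatient admission carrying the code", {
  enc <- dplyr::bind_rows(
    enc_row("P1", "ip1", "2018-05-01", "IP", "2018-05-03"),
    enc_row("P1", "ed1", "2018-06-01", "ED"),
    enc_row("P1", "av1", "2018-07-01", "AV"))
  dx_ip <- dx_row("P1", "E10.10", "2018-05-01", "ip1")
  dx_ed <- dx_row("P1", "E10.10", "2018-06-01", "ed1")
  dx_av <- dx_row("P1", "E10.10", "2018-07-01", "av1")

  expect_true(flag_dka_admission(enc, dx_ip, W, CS, newly_diagnosed = FALSE))
  expect_true(is.na(flag_dka_admission(enc, dx_ip, W, CS,
                                       newly_diagnosed = TRUE)))
  # ED-only visit or outpatient code never counts
  expect_false(flag_dka_admission(enc[-1, ], dx_ed, W, CS, FALSE))
  expect_false(flag_dka_admission(enc, dx_av, W, CS, FALSE))
  # admission outside the window does not count
  old_enc <- enc_row("P1", "ip2", "2017-05-01", "IP", "2017-05-04")
  old_dx <- dx_row("P1", "E10.10", "2017-05-01", "ip2")
  expect_false(flag_dka_admission(old_enc, old_dx, W, CS, FALSE))
  # EI counts as an admission
  ei <- enc_row("P1", "ei1", "2018-05-01", "EI", "2018-05-02")
  expect_true(flag_dka_admission(ei, dx_row("P1", "E10.10", "2018-05-01", "ei1"),
                                 W, CS, FALSE))
})

test_that("patients without in-window A1c stay in the two-A1c denominator but not LAST/IMPROVE", {
  p <- basic_patient("P1")
  p$labs <- p$labs[0, ]
  pm <- run_engine(patient_dataset(p))
  expect_equal(pm$eligible[pm$measure == "TWO_A1C_GT9"], TRUE)
  expect_equal(pm$outcome[pm$measure == "TWO_A1C_GT9"], 0)
  expect_false(pm$eligible[pm$measure == "LAST_A1C"])
  expect_false(pm$eligible[pm$measure == "A1C_IMPROVE"])
})

test_that("site summaries pool the overall row and use medians for last A1c", {
  pm <- dplyr::bind_rows(
    tibble::tibble(site_id = "X", patid = paste0("a", 1:4),
                   measure = "TWO_A1C_GT9", eligible = TRUE,
                   outcome = c(1, 0, 0, 0)),
    tibble::tibble(site_id = "X", patid = paste0("a", 1:3),
                   measure = "LAST_A1C", eligible = TRUE,
                   outcome = c(7.9, 8.5, 9.8)))
  ss <- summarize_sites(pm)
  expect_equal(ss$result[ss$site_id == "X" & ss$measure == "TWO_A1C_GT9"], 25)
  expect_equal(ss$result[ss$site_id == "X" & ss$measure == "LAST_A1C"], 8.5)

  pm2 <- tibble::tibble(
    site_id = rep(c("A", "B"), each = 100),
    patid = paste0("p", 1:200), measure = "FOUR_VISITS", eligible = TRUE,
    outcome = c(rep(1, 10), rep(0, 90), rep(1, 30), rep(0, 70)))
  ss2 <- summarize_sites(pm2)
  expect_equal(ss2$result[ss2$site_id == "Overall"], 20)  # pooled, not averaged
  # pooled overall lies within site min/max
  sites <- ss2$result[ss2$site_id != "Overall"]
  expect_gte(ss2$result[ss2$site_id == "Overall"], min(sites))
  expect_lte(ss2$result[ss2$site_id == "Overall"], max(sites))

  # even count: midpoint of the two central values
  pm3 <- tibble::tibble(site_id = "X", patid = paste0("q", 1:4),
                        measure = "LAST_A1C", eligible = TRUE,
                        outcome = c(7, 8, 9, 12))
  expect_equal(summarize_sites(pm3)$result[1], 8.5)

  # zero eligible -> n = 0, absent result
  pm4 <- tibble::tibble(site_id = "X", patid = "z1", measure = "LAST_A1C",
                        eligible = FALSE, outcome = NA_real_)
  ss4 <- summarize_sites(pm4)
  expect_equal(ss4$n_eligible, c(0L, 0L))
  expect_true(all(is.na(ss4$result)))
})

test_that("denominators nest and cross-measure consistency holds", {
  net <- generate_network(site_scenario("NST", 120), seed = 31)
  pm <- run_engine(net$datasets$NST, net$window)
  elig <- function(m) pm$patid[pm$measure == m & pm$eligible]
  expect_true(all(elig("A1C_IMPROVE") %in% elig("LAST_A1C")))
  expect_true(all(elig("LAST_A1C") %in% elig("TWO_A1C_GT9")))
  expect_true(all(elig("DKA_ADMIT") %in% elig("TWO_A1C_GT9")))

  # if every in-window A1c of a patient is > 9 (and there are >= 2),
  # then the poor-control flag is set and the last A1c exceeds 9
  hi <- patient_dataset(basic_patient("HI"))
  hi$labs$result_num <- c(9.8, 10.4)
  pm_hi <- run_engine(hi)
  expect_equal(pm_hi$outcome[pm_hi$measure == "TWO_A1C_GT9"], 1)
  expect_gt(pm_hi$outcome[pm_hi$measure == "LAST_A1C"], 9)
})

test_that("deleting A1c rows never increases the poor-control count", {
  net <- generate_network(site_scenario("DEL", 150, rate_two_a1c_gt9 = 0.4),
                          seed = 17)
  ds <- net$datasets$DEL
  count_two <- function(d) {
    pm <- run_engine(d, net$window)
    sum(pm$outcome[pm$measure == "TWO_A1C_GT9"])
  }
  full <- count_two(ds)
  for (frac in c(0.2, 0.5, 1)) {
    expect_lte(count_two(apply_external_lab_loss(ds, frac, seed = 3)), full)
  }
})
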