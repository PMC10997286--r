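test_that("contingency tables enumerate the four agreement cells", {
  all_pos <- build_contingency(rep(TRUE, 10), rep(TRUE, 10))
  expect_equal(unlist(all_pos[c("tp", "fp", "tn", "fn")]),
               c(tp = 10L, fp = 0L, tn = 0L, fn = 0L))
  one_fp <- build_contingency(TRUE, FALSE)
  expect_equal(unlist(one_fp[c("tp", "fp", "tn", "fn")]),
               c(tp = 0L, fp = 1L, tn = 0L, fn = 0L))
  mixed <- build_contingency(c(TRUE, TRUE, FALSE, FALSE),
                             c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(unlist(mixed[c("tp", "fp", "tn", "fn")]),
               c(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
})

test_that("predictive values are undefined (not zero) on empty denominators", {
  pv <- function(tp, fp, tn, fn) {
    predictive_values(build_contingency(
      c(rep(TRUE, tp + fp), rep(FALSE, tn + fn)),
      c(rep(TRUE, tp), rep(FALSE, fp), rep(FALSE, tn), rep(TRUE, fn))))
  }
  expect_equal(pv(10, 0, 5, 0), list(ppv = 1, npv = 1))
  r <- pv(3, 1, 0, 0)
  expect_equal(r$ppv, 0.75)
  expect_true(is.na(r$npv))
  empty <- predictive_values(build_contingency(logical(), logical()))
  expect_true(is.na(empty$ppv) && is.na(empty$npv))
})

test_that("contingency and predictive values match the brute-force oracle", {
  set.seed(2024)
  for (rep in seq_len(200)) {
    n <- sample(1:30, 1)
    cdm <- stats::runif(n) < stats::runif(1)
    chart <- ifelse(stats::runif(n) < 0.7, cdm, stats::runif(n) < 0.5)
    ct <- build_contingency(cdm, chart)
    pv <- predictive_values(ct)
    bf <- brute_force_pv(cdm, chart)
    expect_identical(unlist(ct[c("tp", "fp", "tn", "fn")]),
                     unlist(bf[c("tp", "fp", "tn", "fn")]))
    expect_equal(pv$ppv, bf$ppv)
    expect_equal(pv$npv, bf$npv)
  }
})

test_that("Clopper-Pearson matches the boundary closed forms to 1e-9", {
  for (n in c(5, 10, 40, 513)) {
    expect_equal(clopper_pearson_ci(0, n),
                 c(0, 1 - 0.025^(1 / n)), tolerance = 1e-9)
    expect_equal(clopper_pearson_ci(n, n),
                 c(0.025^(1 / n), 1), tolerance = 1e-9)
  }
})

test_that("Clopper-Pearson matches a binomial-tail-inversion oracle", {
  set.seed(7)
  cases <- data.frame(n = sample(2:200, 40, replace = TRUE))
  cases$k <- vapply(cases$n, function(n) sample(0:n, 1), integer(1))
  for (i in seq_len(nrow(cases))) {
    k <- cases$k[i]; n <- cases$n[i]
    got <- clopper_pearson_ci(k, n)
    expect_equal(got, cp_oracle(k, n), tolerance = 1e-7,
                 info = sprintf("k=%d n=%d", k, n))
    # interval always contains the point estimate
    expect_lte(got[1], k / n + 1e-12)
    expect_gte(got[2], k / n - 1e-12)
  }
  # width shrinks with n at fixed k/n
  widths <- vapply(c(10, 20, 40, 80, 160), function(n) {
    ci <- clopper_pearson_ci(n / 2, n); ci[2] - ci[1]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # symmetric about 0.5 at k = n/2
  ci <- clopper_pearson_ci(5, 10)
  expect_equal(ci[1], 1 - ci[2], tolerance = 1e-12)
})

test_that("percent agreement applies its tolerance and is symmetric", {
  expect_equal(percent_agreement_last_a1c(c(8.5, 9.0), c(8.5, 9.0)), 1)
  expect_equal(percent_agreement_last_a1c(8.5, 8.4), 0)
  expect_equal(percent_agreement_last_a1c(8.50, 8.54), 1)
  expect_true(is.na(percent_agreement_last_a1c(numeric(), numeric())))
  set.seed(3)
  a <- round(stats::runif(50, 6, 12), 1)
  b <- a + sample(c(0, 0.1, -0.3), 50, replace = TRUE)
  expect_equal(percent_agreement_last_a1c(a, b),
               percent_agreement_last_a1c(b, a))
})

test_that("validation emits N/A rows for unreviewed sites plus a pooled overall", {
  pm <- dplyr::bind_rows(
    tibble::tibble(site_id = "A", patid = paste0("a", 1:4),
                   measure = "DKA_ADMIT", eligible = TRUE,
                   outcome = c(1, 1, 0, 0)),
    tibble::tibble(site_id = "B", patid = paste0("b", 1:4),
                   measure = "DKA_ADMIT", eligible = TRUE,
                   outcome = c(1, 0, 0, 0)),
    tibble::tibble(site_id = "C", patid = paste0("c", 1:2),
                   measure = "DKA_ADMIT", eligible = TRUE,
                   outcome = c(0, 1)))
  chart <- dplyr::bind_rows(
    tibble::tibble(site_id = "A", patid = paste0("a", 1:4),
                   measure = "DKA_ADMIT", eligible = TRUE,
                   outcome = c(1, 0, 0, 0)),
    tibble::tibble(site_id = "B", patid = paste0("b", 1:4),
                   measure = "DKA_ADMIT", eligible = TRUE,
                   outcome = c(1, 0, 0, 1)))
  v <- validate_measures(pm, chart)
  expect_equal(nrow(v), 4L)  # A, B, C (N/A) + Overall
  expect_equal(v$n_reviewed[v$site_id == "C"], 0L)
  expect_true(is.na(v$ppv[v$site_id == "C"]))
  # pooled overall contingency = element-wise sum of per-site tables
  for (cell in c("tp", "fp", "tn", "fn")) {
    expect_equal(v[[cell]][v$site_id == "Overall"],
                 sum(v[[cell]][v$site_id %in% c("A", "B")]))
  }
  expect_equal(v$ppv[v$site_id == "A"], 0.5)
  expect_equal(v$npv[v$site_id == "B"], 2 / 3)
})

test_that("zero-noise synthetic data validates perfectly against its gold standard", {
  net <- generate_network(site_scenario("V0", 100), seed = 13)
  pm <- run_engine(net$datasets$V0, net$window)
  v <- validate_measures(pm, net$gold)
  binv <- v[v$measure != "LAST_A1C" & v$n_reviewed > 0, ]
  expect_true(all(binv$ppv[!is.na(binv$ppv)] == 1))
  expect_true(all(binv$npv[!is.na(binv$npv)] == 1))
  expect_true(all(v$agreement[v$measure == "LAST_A1C" & v$n_reviewed > 0] == 1))
})
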