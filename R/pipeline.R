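# sort direction per measure in benchmark tables: adverse outcomes ascend
# (best first), utilization/improvement descend
MEASURE_SORT <- c(TWO_A1C_GT9 = "asc", DKA_ADMIT = "asc", LAST_A1C = "asc",
                  FOUR_VISITS = "desc", A1C_IMPROVE = "desc")
MEASURE_LABELS <- c(
  TWO_A1C_GT9 = "2 or more measures of hemoglobin A1c > 9 in prior year",
  A1C_IMPROVE = "0.5% improvement in hemoglobin A1c",
  LAST_A1C = "Median last hemoglobin A1c",
  DKA_ADMIT = "DKA hospital admissions annually",
  FOUR_VISITS = "4 or more T1D visits annually")

#' Run the full benchmarking pipeline
#'
#' Orchestrates generate/read, phenotype, measures, summaries and (when
#' truth is available) validation, writing all artifacts to an output
#' directory. Two input modes: `scenario` (synthesize a network from
#' [site_scenario()] rows; the planted gold standard doubles as the chart
#' truth) and `cdm` (read site directories with [read_cdm_site()];
#' validation runs only if `chart` records are supplied). Re-running with
#' an identical config and seed reproduces identical outputs.
#'
#' @param config A list (or path to a JSON file) with fields:
#'   `mode` ("scenario" or "cdm"); `scenarios` (tibble or CSV path,
#'   scenario mode); `cdm_dirs` (named character vector site_id = path,
#'   cdm mode); `anchor_date`; `lookback_days` (default 365);
#'   `codesets_path` (default: shipped sets); `chart` (tibble or CSV path
#'   of chart outcomes, optional); `out_dir` (optional: write artifacts
#'   there); `seed` (default 1); `strict_gt9` (default TRUE);
#'   `improve_delta` (default 0.5); `decoy_frac` (default 0.1).
#' @return Invisibly, a list with `cohort`, `rejections`,
#'   `patient_measures`, `site_summary`, `validation` (or `NULL`),
#'   `window`, and `paths` of written files.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  mode <- config$mode %||% "scenario"
  if (!mode %in% c("scenario", "cdm")) {
    stop("config$mode must be 'scenario' or 'cdm'", call. = FALSE)
  }
  anchor <- config$anchor_date %||% "2018-12-31"
  lookback <- config$lookback_days %||% 365L
  seed <- as.integer(config$seed %||% 1L)
  codesets <- load_codesets(config$codesets_path %||% default_codesets_path())
  window <- analysis_window(anchor, lookback)
  chart <- NULL

  if (mode == "scenario") {
    scen <- config$scenarios
    if (is.null(scen)) stop("scenario mode needs config$scenarios",
                            call. = FALSE)
    if (is.character(scen)) {
      scen <- readr::read_csv(scen, col_types = readr::cols(site_id = "c",
                                                            .default = "d"),
                              progress = FALSE)
    }
    net <- generate_network(tibble::as_tibble(scen), seed = seed,
                            anchor_date = anchor, lookback_days = lookback,
                            decoy_frac = config$decoy_frac %||% 0.10)
    datasets <- net$datasets
    chart <- net$gold
  } else {
    dirs <- config$cdm_dirs
    if (is.null(dirs) || is.null(names(dirs)) || any(!nzchar(names(dirs)))) {
      stop("cdm mode needs config$cdm_dirs as a named site_id = path vector",
           call. = FALSE)
    }
    missing_dirs <- dirs[!dir.exists(unlist(dirs))]
    if (length(missing_dirs)) {
      stop("cdm directory not found: ", paste(missing_dirs, collapse = ", "),
           call. = FALSE)
    }
    datasets <- lapply(names(dirs), function(s) {
      read_cdm_site(dirs[[s]], s, codesets)
    })
    names(datasets) <- names(dirs)
  }
  if (!is.null(config$chart)) {
    chart <- config$chart
    if (is.character(chart)) chart <- read_gold_standard(chart)
  }

  cohorts <- list(); rejections <- list(); pms <- list()
  for (s in names(datasets)) {
    co <- eligible_cohort(datasets[[s]], window, codesets)
    cohorts[[s]] <- co
    rj <- cohort_rejections(co)
    if (nrow(rj)) rejections[[s]] <- mutate(rj, site_id = s, .before = 1)
    pms[[s]] <- compute_patient_measures(
      datasets[[s]], co, window, codesets,
      strict_gt9 = config$strict_gt9 %||% TRUE,
      improve_delta = config$improve_delta %||% 0.5)
  }
  cohort_tbl <- dplyr::bind_rows(cohorts)
  rejection_tbl <- if (length(rejections)) dplyr::bind_rows(rejections) else
    tibble::tibble(site_id = character(), patid = character(),
                   reasons = character())
  pm <- dplyr::bind_rows(pms)
  summary_tbl <- summarize_sites(pm)
  validation_tbl <- if (!is.null(chart)) validate_measures(pm, chart) else NULL

  paths <- character()
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(tbl, file) {
      p <- file.path(out_dir, file)
      readr::write_csv(tbl, p, na = "", progress = FALSE)
      p
    }
    paths <- c(paths,
               wr(cohort_tbl, "cohort.csv"),
               wr(rejection_tbl, "rejections.csv"),
               wr(pm, "patient_measures.csv"),
               wr(summary_tbl, "site_summary.csv"))
    if (!is.null(chart)) {
      paths <- c(paths, wr(tibble::as_tibble(chart), "gold_standard.csv"),
                 wr(validation_tbl, "validation.csv"))
    }
    quarantines <- dplyr::bind_rows(lapply(names(datasets), function(s) {
      q <- cdm_quarantine(datasets[[s]])
      if (nrow(q)) mutate(q, site_id = s, .before = 1) else NULL
    }))
    if (nrow(quarantines)) paths <- c(paths, wr(quarantines, "quarantine.csv"))
    tables <- render_benchmark_tables(summary_tbl, validation_tbl)
    md_path <- file.path(out_dir, "benchmark_report.md")
    writeLines(format_benchmark_markdown(tables), md_path)
    paths <- c(paths, md_path)
    for (m in names(tables)) {
      paths <- c(paths, wr(tables[[m]], sprintf("benchmark_%s.csv",
                                                tolower(m))))
    }
    log <- list(
      seed = seed, mode = mode, anchor_date = as.character(window$anchor),
      lookback_days = window$lookback_days,
      config_hash = rlang::hash(config),
      n_sites = length(datasets),
      n_cohort = nrow(cohort_tbl),
      n_patient_measures = nrow(pm))
    log_path <- file.path(out_dir, "run_log.json")
    jsonlite::write_json(log, log_path, auto_unbox = TRUE, pretty = TRUE)
    paths <- c(paths, log_path)
  }

  invisible(list(cohort = cohort_tbl, rejections = rejection_tbl,
                 patient_measures = pm, site_summary = summary_tbl,
                 validation = validation_tbl, window = window,
                 paths = paths))
}

# boundary values (exactly 0 or 100 %) print without an interval, the
# convention benchmark tables use for degenerate exact CIs
fmt_pct_ci <- function(value, low, high) {
  ifelse(is.na(value), "N/A",
         ifelse(is.na(low) | value %in% c(0, 1),
                sprintf("%.0f%%", 100 * value),
                sprintf("%.0f%% (%.0f%%-%.0f%%)", 100 * value, 100 * low,
                        100 * high)))
}

#' Render per-measure benchmark tables
#'
#' One table per measure, sites ordered by performance (ascending result
#' for the adverse-outcome measures -- two A1c above 9, DKA admissions,
#' median last A1c -- descending for visit and improvement rates), with
#' the pooled `Overall` row last. Results are shown to 0.1, predictive
#' values and their intervals to whole percents; sites without chart
#' review show `N/A`. A value of 100 % whose exact interval degenerates at
#' the boundary is printed without an interval.
#'
#' @param summaries Output of [summarize_sites()].
#' @param validations Output of [validate_measures()], or `NULL`.
#' @return Named list (by measure id) of formatted tibbles with columns
#'   `site`, `n_eligible`, `result`, `n_reviewed`, `ppv`, `npv` (or
#'   `agreement` for the median-A1c table).
#' @export
render_benchmark_tables <- function(summaries, validations = NULL) {
  out <- list()
  for (m in intersect(names(MEASURE_SORT), unique(summaries$measure))) {
    s <- summaries[summaries$measure == m, ]
    sites <- s[s$site_id != "Overall", ]
    ord <- order(sites$result, na.last = TRUE)
    if (MEASURE_SORT[[m]] == "desc") ord <- order(-sites$result,
                                                  na.last = TRUE)
    s <- dplyr::bind_rows(sites[ord, ], s[s$site_id == "Overall", ])
    tbl <- tibble::tibble(
      site = s$site_id,
      n_eligible = s$n_eligible,
      result = round(s$result, 1))
    if (!is.null(validations)) {
      v <- validations[validations$measure == m, ]
      v <- v[match(s$site_id, v$site_id), ]
      tbl$n_reviewed <- ifelse(is.na(v$n_reviewed) | v$n_reviewed == 0L,
                               "N/A", as.character(v$n_reviewed))
      if (m == "LAST_A1C") {
        tbl$agreement <- fmt_pct_ci(v$agreement, v$agreement_low,
                                    v$agreement_high)
      } else {
        tbl$ppv <- fmt_pct_ci(v$ppv, v$ppv_low, v$ppv_high)
        tbl$npv <- fmt_pct_ci(v$npv, v$npv_low, v$npv_high)
      }
    }
    out[[m]] <- tbl
  }
  out
}

#' Format benchmark tables as a Markdown report
#' @param tables Output of [render_benchmark_tables()].
#' @return Character vector of Markdown lines.
#' @export
format_benchmark_markdown <- function(tables) {
  lines <- character()
  for (m in names(tables)) {
    tbl <- tables[[m]]
    lines <- c(lines, paste0("## ", MEASURE_LABELS[[m]]), "")
    header <- paste0("| ", paste(names(tbl), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(tbl)), collapse = "|"), "|")
    body <- apply(tbl, 1, function(r) {
      paste0("| ", paste(ifelse(is.na(r), "N/A", r), collapse = " | "), " |")
    })
    lines <- c(lines, header, sep, body, "")
  }
  lines
}

`%||%` <- function(x, y) if (is.null(x)) y else x
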