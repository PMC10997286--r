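ENC_TYPES <- c("AV", "TH", "IP", "EI", "ED", "OA")
A1C_BOUNDS <- c(3.0, 20.0)  # plausibility bounds for HbA1c (%) rows

CDM_FILES <- c(
  demographics = "demographic.csv",
  encounters   = "encounter.csv",
  diagnoses    = "diagnosis.csv",
  labs         = "lab_result_cm.csv"
)

empty_demographics <- function() tibble::tibble(
  patid = character(), birth_date = as.Date(character()),
  sex = character(), race = character(), hispanic = character())
empty_encounters <- function() tibble::tibble(
  encounterid = character(), patid = character(),
  admit_date = as.Date(character()), discharge_date = as.Date(character()),
  enc_type = character())
empty_diagnoses <- function() tibble::tibble(
  diagnosisid = character(), patid = character(), encounterid = character(),
  dx = character(), dx_type = character(), dx_date = as.Date(character()))
empty_labs <- function() tibble::tibble(
  lab_result_cm_id = character(), patid = character(),
  lab_loinc = character(), result_num = double(),
  result_date = as.Date(character()))

#' Construct a four-table CDM dataset for one site
#'
#' Bundles the demographic, encounter, diagnosis and lab-result tables of a
#' single site. Column sets are checked; missing optional tables default to
#' empty. This is the unit of ingestion for the cohort and measure engines.
#'
#' @param site_id Site identifier (single string).
#' @param demographics,encounters,diagnoses,labs Tibbles with columns as in
#'   the package's CDM subset (lowercase: `patid`, `birth_date`, `sex`,
#'   `race`, `hispanic`; `encounterid`, `admit_date`, `discharge_date`,
#'   `enc_type`; `diagnosisid`, `encounterid`, `dx`, `dx_type`, `dx_date`;
#'   `lab_result_cm_id`, `lab_loinc`, `result_num`, `result_date`).
#' @param quarantine Optional tibble `(table, row, reason)` of rows rejected
#'   at load time.
#' @return An object of class `cdm_dataset`.
#' @export
cdm_dataset <- function(site_id,
                        demographics = empty_demographics(),
                        encounters = empty_encounters(),
                        diagnoses = empty_diagnoses(),
                        labs = empty_labs(),
                        quarantine = NULL) {
  stopifnot(is.character(site_id), length(site_id) == 1L)
  check_cols <- function(tbl, ref, name) {
    missing <- setdiff(names(ref), names(tbl))
    if (length(missing)) {
      stop(name, " table is missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    tibble::as_tibble(tbl)[names(ref)]
  }
  ds <- structure(list(
    site_id = site_id,
    demographics = check_cols(demographics, empty_demographics(), "demographic"),
    encounters = check_cols(encounters, empty_encounters(), "encounter"),
    diagnoses = check_cols(diagnoses, empty_diagnoses(), "diagnosis"),
    labs = check_cols(labs, empty_labs(), "lab_result_cm")
  ), class = "cdm_dataset")
  attr(ds, "quarantine") <- if (is.null(quarantine)) {
    tibble::tibble(table = character(), row = integer(), reason = character())
  } else tibble::as_tibble(quarantine)
  ds
}

#' @export
print.cdm_dataset <- function(x, ...) {
  q <- attr(x, "quarantine")
  cat("<cdm_dataset> site", x$site_id, "\n")
  cat(sprintf("  demographics: %d  encounters: %d  diagnoses: %d  labs: %d\n",
              nrow(x$demographics), nrow(x$encounters), nrow(x$diagnoses),
              nrow(x$labs)))
  if (!is.null(q) && nrow(q)) cat("  quarantined rows:", nrow(q), "\n")
  invisible(x)
}

#' Quarantined rows of a loaded CDM dataset
#' @param ds A `cdm_dataset`.
#' @return Tibble `(table, row, reason)`.
#' @export
cdm_quarantine <- function(ds) attr(ds, "quarantine")

parse_iso_date <- function(x) {
  x <- trimws(as.character(x))
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

#' Read one site's CDM tables from a directory
#'
#' Expects `demographic.csv`, `encounter.csv`, `diagnosis.csv` and
#' `lab_result_cm.csv` with PCORnet-inspired uppercase column names (PATID,
#' BIRTH_DATE, ...; see [write_cdm_site()]). Dates must be ISO 8601. Rows
#' that fail parsing, referential integrity (patient ids absent from the
#' demographic table) or HbA1c plausibility bounds (result outside
#' 3--20 %) are quarantined, not silently dropped: they are excluded from the
#' returned tables and reported in [cdm_quarantine()].
#'
#' @param directory Directory holding the four files.
#' @param site_id Site identifier to stamp on the dataset.
#' @param codesets Code sets used to recognize HbA1c lab rows (defaults to
#'   the shipped sets).
#' @return A `cdm_dataset`; quarantined rows in `attr(, "quarantine")`.
#' @export
read_cdm_site <- function(directory, site_id,
                          codesets = default_codesets()) {
  for (f in CDM_FILES) {
    if (!file.exists(file.path(directory, f))) {
      stop("missing CDM table file: ", f, " in ", directory, call. = FALSE)
    }
  }
  rd <- function(f) readr::read_csv(file.path(directory, f),
                                    col_types = readr::cols(.default = "c"),
                                    progress = FALSE)
  demo_raw <- rd(CDM_FILES[["demographics"]])
  enc_raw <- rd(CDM_FILES[["encounters"]])
  dx_raw <- rd(CDM_FILES[["diagnoses"]])
  lab_raw <- rd(CDM_FILES[["labs"]])
  quarantine <- list()
  note <- function(tbl, rows, reason) {
    if (length(rows)) {
      quarantine[[length(quarantine) + 1L]] <<-
        tibble::tibble(table = tbl, row = as.integer(rows), reason = reason)
    }
  }

  # demographic
  demo <- tibble::tibble(
    patid = demo_raw$PATID,
    birth_date = parse_iso_date(demo_raw$BIRTH_DATE),
    sex = demo_raw$SEX, race = demo_raw$RACE, hispanic = demo_raw$HISPANIC)
  bad <- which(is.na(demo$birth_date))
  note("demographic", bad, "unparseable BIRTH_DATE")
  if (length(bad)) demo <- demo[-bad, ]
  known <- demo$patid

  # encounter
  enc <- tibble::tibble(
    encounterid = enc_raw$ENCOUNTERID, patid = enc_raw$PATID,
    admit_date = parse_iso_date(enc_raw$ADMIT_DATE),
    discharge_date = parse_iso_date(enc_raw$DISCHARGE_DATE),
    enc_type = enc_raw$ENC_TYPE)
  bad_date <- is.na(enc$admit_date)
  bad_type <- !enc$enc_type %in% ENC_TYPES
  bad_pat <- !enc$patid %in% known
  note("encounter", which(bad_date), "unparseable ADMIT_DATE")
  note("encounter", which(!bad_date & bad_type), "unknown ENC_TYPE")
  note("encounter", which(!bad_date & !bad_type & bad_pat),
       "PATID not in demographic table")
  enc <- enc[!(bad_date | bad_type | bad_pat), ]

  # diagnosis
  dx <- tibble::tibble(
    diagnosisid = dx_raw$DIAGNOSISID, patid = dx_raw$PATID,
    encounterid = dx_raw$ENCOUNTERID,
    dx = dx_raw$DX,
    dx_type = normalize_dx_type(dx_raw$DX_TYPE),
    dx_date = parse_iso_date(dx_raw$DX_DATE))
  bad_date <- is.na(dx$dx_date)
  bad_type <- is.na(dx$dx_type)
  bad_pat <- !dx$patid %in% known
  note("diagnosis", which(bad_date), "unparseable DX_DATE")
  note("diagnosis", which(!bad_date & bad_type), "unknown DX_TYPE")
  note("diagnosis", which(!bad_date & !bad_type & bad_pat),
       "PATID not in demographic table")
  dx <- dx[!(bad_date | bad_type | bad_pat), ]

  # lab_result_cm
  lab <- tibble::tibble(
    lab_result_cm_id = lab_raw$LAB_RESULT_CM_ID, patid = lab_raw$PATID,
    lab_loinc = trimws(lab_raw$LAB_LOINC),
    result_num = suppressWarnings(as.numeric(lab_raw$RESULT_NUM)),
    result_date = parse_iso_date(lab_raw$RESULT_DATE))
  a1c_loincs <- codeset_entries(codesets, "hba1c_lab")$code
  is_a1c <- lab$lab_loinc %in% a1c_loincs
  bad_date <- is.na(lab$result_date)
  bad_num <- is.na(lab$result_num)
  bad_bounds <- is_a1c & !bad_num &
    (lab$result_num < A1C_BOUNDS[1] | lab$result_num > A1C_BOUNDS[2])
  bad_pat <- !lab$patid %in% known
  note("lab_result_cm", which(bad_date), "unparseable RESULT_DATE")
  note("lab_result_cm", which(!bad_date & bad_num), "missing RESULT_NUM")
  note("lab_result_cm", which(!bad_date & !bad_num & bad_bounds),
       "RESULT_NUM outside HbA1c plausibility bounds [3, 20]")
  note("lab_result_cm", which(!bad_date & !bad_num & !bad_bounds & bad_pat),
       "PATID not in demographic table")
  lab <- lab[!(bad_date | bad_num | bad_bounds | bad_pat), ]

  q <- if (length(quarantine)) dplyr::bind_rows(quarantine) else NULL
  if (!is.null(q) && nrow(q)) {
    warning(sprintf("site %s: %d row(s) quarantined on load", site_id,
                    nrow(q)), call. = FALSE)
  }
  cdm_dataset(site_id, demo, enc, dx, lab, quarantine = q)
}

#' Write one site's CDM tables to a directory
#'
#' Inverse of [read_cdm_site()]: emits the four CSV files with uppercase
#' PCORnet-inspired headers and ISO-8601 dates. Reading the written
#' directory back yields the same dataset up to row order.
#'
#' @param ds A `cdm_dataset`.
#' @param directory Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cdm_site <- function(ds, directory) {
  stopifnot(inherits(ds, "cdm_dataset"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    stop("cannot create output directory: ", directory, call. = FALSE)
  }
  w <- function(tbl, file) {
    readr::write_csv(tbl, file.path(directory, file), na = "", progress = FALSE)
    file.path(directory, file)
  }
  paths <- c(
    w(dplyr::rename(ds$demographics, PATID = "patid", BIRTH_DATE = "birth_date",
                    SEX = "sex", RACE = "race", HISPANIC = "hispanic"),
      CDM_FILES[["demographics"]]),
    w(dplyr::rename(ds$encounters, ENCOUNTERID = "encounterid", PATID = "patid",
                    ADMIT_DATE = "admit_date", DISCHARGE_DATE = "discharge_date",
                    ENC_TYPE = "enc_type"),
      CDM_FILES[["encounters"]]),
    w(dplyr::rename(ds$diagnoses, DIAGNOSISID = "diagnosisid", PATID = "patid",
                    ENCOUNTERID = "encounterid", DX = "dx", DX_TYPE = "dx_type",
                    DX_DATE = "dx_date"),
      CDM_FILES[["diagnoses"]]),
    w(dplyr::rename(ds$labs, LAB_RESULT_CM_ID = "lab_result_cm_id",
                    PATID = "patid", LAB_LOINC = "lab_loinc",
                    RESULT_NUM = "result_num", RESULT_DATE = "result_date"),
      CDM_FILES[["labs"]])
  )
  q <- cdm_quarantine(ds)
  if (!is.null(q) && nrow(q)) {
    paths <- c(paths, w(q, "quarantine.csv"))
  }
  invisible(paths)
}

#' Validate a loaded CDM dataset
#'
#' Pure check producing row counts, per-table date ranges, and integrity
#' failures (discharge before admit, duplicate patient ids, dangling
#' references). Does not modify the dataset.
#'
#' @param ds A `cdm_dataset`.
#' @return A list of class `cdm_validation` with elements `site_id`,
#'   `counts` (tibble table/n), `date_ranges`, `failures`
#'   (tibble rule/n), `n_quarantined`.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "cdm_dataset"))
  counts <- tibble::tibble(
    table = names(CDM_FILES),
    n = c(nrow(ds$demographics), nrow(ds$encounters), nrow(ds$diagnoses),
          nrow(ds$labs)))
  rng <- function(x) if (length(x) && any(!is.na(x))) {
    range(x, na.rm = TRUE)
  } else as.Date(c(NA, NA))
  date_ranges <- tibble::tibble(
    table = c("demographic", "encounter", "diagnosis", "lab_result_cm"),
    min_date = c(rng(ds$demographics$birth_date)[1],
                 rng(ds$encounters$admit_date)[1],
                 rng(ds$diagnoses$dx_date)[1],
                 rng(ds$labs$result_date)[1]),
    max_date = c(rng(ds$demographics$birth_date)[2],
                 rng(ds$encounters$admit_date)[2],
                 rng(ds$diagnoses$dx_date)[2],
                 rng(ds$labs$result_date)[2]))
  known <- ds$demographics$patid
  failures <- tibble::tibble(
    rule = c("discharge_before_admit", "duplicate_patid",
             "encounter_unknown_patid", "diagnosis_unknown_patid",
             "lab_unknown_patid"),
    n = c(
      sum(!is.na(ds$encounters$discharge_date) &
            ds$encounters$discharge_date < ds$encounters$admit_date),
      sum(duplicated(known)),
      sum(!ds$encounters$patid %in% known),
      sum(!ds$diagnoses$patid %in% known),
      sum(!ds$labs$patid %in% known)))
  structure(list(site_id = ds$site_id, counts = counts,
                 date_ranges = date_ranges, failures = failures,
                 n_quarantined = nrow(cdm_quarantine(ds))),
            class = "cdm_validation")
}

#' @export
print.cdm_validation <- function(x, ...) {
  cat("<cdm_validation> site", x$site_id, "\n")
  print(x$counts)
  bad <- x$failures[x$failures$n > 0, ]
  if (nrow(bad)) {
    cat("integrity failures:\n"); print(bad)
  } else cat("no integrity failures\n")
  invisible(x)
}
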