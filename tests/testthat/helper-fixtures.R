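# Shared fixtures: hand-built CDM tables small enough to reason about.

CS <- default_codesets()
W <- analysis_window("2018-12-31")

demo_row <- function(patid, birth = as.Date("2004-06-15"), sex = "F",
                     race = "White", hispanic = "N") {
  tibble::tibble(patid = patid, birth_date = as.Date(birth), sex = sex,
                 race = race, hispanic = hispanic)
}

enc_row <- function(patid, encounterid, admit, enc_type = "AV",
                    discharge = NA) {
  tibble::tibble(encounterid = encounterid, patid = patid,
                 admit_date = as.Date(admit),
                 discharge_date = as.Date(discharge), enc_type = enc_type)
}

dx_row <- function(patid, dx, date, encounterid = NA_character_,
                   dx_type = "ICD10CM") {
  tibble::tibble(diagnosisid = paste0("dx-", patid, "-", dx, "-", date),
                 patid = patid, encounterid = encounterid, dx = dx,
                 dx_type = dx_type, dx_date = as.Date(date))
}

lab_row <- function(patid, value, date, loinc = "4548-4") {
  tibble::tibble(lab_result_cm_id = paste0("lab-", patid, "-", date),
                 patid = patid, lab_loinc = loinc,
                 result_num = value, result_date = as.Date(date))
}

# A fully eligible established patient: dx in both year-blocks, >= 2
# in-window T1D visits.
basic_patient <- function(patid = "P1") {
  list(
    demographics = demo_row(patid),
    encounters = dplyr::bind_rows(
      enc_row(patid, paste0(patid, "-e1"), "2018-03-01"),
      enc_row(patid, paste0(patid, "-e2"), "2018-09-15")),
    diagnoses = dplyr::bind_rows(
      dx_row(patid, "E10.9", "2017-05-01"),
      dx_row(patid, "E10.9", "2018-03-01", paste0(patid, "-e1")),
      dx_row(patid, "E10.9", "2018-09-15", paste0(patid, "-e2"))),
    labs = dplyr::bind_rows(
      lab_row(patid, 8.1, "2018-04-01"),
      lab_row(patid, 7.9, "2018-10-01")))
}

patient_dataset <- function(..., site_id = "T") {
  pats <- list(...)
  cdm_dataset(
    site_id,
    demographics = dplyr::bind_rows(lapply(pats, `[[`, "demographics")),
    encounters = dplyr::bind_rows(lapply(pats, `[[`, "encounters")),
    diagnoses = dplyr::bind_rows(lapply(pats, `[[`, "diagnoses")),
    labs = dplyr::bind_rows(lapply(pats, `[[`, "labs")))
}

# run cohort + measures in one go
run_engine <- function(ds, window = W, codesets = CS, ...) {
  co <- eligible_cohort(ds, window, codesets)
  compute_patient_measures(ds, co, window, codesets, ...)
}

series_tbl <- function(values, dates) {
  tibble::tibble(date = as.Date(dates), value = values)
}
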