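#' @importFrom rlang .data
#' @import dplyr
NULL

CODE_SYSTEMS <- c("ICD9CM", "ICD10CM", "SNOMED", "LOINC")
REQUIRED_CODESETS <- c("t1d_dx", "excluded_dx", "dka_dx", "hba1c_lab")

# DX_TYPE dialects seen in CDM extracts -> canonical system ids
DX_TYPE_MAP <- c(
  "09" = "ICD9CM", "10" = "ICD10CM", "SM" = "SNOMED", "LC" = "LOINC",
  "ICD9CM" = "ICD9CM", "ICD10CM" = "ICD10CM", "ICD-9-CM" = "ICD9CM",
  "ICD-10-CM" = "ICD10CM", "SNOMED" = "SNOMED", "SNOMEDCT" = "SNOMED",
  "LOINC" = "LOINC"
)

#' Normalize a clinical terminology code
#'
#' ICD-9-CM and ICD-10-CM codes are uppercased and the decimal point is
#' removed (`E10.10` becomes `E1010`, `250.13` becomes `25013`), because CDM
#' extracts differ in whether they retain the dot. SNOMED and LOINC codes are
#' returned verbatim after trimming surrounding whitespace. The function is
#' idempotent and vectorized over `raw_code`.
#'
#' @param code_system One of `"ICD9CM"`, `"ICD10CM"`, `"SNOMED"`, `"LOINC"`
#'   (recycled against `raw_code`).
#' @param raw_code Character vector of codes as they appear in the source.
#' @return Character vector of normalized codes.
#' @export
#' @examples
#' normalize_code("ICD10CM", "e10.9")
#' normalize_code("ICD9CM", "250.13")
#' normalize_code("LOINC", " 4548-4 ")
normalize_code <- function(code_system, raw_code) {
  raw_code <- trimws(as.character(raw_code))
  if (any(!nzchar(raw_code))) {
    stop("normalize_code(): empty code", call. = FALSE)
  }
  code_system <- rep_len(as.character(code_system), length(raw_code))
  bad <- !code_system %in% CODE_SYSTEMS
  if (any(bad)) {
    stop("normalize_code(): unknown code_system '", code_system[bad][1], "'",
         call. = FALSE)
  }
  icd <- code_system %in% c("ICD9CM", "ICD10CM")
  out <- raw_code
  out[icd] <- gsub(".", "", toupper(raw_code[icd]), fixed = TRUE)
  out
}

#' Load terminology code sets from a delimited file
#'
#' Reads a code-set file with columns `codeset,code_system,code` (an optional
#' `description` column is carried along), normalizes every code with
#' [normalize_code()], collapses duplicates, and checks that all required
#' code sets are present and internally consistent (no code may sit in both
#' the T1D and the excluded-diabetes set).
#'
#' @param path Path to the code-set CSV. Defaults to the code sets shipped
#'   with the package (implementer defaults, intended to be edited per site).
#' @param schema Character vector of code-set names that must be present.
#' @return An object of class `t1d_codesets`: a tibble with columns
#'   `codeset`, `code_system`, `code` (normalized), `description`.
#' @export
#' @examples
#' cs <- load_codesets()
#' dplyr::count(cs, codeset)
load_codesets <- function(path = default_codesets_path(),
                          schema = REQUIRED_CODESETS) {
  if (!file.exists(path)) {
    stop("code-set file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("codeset", "code_system", "code")
  if (!all(need %in% names(raw))) {
    stop("code-set file must have columns codeset, code_system, code",
         call. = FALSE)
  }
  bad_sys <- which(!raw$code_system %in% CODE_SYSTEMS)
  if (length(bad_sys)) {
    stop("unknown code_system '", raw$code_system[bad_sys[1]],
         "' in code-set file row ", bad_sys[1], call. = FALSE)
  }
  if (!"description" %in% names(raw)) raw$description <- NA_character_
  cs <- raw |>
    mutate(code = normalize_code(.data$code_system, .data$code)) |>
    distinct(.data$codeset, .data$code_system, .data$code,
             .keep_all = TRUE) |>
    select("codeset", "code_system", "code", "description")

  missing <- setdiff(schema, unique(cs$codeset))
  if (length(missing)) {
    stop("code-set file is missing required set(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  overlap <- inner_join(
    filter(cs, .data$codeset == "t1d_dx"),
    filter(cs, .data$codeset == "excluded_dx"),
    by = c("code_system", "code")
  )
  if (nrow(overlap)) {
    stop("code(s) present in both t1d_dx and excluded_dx: ",
         paste(overlap$code, collapse = ", "), call. = FALSE)
  }
  structure(cs, class = c("t1d_codesets", class(cs)))
}

#' Path to the package's default code-set file
#' @return File path of the shipped `default_codesets.csv`.
#' @export
default_codesets_path <- function() {
  system.file("extdata", "default_codesets.csv", package = "t1dqm",
              mustWork = TRUE)
}

#' Default code sets
#'
#' Convenience wrapper: [load_codesets()] on the shipped defaults.
#' @return A `t1d_codesets` tibble.
#' @export
default_codesets <- function() load_codesets(default_codesets_path())

codeset_entries <- function(codesets, name) {
  filter(codesets, .data$codeset == name)
}

#' Classify a diagnosis code against the loaded code sets
#'
#' Returns the set of labels whose code set contains the normalized code.
#' A code can be both `T1D` and `DKA` (T1D-with-ketoacidosis codes);
#' `OTHER` is returned only when no set matches. Matching is exact on
#' normalized strings; wildcards must be pre-expanded in the code-set file.
#'
#' @param code_system Terminology id (see [normalize_code()]).
#' @param raw_code A single raw code.
#' @param codesets A `t1d_codesets` object from [load_codesets()].
#' @return Character vector: subset of `c("T1D", "EXCLUDED", "DKA")`, or
#'   `"OTHER"`.
#' @export
#' @examples
#' cs <- load_codesets()
#' classify_diagnosis("ICD10CM", "E10.10", cs)  # T1D and DKA
#' classify_diagnosis("ICD10CM", "E11.9", cs)   # EXCLUDED
classify_diagnosis <- function(code_system, raw_code, codesets) {
  code <- normalize_code(code_system, raw_code)
  hit <- codesets$code_system == code_system & codesets$code == code
  sets <- unique(codesets$codeset[hit])
  labels <- c(t1d_dx = "T1D", excluded_dx = "EXCLUDED", dka_dx = "DKA")
  out <- unname(labels[intersect(names(labels), sets)])
  if (!length(out)) "OTHER" else out
}

# Vectorized classification of a diagnosis table: adds logical columns
# is_t1d, is_excluded, is_dka keyed on (dx_type, normalized dx).
classify_dx_tbl <- function(dx, codesets) {
  if (!nrow(dx)) {
    dx$is_t1d <- logical(0); dx$is_excluded <- logical(0)
    dx$is_dka <- logical(0)
    return(dx)
  }
  norm <- normalize_code(dx$dx_type, dx$dx)
  key <- paste(dx$dx_type, norm, sep = "|")
  set_key <- function(name) {
    e <- codeset_entries(codesets, name)
    key %in% paste(e$code_system, e$code, sep = "|")
  }
  dx$is_t1d <- set_key("t1d_dx")
  dx$is_excluded <- set_key("excluded_dx")
  dx$is_dka <- set_key("dka_dx")
  dx
}

# Normalize a DX_TYPE dialect value ("09", "10", "SM", long names) to the
# canonical system id; unknown dialects return NA.
normalize_dx_type <- function(dx_type) {
  out <- unname(DX_TYPE_MAP[toupper(trimws(as.character(dx_type)))])
  out
}
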