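#' Assemble a cohort dataset from in-memory tables
#'
#' A cohort dataset bundles one demographics table and four longitudinal
#' event tables (diagnoses, labs, medications, procedures), all keyed by
#' `patient_id`. Tables are canonically sorted on construction so loading is
#' order-insensitive: shuffled input rows yield an identical dataset.
#'
#' @param patients Tibble with columns `patient_id`, `age_years`, `sex`
#'   (`"female"`/`"male"`; other values are preserved but excluded from model
#'   fitting), `stratum`.
#' @param diagnoses Tibble with `patient_id`, `code_system` (ICD9/ICD10),
#'   `code`, `date`.
#' @param labs Tibble with `patient_id`, `analyte`, `value`, `units`, `date`.
#' @param medications Tibble with `patient_id`, `drug_class`, `date` and an
#'   optional `route`.
#' @param procedures Tibble with `patient_id`, `code`, `date`,
#'   `is_amputation` (0/1).
#' @param provenance Named list of free-text metadata (source, seed, ...).
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(patients, diagnoses, labs, medications, procedures,
                           provenance = list()) {
  patients <- tibble::as_tibble(patients)
  if (anyDuplicated(patients$patient_id))
    stop("duplicate patient_id in patients table: ",
         paste(unique(patients$patient_id[duplicated(patients$patient_id)]),
               collapse = ", "), call. = FALSE)

  drop_orphans <- function(tbl, what) {
    tbl <- tibble::as_tibble(tbl)
    if ("date" %in% names(tbl) && !inherits(tbl$date, "Date"))
      tbl$date <- parse_iso_date(tbl$date, sprintf("%s table", what))
    orphan <- !tbl$patient_id %in% patients$patient_id
    if (any(orphan))
      log_info("dropping %d orphan %s row(s) with unknown patient_id",
               sum(orphan), what)
    tbl[!orphan, , drop = FALSE]
  }

  diagnoses <- drop_orphans(diagnoses, "diagnosis") |>
    dplyr::mutate(code = normalize_code(.data$code)) |>
    dplyr::arrange(dplyr::pick(dplyr::everything()))
  labs <- drop_orphans(labs, "lab") |>
    dplyr::mutate(value = as.numeric(.data$value)) |>
    dplyr::arrange(dplyr::pick(dplyr::everything()))
  medications <- drop_orphans(medications, "medication") |>
    dplyr::arrange(dplyr::pick(dplyr::everything()))
  procedures <- drop_orphans(procedures, "procedure") |>
    dplyr::mutate(code = normalize_code(.data$code),
                  is_amputation = as.integer(.data$is_amputation)) |>
    dplyr::arrange(dplyr::pick(dplyr::everything()))

  structure(
    list(patients = dplyr::arrange(patients, .data$patient_id),
         diagnoses = diagnoses, labs = labs, medications = medications,
         procedures = procedures, provenance = provenance),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf(paste0("<cohort_dataset> %d patients | %d diagnoses | %d labs",
                     " | %d medications | %d procedures\n"),
              nrow(x$patients), nrow(x$diagnoses), nrow(x$labs),
              nrow(x$medications), nrow(x$procedures)))
  invisible(x)
}

cohort_required_cols <- list(
  patients = c("patient_id", "age_years", "sex", "stratum"),
  diagnoses = c("patient_id", "code_system", "code", "date"),
  labs = c("patient_id", "analyte", "value", "units", "date"),
  medications = c("patient_id", "drug_class", "date"),
  procedures = c("patient_id", "code", "date", "is_amputation")
)

read_cohort_table <- function(path, what) {
  if (!file.exists(path))
    stop(sprintf("%s table not found: %s", what, path), call. = FALSE)
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(cohort_required_cols[[what]], names(tbl))
  if (length(missing))
    stop(sprintf("%s table '%s' is missing required column(s): %s", what,
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  if ("date" %in% names(tbl))
    tbl$date <- parse_iso_date(tbl$date, sprintf("%s table", what))
  tbl
}

#' Read a cohort from five delimited-text tables
#'
#' All tables are comma-separated UTF-8 with a mandatory header and ISO-8601
#' (`YYYY-MM-DD`) dates. ICD and procedure codes are normalized on load (dots
#' stripped, upper-cased); event rows whose `patient_id` is absent from the
#' patients table are dropped with a logged count.
#'
#' @param patients_path,diagnoses_path,labs_path,medications_path,procedures_path
#'   Paths to the five CSV tables.
#' @return A [cohort_dataset()].
#' @export
read_cohort <- function(patients_path, diagnoses_path, labs_path,
                        medications_path, procedures_path) {
  patients <- read_cohort_table(patients_path, "patients") |>
    dplyr::mutate(age_years = as.numeric(.data$age_years))
  labs <- read_cohort_table(labs_path, "labs") |>
    dplyr::mutate(value = as.numeric(.data$value))
  procedures <- read_cohort_table(procedures_path, "procedures") |>
    dplyr::mutate(is_amputation = as.integer(.data$is_amputation))
  cohort_dataset(
    patients = patients,
    diagnoses = read_cohort_table(diagnoses_path, "diagnoses"),
    labs = labs,
    medications = read_cohort_table(medications_path, "medications"),
    procedures = procedures,
    provenance = list(source = dirname(patients_path))
  )
}

#' Write a cohort to five CSV tables in a directory
#'
#' Writes `patients.csv`, `diagnoses.csv`, `labs.csv`, `medications.csv`,
#' `procedures.csv` (plus `provenance.json` when provenance is non-empty)
#' in a stable, reproducible byte layout.
#'
#' @param cohort A [cohort_dataset()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tbl in c("patients", "diagnoses", "labs", "medications",
                "procedures")) {
    readr::write_csv(cohort[[tbl]], file.path(dir, paste0(tbl, ".csv")),
                     progress = FALSE)
  }
  if (length(cohort$provenance))
    jsonlite::write_json(cohort$provenance,
                         file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' @param dir Directory holding the five cohort CSVs.
#' @return A [cohort_dataset()].
#' @export
read_cohort_dir <- function(dir) {
  read_cohort(file.path(dir, "patients.csv"),
              file.path(dir, "diagnoses.csv"),
              file.path(dir, "labs.csv"),
              file.path(dir, "medications.csv"),
              file.path(dir, "procedures.csv"))
}

#' Write an element matrix to CSV
#'
#' One row per patient: `patient_id`, `stratum`, `age_years`, `sex`, then one
#' 0/1 column per element in cycle order.
#'
#' @param matrix Element-matrix tibble from [derive_element_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_element_matrix <- function(matrix, path) {
  if (!nrow(matrix))
    stop("element matrix is empty; nothing to write", call. = FALSE)
  out <- dplyr::mutate(matrix,
                       dplyr::across(dplyr::where(is.logical), as.integer))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an element matrix written by [write_element_matrix()]
#'
#' @param path CSV path.
#' @return Tibble with logical element columns.
#' @export
read_element_matrix <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    patient_id = "c", stratum = "c", age_years = "d", sex = "c",
    .default = "i"), progress = FALSE)
  dplyr::mutate(tbl, dplyr::across(dplyr::where(is.integer), as.logical))
}

#' Write continuum estimates to CSV and/or JSON
#'
#' The CSV is the long-form estimates table — `stratum`, `element_id`, `or`,
#' `ci_low`, `ci_high`, `p_value`, `significant` (0/1), `is_reference` (0/1),
#' `degenerate` (0/1), `n_events_stratum` — with ORs and CI bounds rendered
#' to a fixed precision (default 4 decimals). The JSON export additionally
#' embeds all model metadata (reference stratum, covariates, alpha, per-model
#' n, convergence status) for programmatic use.
#'
#' @param est A `continuum_estimates` object from [estimate_continuum()].
#' @param path Output path; `.json` extension selects the JSON form,
#'   anything else CSV.
#' @param digits Decimal places used for OR and CI bounds in the CSV.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(est, path, digits = 4L) {
  stopifnot(inherits(est, "continuum_estimates"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- list(
      spec_name = est$spec_name,
      reference_stratum = est$reference_stratum,
      covariates = est$covariates,
      alpha = est$alpha,
      models = est$models,
      results = est$results
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    out <- est$results |>
      dplyr::mutate(
        dplyr::across(c("or", "ci_low", "ci_high"), ~ round(.x, digits)),
        significant = as.integer(.data$significant),
        is_reference = as.integer(.data$is_reference),
        degenerate = as.integer(.data$degenerate))
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}
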