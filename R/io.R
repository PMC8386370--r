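# CSV / YAML / JSON interchange. CSVs are RFC 4180 via write.csv with
# ISO-8601 dates and the empty string for missing values.

.write_csv <- function(df, path) {
  for (nm in names(df)) {
    if (inherits(df[[nm]], "Date")) df[[nm]] <- format(df[[nm]], "%Y-%m-%d")
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a synthetic EHR to CSV files
#'
#' Writes `visits.csv`, `diagnoses.csv`, `demographics.csv`,
#' `registry_ids.csv` and a `truth.json` sidecar with the ground-truth
#' model parameters, onset dates and corruption counts.
#'
#' @param sim a `"synthetic_ehr"` object from [simulate_ehr()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_ehr_csvs <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_ehr"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    visits = file.path(dir, "visits.csv"),
    diagnoses = file.path(dir, "diagnoses.csv"),
    demographics = file.path(dir, "demographics.csv"),
    registry_ids = file.path(dir, "registry_ids.csv"),
    truth = file.path(dir, "truth.json")
  )
  .write_csv(sim$visits, paths["visits"])
  .write_csv(sim$diagnoses, paths["diagnoses"])
  .write_csv(sim$demographics, paths["demographics"])
  .write_csv(data.frame(patient_id = sim$registry_ids), paths["registry_ids"])
  truth <- sim$truth
  sidecar <- list(
    model = lapply(truth$model, function(s) unclass(s)),
    corruption = as.list(truth$corruption),
    onsets = truth$onsets,
    patients = truth$patients
  )
  jsonlite::write_json(sidecar, paths["truth"], auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(paths)
}

#' Read the visit table
#' @param path CSV path with columns `patient_id,date,height,weight`.
#' @return data.frame with typed columns; empty strings become `NA`.
#' @export
read_visit_csv <- function(path) {
  v <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(patient_id = "character"))
  v$date <- as.Date(v$date)
  v$height <- as.numeric(v$height)
  v$weight <- as.numeric(v$weight)
  v
}

#' Read the diagnosis table
#' @param path CSV path with columns `patient_id,date,code`.
#' @return data.frame with typed columns.
#' @export
read_diagnosis_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(patient_id = "character",
                                      code = "character"))
  d$date <- as.Date(d$date)
  d
}

#' Read the demographics table
#' @param path CSV path with columns
#'   `patient_id,birth_date,sex,race_ethnicity,insurance,smoking`.
#' @return data.frame with typed columns.
#' @export
read_demographics_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(patient_id = "character"))
  d$birth_date <- as.Date(d$birth_date)
  d
}

#' Read a registry id list
#' @param path CSV path with a `patient_id` column (or a bare id list).
#' @return character vector of ids.
#' @export
read_registry_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  as.character(d[[1]])
}

#' Read a generator configuration from YAML
#'
#' Top-level keys mirror the [ehr_config()] arguments; `comorbidities`
#' maps names to [true_model_spec()] fields and `errors` to
#' [error_spec()] fields.
#'
#' @param path YAML file path.
#' @return an `"ehr_config"` object.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        c("n_patients", "window_start", "window_end",
                          "visit_rate", "demographics", "anthro",
                          "exclusions"))]
  if (!is.null(raw$comorbidities)) {
    args$comorbidities <- stats::setNames(
      lapply(names(raw$comorbidities), function(nm) {
        do.call(true_model_spec,
                c(list(name = nm), raw$comorbidities[[nm]]))
      }), names(raw$comorbidities))
  }
  if (!is.null(raw$errors)) args$errors <- do.call(error_spec, raw$errors)
  if (!is.null(args$demographics)) {
    for (nm in c("race", "insurance", "smoking")) {
      if (!is.null(args$demographics[[nm]])) {
        args$demographics[[nm]] <- unlist(args$demographics[[nm]])
      }
    }
    if (!is.null(args$demographics$age_range)) {
      args$demographics$age_range <- unlist(args$demographics$age_range)
    }
  }
  if (!is.null(args$anthro)) {
    for (nm in c("height_mean", "height_sd")) {
      if (!is.null(args$anthro[[nm]])) {
        args$anthro[[nm]] <- unlist(args$anthro[[nm]])
      }
    }
  }
  do.call(ehr_config, args)
}
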