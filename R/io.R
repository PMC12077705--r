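#' Read and write cohort bundles as flat files
#'
#' A cohort directory holds `patients.csv`, `prescriptions.csv`,
#' `reports.jsonl` (one JSON object per line with `patient_id`,
#' `report_date`, `document_type`, `text`) and `volumes.csv`. Dates are
#' ISO-8601; empty strings are missing. Unknown extra columns in the CSV
#' tables are preserved through a round trip. `write_cohort()` followed by
#' `read_cohort()` reproduces the bundle exactly.
#'
#' @param dir Directory containing (or to receive) the four cohort files.
#' @param cohort A [gbm_cohort()] bundle.
#' @return `read_cohort()` returns a `gbm_cohort`; `write_cohort()` returns
#'   `dir` invisibly.
#' @export
read_cohort <- function(dir) {
  paths <- cohort_paths(dir)
  for (p in paths[c("patients", "prescriptions", "volumes")]) {
    if (!file.exists(p)) stop("missing cohort file: ", p, call. = FALSE)
  }
  patients <- utils::read.csv(paths$patients, colClasses = "character")
  prescriptions <- utils::read.csv(paths$prescriptions,
    colClasses = "character"
  )
  volumes <- utils::read.csv(paths$volumes, colClasses = "character")
  reports <- if (file.exists(paths$reports)) {
    read_reports_jsonl(paths$reports)
  } else {
    NULL
  }
  gbm_cohort(patients, prescriptions, reports, volumes)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gbm_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- cohort_paths(dir)
  write_csv_iso(cohort$patients, paths$patients)
  write_csv_iso(cohort$prescriptions, paths$prescriptions)
  vol <- cohort$volumes
  vol$total_tumor_cm3 <- NULL # derived; recomputed on read
  vol$total_burden_cm3 <- NULL
  write_csv_iso(vol, paths$volumes)
  write_reports_jsonl(cohort$reports, paths$reports)
  invisible(dir)
}

cohort_paths <- function(dir) {
  list(
    patients = file.path(dir, "patients.csv"),
    prescriptions = file.path(dir, "prescriptions.csv"),
    reports = file.path(dir, "reports.jsonl"),
    volumes = file.path(dir, "volumes.csv")
  )
}

write_csv_iso <- function(df, path) {
  for (col in names(df)) {
    if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]], "%Y-%m-%d")
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

read_reports_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(NULL)
  }
  recs <- lapply(lines, jsonlite::fromJSON)
  as.data.frame(do.call(rbind, lapply(recs, function(r) {
    data.frame(
      patient_id = as.character(r$patient_id),
      report_date = as.character(r$report_date),
      document_type = as.character(r$document_type),
      text = as.character(r$text),
      stringsAsFactors = FALSE
    )
  })))
}

write_reports_jsonl <- function(reports, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(reports)) {
    for (i in seq_len(nrow(reports))) {
      writeLines(jsonlite::toJSON(
        list(
          patient_id = reports$patient_id[i],
          report_date = format(reports$report_date[i], "%Y-%m-%d"),
          document_type = reports$document_type[i],
          text = reports$text[i]
        ),
        auto_unbox = TRUE
      ), con)
    }
  }
  invisible(path)
}

#' Write derived endpoints to results.csv
#'
#' Serialises a long results table (`patient_id`, `method`, `progressed`,
#' `progression_date`, `pfs_months`) as CSV. `progressed` is written as
#' `true`/`false`, and left empty for patients not evaluable by a method
#' (e.g. no pre-CRT baseline scan for the volumetric method).
#'
#' @param results Results data.frame, e.g. `derive_pfs(...)$results`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  out <- results[, c(
    "patient_id", "method", "progressed", "progression_date", "pfs_months"
  )]
  out$progressed <- ifelse(is.na(out$progressed), "",
    ifelse(out$progressed, "true", "false")
  )
  out$progression_date <- ifelse(is.na(out$progression_date), "",
    format(as.Date(out$progression_date, origin = "1970-01-01"), "%Y-%m-%d")
  )
  out$pfs_months <- ifelse(is.na(out$pfs_months), "",
    format(out$pfs_months, trim = TRUE)
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
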