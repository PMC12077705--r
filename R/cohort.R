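#' Assemble an EHR cohort bundle
#'
#' Bundles the four per-patient EHR tables used throughout the package into a
#' validated `gbm_cohort` object: a patient table of anchor dates, a
#' prescription table, a radiology-report table, and a scan-volume table.
#' Derived volume columns (`total_tumor_cm3 = ce + ne`,
#' `total_burden_cm3 = total_tumor + edema`) are recomputed on construction.
#'
#' @param patients data.frame with columns `patient_id`, `diagnosis_date`,
#'   `surgery_date`, `crt_end_date`, `clinical_progression_date`,
#'   `treatment_year`, and optionally `followup_complete` (logical; `FALSE`
#'   marks a patient whose clinical progression status could not be
#'   determined, e.g. lost to follow-up). Dates are ISO-8601; empty = missing.
#' @param prescriptions data.frame with `patient_id`, `drug_name`,
#'   `brand_name`, `dose_mg` (> 0, milligrams), `route`, `order_date`.
#' @param reports data.frame with `patient_id`, `report_date`,
#'   `document_type`, `text`.
#' @param volumes data.frame with `patient_id`, `scan_date`, `ce_tumor_cm3`,
#'   `ne_tumor_cm3`, `edema_cm3` (all >= 0, cubic centimetres).
#' @return An object of class `gbm_cohort`: a list of the four validated
#'   tables.
#' @seealso [read_cohort()], [apply_eligibility()], [derive_pfs()]
#' @export
gbm_cohort <- function(patients, prescriptions = NULL, reports = NULL,
                       volumes = NULL) {
  patients <- validate_patients(as.data.frame(patients))
  prescriptions <- validate_prescriptions(empty_if_null(
    prescriptions,
    c("patient_id", "drug_name", "brand_name", "dose_mg", "route", "order_date")
  ))
  reports <- validate_reports(empty_if_null(
    reports, c("patient_id", "report_date", "document_type", "text")
  ))
  volumes <- validate_volumes(empty_if_null(
    volumes,
    c("patient_id", "scan_date", "ce_tumor_cm3", "ne_tumor_cm3", "edema_cm3")
  ))
  out <- structure(
    list(
      patients = patients, prescriptions = prescriptions,
      reports = reports, volumes = volumes
    ),
    class = "gbm_cohort"
  )
  check_referential_integrity(out)
  out
}

empty_if_null <- function(x, cols) {
  if (is.null(x)) {
    x <- as.data.frame(
      stats::setNames(rep(list(character(0)), length(cols)), cols)
    )
  }
  as.data.frame(x)
}

validate_patients <- function(p) {
  need_cols(p, c(
    "patient_id", "diagnosis_date", "surgery_date", "crt_end_date",
    "clinical_progression_date", "treatment_year"
  ), "patients")
  p$patient_id <- as.character(p$patient_id)
  if (anyDuplicated(p$patient_id)) {
    stop("duplicate patient_id in patient table", call. = FALSE)
  }
  for (col in c(
    "diagnosis_date", "surgery_date", "crt_end_date",
    "clinical_progression_date"
  )) {
    p[[col]] <- as_date_strict(p[[col]], col)
  }
  p$treatment_year <- as.integer(p$treatment_year)
  if (is.null(p$followup_complete)) p$followup_complete <- TRUE
  p$followup_complete <- as.logical(p$followup_complete)
  ok <- is.na(p$diagnosis_date) | is.na(p$surgery_date) |
    p$diagnosis_date <= p$surgery_date
  ok2 <- is.na(p$surgery_date) | is.na(p$crt_end_date) |
    p$surgery_date <= p$crt_end_date
  if (!all(ok & ok2)) {
    stop("patient anchor dates out of order (diagnosis <= surgery <= CRT end)",
      call. = FALSE
    )
  }
  ok3 <- is.na(p$clinical_progression_date) | is.na(p$crt_end_date) |
    p$clinical_progression_date >= p$crt_end_date
  if (!all(ok3)) {
    stop("clinical_progression_date precedes crt_end_date", call. = FALSE)
  }
  p
}

validate_prescriptions <- function(x) {
  need_cols(x, c(
    "patient_id", "drug_name", "brand_name", "dose_mg", "route", "order_date"
  ), "prescriptions")
  x$patient_id <- as.character(x$patient_id)
  x$drug_name <- as.character(x$drug_name)
  x$brand_name <- as.character(x$brand_name)
  x$dose_mg <- as.numeric(x$dose_mg)
  bad <- which(is.na(x$dose_mg) | x$dose_mg <= 0)
  if (length(bad)) {
    stop(sprintf("prescriptions row %d: dose_mg must be > 0", bad[1L]),
      call. = FALSE
    )
  }
  x$route <- as.character(x$route)
  x$order_date <- as_date_strict(x$order_date, "order_date")
  if (anyNA(x$order_date)) {
    stop(sprintf(
      "prescriptions row %d: missing order_date",
      which(is.na(x$order_date))[1L]
    ), call. = FALSE)
  }
  x
}

validate_reports <- function(x) {
  need_cols(x, c("patient_id", "report_date", "document_type", "text"),
    "reports")
  x$patient_id <- as.character(x$patient_id)
  x$report_date <- as_date_strict(x$report_date, "report_date")
  x$document_type <- as.character(x$document_type)
  x$text <- as.character(x$text)
  x
}

validate_volumes <- function(x) {
  need_cols(x, c(
    "patient_id", "scan_date", "ce_tumor_cm3", "ne_tumor_cm3", "edema_cm3"
  ), "volumes")
  x$patient_id <- as.character(x$patient_id)
  x$scan_date <- as_date_strict(x$scan_date, "scan_date")
  for (col in c("ce_tumor_cm3", "ne_tumor_cm3", "edema_cm3")) {
    x[[col]] <- as.numeric(x[[col]])
    bad <- which(is.na(x[[col]]) | x[[col]] < 0)
    if (length(bad)) {
      stop(sprintf("volumes row %d: %s must be a non-negative number",
        bad[1L], col), call. = FALSE)
    }
  }
  x$total_tumor_cm3 <- x$ce_tumor_cm3 + x$ne_tumor_cm3
  x$total_burden_cm3 <- x$total_tumor_cm3 + x$edema_cm3
  x
}

need_cols <- function(x, cols, what) {
  miss <- setdiff(cols, names(x))
  if (length(miss)) {
    stop(sprintf("%s table is missing column(s): %s", what,
      paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

check_referential_integrity <- function(cohort) {
  ids <- cohort$patients$patient_id
  for (tab in c("prescriptions", "reports", "volumes")) {
    stray <- setdiff(unique(cohort[[tab]]$patient_id), ids)
    if (length(stray)) {
      stop(sprintf("%s table references unknown patient(s): %s", tab,
        paste(stray, collapse = ", ")), call. = FALSE)
    }
  }
  invisible(cohort)
}

#' @export
print.gbm_cohort <- function(x, ...) {
  cat("EHR cohort bundle\n")
  cat(sprintf("  patients:      %d\n", nrow(x$patients)))
  cat(sprintf("  prescriptions: %d\n", nrow(x$prescriptions)))
  cat(sprintf("  reports:       %d\n", nrow(x$reports)))
  cat(sprintf("  scan volumes:  %d\n", nrow(x$volumes)))
  invisible(x)
}

#' Cohort eligibility filter
#'
#' Applies the study inclusion rules: a patient is eligible when they have at
#' least one radiology report, at least one prescription, at least two brain
#' MRI scans dated after the end of chemoirradiation, and a resolvable
#' clinical progression determination (a clinical progression date, or
#' complete follow-up documenting stability). Patients flagged
#' `followup_complete = FALSE` without a clinical date are excluded.
#'
#' The filter is idempotent and monotone: removing a patient's datapoints can
#' only remove them from the eligible set, never add them.
#'
#' @param cohort A [gbm_cohort()] bundle.
#' @return Character vector of eligible patient ids, in patient-table order.
#' @export
apply_eligibility <- function(cohort) {
  stopifnot(inherits(cohort, "gbm_cohort"))
  check_referential_integrity(cohort)
  p <- cohort$patients
  n_rx <- table(factor(cohort$prescriptions$patient_id, levels = p$patient_id))
  n_rep <- table(factor(cohort$reports$patient_id, levels = p$patient_id))
  post_crt <- merge(
    cohort$volumes[, c("patient_id", "scan_date")],
    p[, c("patient_id", "crt_end_date")],
    by = "patient_id"
  )
  post_crt <- post_crt[!is.na(post_crt$crt_end_date) &
    post_crt$scan_date > post_crt$crt_end_date, ]
  n_scan <- table(factor(post_crt$patient_id, levels = p$patient_id))
  resolvable <- !is.na(p$clinical_progression_date) |
    (is.na(p$clinical_progression_date) & p$followup_complete)
  keep <- as.integer(n_rx) >= 1L & as.integer(n_rep) >= 1L &
    as.integer(n_scan) >= 2L & resolvable & !is.na(p$crt_end_date)
  p$patient_id[keep]
}
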