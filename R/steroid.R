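#' Default dexamethasone brand synonyms
#'
#' Case-insensitive brand names accepted as dexamethasone alongside the
#' generic keyword. Shipped as an editable default: pass your formulary's
#' list to [select_dexamethasone()] to extend it.
#'
#' @return Character vector of synonyms.
#' @export
dexamethasone_synonyms <- function() {
  c(
    "decadron", "dexamethasone intensol", "dexpak", "dxevo", "hemady",
    "taperdex", "zcort", "zonacort", "maxidex"
  )
}

#' Select dexamethasone prescriptions
#'
#' Keeps prescription records whose generic `drug_name` contains
#' "dexamethasone" (case-insensitive) or whose generic/brand name matches a
#' configured brand synonym, at any dose and any administration route.
#'
#' @param prescriptions Prescription table (see [gbm_cohort()]).
#' @param synonyms Character vector of brand synonyms; defaults to
#'   [dexamethasone_synonyms()].
#' @return The matching subset of `prescriptions`.
#' @export
select_dexamethasone <- function(prescriptions,
                                 synonyms = dexamethasone_synonyms()) {
  generic <- tolower(trimws(prescriptions$drug_name))
  brand <- tolower(trimws(prescriptions$brand_name))
  syn <- tolower(trimws(synonyms))
  keep <- grepl("dexamethasone", generic, fixed = TRUE) |
    generic %in% syn | brand %in% syn
  prescriptions[keep, , drop = FALSE]
}

#' Restrict prescriptions to one month after chemoirradiation
#'
#' Steroids are routinely given post-surgery and during chemoirradiation
#' (CRT), so only orders dated at least one mean month (30.4375 days,
#' boundary inclusive) after the CRT end date can signal progression.
#'
#' @param prescriptions Prescription table rows for one patient.
#' @param crt_end_date The patient's last day of radiotherapy (`Date`).
#' @return The subset with `order_date >= crt_end_date + 30.4375` days.
#' @export
filter_post_crt <- function(prescriptions, crt_end_date) {
  if (is.null(crt_end_date) || length(crt_end_date) != 1L ||
    is.na(crt_end_date)) {
    stop("filter_post_crt() requires the patient's crt_end_date",
      call. = FALSE
    )
  }
  crt_end_date <- as_date_strict(crt_end_date, "crt_end_date")
  offset <- as.numeric(prescriptions$order_date - crt_end_date,
    units = "days"
  )
  prescriptions[offset >= DAYS_PER_MONTH, , drop = FALSE]
}

#' Derive the post-CRT dexamethasone taper window
#'
#' All post-CRT dexamethasone orders for a patient are treated as a single
#' taper course: the course runs from the first order date carrying the
#' largest dose to the last order date carrying the smallest dose. Ties in
#' dose are resolved by exhaustive min/max over the tied records, so when
#' all doses are equal the course spans the earliest to the latest order.
#'
#' @param prescriptions Post-CRT dexamethasone records for one patient.
#' @return A list of class `taper_course` with `course_start`, `course_end`,
#'   `max_dose_mg`, `min_dose_mg`, `n_orders`, or `NULL` when no records
#'   exist (the no-course signal).
#' @export
derive_taper_course <- function(prescriptions) {
  if (is.null(prescriptions) || nrow(prescriptions) == 0L) {
    return(NULL)
  }
  dose <- prescriptions$dose_mg
  dmax <- max(dose)
  dmin <- min(dose)
  structure(
    list(
      patient_id = prescriptions$patient_id[1L],
      course_start = min(prescriptions$order_date[dose == dmax]),
      course_end = max(prescriptions$order_date[dose == dmin]),
      max_dose_mg = dmax,
      min_dose_mg = dmin,
      n_orders = nrow(prescriptions)
    ),
    class = "taper_course"
  )
}

#' @export
print.taper_course <- function(x, ...) {
  cat(sprintf(
    "Dexamethasone taper course for %s: %s to %s (%g mg -> %g mg, %d orders)\n",
    x$patient_id, format(x$course_start), format(x$course_end),
    x$max_dose_mg, x$min_dose_mg, x$n_orders
  ))
  invisible(x)
}

#' Prescription-derived progression endpoint for one patient
#'
#' Selects the patient's dexamethasone orders, drops everything within one
#' month of CRT end, collapses the remainder into a single taper course, and
#' calls progression at the course start date. Patients with no post-CRT
#' dexamethasone are non-progressors under this method.
#'
#' @param patient One row of the patient table.
#' @param prescriptions The patient's prescription records.
#' @param synonyms Brand synonyms passed to [select_dexamethasone()].
#' @return A one-row endpoint data.frame (see [derive_pfs()]) with the taper
#'   course attached as the `evidence` attribute.
#' @export
steroid_pfs <- function(patient, prescriptions,
                        synonyms = dexamethasone_synonyms()) {
  dex <- select_dexamethasone(prescriptions, synonyms)
  dex <- filter_post_crt(dex, patient$crt_end_date)
  course <- derive_taper_course(dex)
  if (is.null(course)) {
    return(endpoint_row(patient, "steroid", FALSE))
  }
  endpoint_row(patient, "steroid", TRUE, course$course_start,
    evidence = course
  )
}
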