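# One-row endpoint record shared by all methods. `progressed` may be NA for
# not-evaluable (e.g. no volumetric baseline); a date is carried iff
# progressed is TRUE, and pfs_months is measured from the CRT end date.
endpoint_row <- function(patient, method, progressed, progression_date = NULL,
                         evidence = NULL) {
  progressed <- as.logical(progressed)
  if (isTRUE(progressed)) {
    stopifnot(!is.null(progression_date), !is.na(progression_date))
    pfs <- months_between(patient$crt_end_date, progression_date)
    date <- as.Date(progression_date)
  } else {
    pfs <- NA_real_
    date <- as.Date(NA)
  }
  out <- data.frame(
    patient_id = patient$patient_id, method = method,
    progressed = progressed, progression_date = date, pfs_months = pfs,
    stringsAsFactors = FALSE
  )
  attr(out, "evidence") <- evidence
  out
}

#' Clinical-standard progression endpoint
#'
#' Wraps the manually assigned (RANO chart review, or synthetic ground
#' truth) progression date as an endpoint record: progression-free survival
#' is measured in months from the end of chemoirradiation.
#'
#' @param patient One row of the patient table.
#' @return A one-row endpoint data.frame (see [derive_pfs()]).
#' @export
clinical_pfs <- function(patient) {
  if (!is.na(patient$clinical_progression_date)) {
    endpoint_row(patient, "clinical", TRUE,
      patient$clinical_progression_date)
  } else if (isTRUE(patient$followup_complete)) {
    endpoint_row(patient, "clinical", FALSE)
  } else {
    endpoint_row(patient, "clinical", NA)
  }
}

#' Derive PFS endpoints from every EHR modality
#'
#' The package's main entry point. For each eligible patient it derives a
#' progression-free-survival determination from each requested modality:
#'
#' * `clinical` — the manually assigned clinical-standard date;
#' * `steroid` — the start of the post-CRT dexamethasone taper course
#'   ([steroid_pfs()]);
#' * `nlp` — the first post-treatment brain-MRI report whose rule-based
#'   assessment indicates progression ([nlp_pfs()]);
#' * `volumetric` — the first post-CRT scan with a relative
#'   contrast-enhancing volume increase at or above the threshold
#'   ([volumetric_pfs()]).
#'
#' @param cohort A [gbm_cohort()] bundle.
#' @param methods Subset of `c("clinical", "steroid", "nlp", "volumetric")`.
#' @param lexicon Term lexicon for the report method.
#' @param synonyms Dexamethasone brand synonyms for the prescription method.
#' @param threshold Volumetric progression threshold (default 1.05).
#' @param eligible_only Apply [apply_eligibility()] first (default `TRUE`).
#' @return An object of class `pfs_endpoints`: a list with `results` (long
#'   data.frame of `patient_id`, `method`, `progressed`,
#'   `progression_date`, `pfs_months`), `evidence` (per patient and method,
#'   the audit payload), `cohort_n`, `patients` and the matched `call`.
#'   `progressed` is `NA` where a method was not evaluable for a patient.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_patients = 8, seed = 1))$cohort
#' fit <- derive_pfs(cohort)
#' summary(fit)
#' @export
derive_pfs <- function(cohort,
                       methods = c("clinical", "steroid", "nlp", "volumetric"),
                       lexicon = default_lexicon(),
                       synonyms = dexamethasone_synonyms(),
                       threshold = 1.05,
                       eligible_only = TRUE) {
  stopifnot(inherits(cohort, "gbm_cohort"))
  methods <- match.arg(methods, several.ok = TRUE)
  ids <- if (eligible_only) {
    apply_eligibility(cohort)
  } else {
    cohort$patients$patient_id
  }
  patients <- cohort$patients[cohort$patients$patient_id %in% ids, ,
    drop = FALSE
  ]
  rows <- list()
  evidence <- list()
  for (i in seq_len(nrow(patients))) {
    patient <- patients[i, ]
    pid <- patient$patient_id
    rx <- cohort$prescriptions[cohort$prescriptions$patient_id == pid, ,
      drop = FALSE
    ]
    reports <- cohort$reports[cohort$reports$patient_id == pid, ,
      drop = FALSE
    ]
    scans <- cohort$volumes[cohort$volumes$patient_id == pid, , drop = FALSE]
    for (method in methods) {
      row <- switch(method,
        clinical = clinical_pfs(patient),
        steroid = steroid_pfs(patient, rx, synonyms),
        nlp = nlp_pfs(patient, reports, lexicon),
        volumetric = volumetric_pfs(patient, scans, threshold)
      )
      rows[[length(rows) + 1L]] <- row
      evidence[[pid]][[method]] <- attr(row, "evidence")
    }
  }
  results <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      patient_id = character(), method = character(), progressed = logical(),
      progression_date = as.Date(character()), pfs_months = numeric()
    )
  }
  rownames(results) <- NULL
  structure(
    list(
      results = results, evidence = evidence, cohort_n = nrow(patients),
      patients = patients, methods = methods, threshold = threshold,
      call = match.call()
    ),
    class = "pfs_endpoints"
  )
}

#' @export
print.pfs_endpoints <- function(x, ...) {
  cat("PFS endpoint derivation\n")
  cat(sprintf("  cohort: %d eligible patients\n", x$cohort_n))
  for (m in x$methods) {
    sub <- x$results[x$results$method == m, ]
    n_prog <- sum(sub$progressed %in% TRUE)
    cat(sprintf(
      "  %-10s progressed %d/%d (%d%%)\n", m, n_prog, x$cohort_n,
      round(100 * n_prog / max(x$cohort_n, 1L))
    ))
  }
  cat("Use summary() for descriptive statistics and comparative tests.\n")
  invisible(x)
}

#' Differences from the clinical-standard endpoint
#'
#' For a fitted [derive_pfs()] object, the residual of an automated method
#' for a patient is its PFS minus the clinical-standard PFS in months
#' (negative = automated date earlier), defined where both exist.
#'
#' @param object A `pfs_endpoints` object including the `clinical` method.
#' @param ... Unused.
#' @return Data.frame of `patient_id`, `method`, `difference_months`.
#' @export
residuals.pfs_endpoints <- function(object, ...) {
  wide <- aggregate_pfs(object$results)
  stopifnot("clinical" %in% names(wide))
  auto <- setdiff(object$methods, "clinical")
  out <- do.call(rbind, lapply(auto, function(m) {
    d <- wide[[m]] - wide$clinical
    keep <- !is.na(d)
    data.frame(
      patient_id = wide$patient_id[keep], method = m,
      difference_months = d[keep], stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
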