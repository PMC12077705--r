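#' Select the pre-treatment baseline scan
#'
#' The volumetric method compares every follow-up scan against a fixed
#' reference: the earliest scan acquired after surgical resection but before
#' chemoirradiation. Scans outside that window never serve as baseline.
#'
#' @param scans Scan-volume rows for one patient.
#' @param surgery_date The patient's resection date.
#' @param crt_date Upper bound of the baseline window: the CRT start date
#'   when known, otherwise the CRT end date (the patient table carries only
#'   the latter; surveillance scans resume after CRT, so either bound
#'   isolates the same pre-treatment scan).
#' @return The baseline scan row, or `NULL` when no scan falls in the window
#'   (the patient is then not evaluable by this method).
#' @export
select_baseline <- function(scans, surgery_date, crt_date) {
  if (is.na(surgery_date) || is.na(crt_date) || !nrow(scans)) {
    return(NULL)
  }
  window <- scans[!is.na(scans$scan_date) &
    scans$scan_date >= surgery_date &
    scans$scan_date < crt_date, , drop = FALSE]
  if (!nrow(window)) {
    return(NULL)
  }
  window[which.min(window$scan_date), , drop = FALSE]
}

#' Relative volumetric change of contrast-enhancing tumor
#'
#' The ratio of a follow-up contrast-enhancing (CE) tumor volume to the
#' fixed pre-CRT baseline CE volume. Scale-free: multiplying both volumes by
#' a constant leaves the ratio unchanged.
#'
#' @param baseline_ce Baseline CE volume in cm^3 (must be > 0; a zero
#'   baseline, e.g. complete resection, is a degenerate case handled by the
#'   caller as not-evaluable).
#' @param scan_ce Follow-up CE volume in cm^3 (>= 0).
#' @return `scan_ce / baseline_ce`.
#' @export
relative_change <- function(baseline_ce, scan_ce) {
  if (any(baseline_ce < 0) || any(scan_ce < 0)) {
    stop("volumes must be non-negative", call. = FALSE)
  }
  if (any(baseline_ce == 0)) {
    stop("degenerate baseline: contrast-enhancing volume is zero",
      call. = FALSE
    )
  }
  scan_ce / baseline_ce
}

#' Threshold a volume ratio as progression
#'
#' A scan indicates progression when its relative CE change meets or exceeds
#' the threshold (default 1.05, i.e. a >= 5% increase; boundary inclusive).
#' Ratios are compared at full floating precision.
#'
#' @param ratio Relative change from [relative_change()].
#' @param threshold Progression threshold ratio (default `1.05`).
#' @return Logical vector.
#' @export
classify_scan <- function(ratio, threshold = 1.05) {
  if (any(ratio < 0)) stop("ratio must be non-negative", call. = FALSE)
  ratio >= threshold
}

#' Volume-derived progression endpoint for one patient
#'
#' Resolves the pre-CRT baseline, computes the relative CE change of every
#' post-CRT scan against it, and calls progression at the earliest scan
#' meeting the threshold. Later shrinkage never rescinds an earlier call.
#' Patients without a usable baseline (no pre-CRT scan, or zero baseline CE
#' volume after complete resection) are *not evaluable* — distinguished from
#' non-progressors by `progressed = NA`.
#'
#' @param patient One row of the patient table.
#' @param scans The patient's scan-volume records.
#' @param threshold Progression threshold passed to [classify_scan()].
#' @return A one-row endpoint data.frame (see [derive_pfs()]); the evidence
#'   attribute holds the full assessment series (scan date, baseline and
#'   scan CE volumes, ratio, flag).
#' @export
volumetric_pfs <- function(patient, scans, threshold = 1.05) {
  scans <- scans[order(scans$scan_date), , drop = FALSE]
  baseline <- select_baseline(scans, patient$surgery_date,
    patient$crt_end_date)
  if (is.null(baseline) || baseline$ce_tumor_cm3 == 0) {
    return(endpoint_row(patient, "volumetric", NA))
  }
  followup <- scans[scans$scan_date > patient$crt_end_date, , drop = FALSE]
  series <- data.frame(
    scan_date = followup$scan_date,
    baseline_ce_cm3 = baseline$ce_tumor_cm3,
    scan_ce_cm3 = followup$ce_tumor_cm3,
    relative_change = relative_change(
      baseline$ce_tumor_cm3, followup$ce_tumor_cm3
    )
  )
  series$progression_flag <- classify_scan(series$relative_change, threshold)
  hit <- which(series$progression_flag)
  if (length(hit)) {
    endpoint_row(patient, "volumetric", TRUE, series$scan_date[hit[1L]],
      evidence = series
    )
  } else {
    endpoint_row(patient, "volumetric", FALSE, evidence = series)
  }
}
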