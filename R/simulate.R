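#' Synthetic cohort generator configuration
#'
#' Parameters of the seeded synthetic EHR generator. Defaults encode the
#' study conditions of a 92-patient glioblastoma surveillance cohort:
#' right-skewed clinical PFS (lognormal with median ~6.5 and mean ~13.3
#' months), near-universal progression (91/92), dexamethasone taper courses
#' lagging the clinical date by a normal draw (mean 4.5, sd 8.3 months),
#' brain-MRI surveillance every 2-4 months, report/volume radiographic
#' evidence preceding the clinical-standard date (means 6.9 and 2.6 months),
#' and per-modality silence fractions calibrated to standalone progression
#' rates of roughly 63% (prescriptions), 79% (reports) and 54% (volumes).
#'
#' All distributional forms are stand-ins: the generator emulates timing and
#' phrasing structure, not real clinical prose or imaging.
#'
#' @param n_patients Cohort size (default 92).
#' @param seed Integer RNG seed used by [simulate_cohort()].
#' @param p_progress Probability a patient truly progresses (default 91/92).
#' @param truth_pfs_log_mu,truth_pfs_log_sigma Lognormal parameters of true
#'   clinical PFS in months (defaults `log(6.5)` and
#'   `sqrt(2 * log(13.3 / 6.5))`, hitting median 6.5 / mean 13.3).
#' @param truth_pfs_min_months Floor applied to PFS draws (default 0).
#' @param steroid_lag_mean_months,steroid_lag_sd_months Normal lag of the
#'   progression-triggered taper start after the clinical date (4.5, 8.3).
#' @param report_lead_mean_months,report_lead_sd_months Normal lead of
#'   report-visible progression before the clinical date, truncated to
#'   `[0, clinical PFS]` (defaults 6.9, 19.2).
#' @param volume_lead_mean_months,volume_lead_sd_months Same for
#'   volume-visible growth onset (defaults 2.6, 5.8).
#' @param report_interval_months_min,report_interval_months_max Surveillance
#'   spacing bounds in months (defaults 2 and 4).
#' @param p_report_detect Probability a post-onset report uses progression
#'   templates (default 0.8).
#' @param taper_doses_mg Strictly decreasing taper dose sequence in mg
#'   (default 8, 4, 2, 1).
#' @param taper_spacing_days Days between consecutive taper orders (7).
#' @param baseline_ce_log_mu,baseline_ce_log_sigma Lognormal baseline
#'   contrast-enhancing volume, cm^3 (defaults `log(5)`, 0.8).
#' @param ce_growth_rate_per_month Multiplicative post-onset CE growth rate
#'   (default 0.35/month, i.e. a volume doubling time near 2.3 months).
#' @param ce_noise_cv Coefficient of variation of multiplicative scan noise
#'   (default 0.01, small segmentation error).
#' @param frac_volume_silent Fraction of progressors whose CE ratio is
#'   clamped below 1.05 forever (default 0.46).
#' @param frac_steroid_missing Fraction of progressors with no
#'   progression-triggered steroid course (default 0.36).
#' @param frac_report_silent Fraction of progressors whose reports never use
#'   progression phrasing (default 0.20).
#' @param p_distractor_report Probability of one non-brain (chest film)
#'   distractor report per patient (default 0.15).
#' @param followup_extra_months Surveillance continues this long past the
#'   clinical progression date (default 12).
#' @param followup_min_months Minimum surveillance horizon, also used for
#'   non-progressors (default 36).
#' @param followup_max_months Study-window cap on the surveillance schedule
#'   (default 150; the truth PFS itself is never capped).
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 92L,
                          seed = 1L,
                          p_progress = 91 / 92,
                          truth_pfs_log_mu = log(6.5),
                          truth_pfs_log_sigma = sqrt(2 * log(13.3 / 6.5)),
                          truth_pfs_min_months = 0,
                          steroid_lag_mean_months = 4.5,
                          steroid_lag_sd_months = 8.3,
                          report_lead_mean_months = 6.9,
                          report_lead_sd_months = 19.2,
                          volume_lead_mean_months = 2.6,
                          volume_lead_sd_months = 5.8,
                          report_interval_months_min = 2,
                          report_interval_months_max = 4,
                          p_report_detect = 0.8,
                          taper_doses_mg = c(8, 4, 2, 1),
                          taper_spacing_days = 7L,
                          baseline_ce_log_mu = log(5),
                          baseline_ce_log_sigma = 0.8,
                          ce_growth_rate_per_month = 0.35,
                          ce_noise_cv = 0.01,
                          frac_volume_silent = 0.46,
                          frac_steroid_missing = 0.36,
                          frac_report_silent = 0.20,
                          p_distractor_report = 0.15,
                          followup_extra_months = 12,
                          followup_min_months = 36,
                          followup_max_months = 150) {
  config <- as.list(environment())
  validate_config(config)
}

validate_config <- function(config) {
  with(config, {
    stopifnot(
      n_patients >= 1,
      truth_pfs_log_sigma >= 0,
      steroid_lag_sd_months >= 0, report_lead_sd_months >= 0,
      volume_lead_sd_months >= 0,
      report_interval_months_min <= report_interval_months_max,
      report_interval_months_min > 0,
      all(diff(taper_doses_mg) < 0), all(taper_doses_mg > 0),
      taper_spacing_days >= 1,
      ce_growth_rate_per_month >= 0, ce_noise_cv >= 0,
      followup_extra_months > 0, followup_min_months > 0
    )
    for (p in c(
      p_progress, p_report_detect, frac_volume_silent,
      frac_steroid_missing, frac_report_silent, p_distractor_report
    )) {
      stopifnot(p >= 0, p <= 1)
    }
  })
  structure(config, class = "cohort_config")
}

#' Perfect-information generator configuration
#'
#' A diagnostic scenario in which every modality carries an immediate,
#' noise-free progression signal: zero steroid lag and radiographic leads,
#' certain report detection, no silent fractions, no scan noise, CE growth
#' fast enough to cross the 5% threshold within a day (progression visible
#' at the first post-onset scan), and a 1.5-month floor on
#' true PFS so the taper course clears the one-month post-CRT filter. Under
#' it every derived date should land within one surveillance interval of
#' the true progression date.
#'
#' @param n_patients Cohort size.
#' @param seed RNG seed.
#' @return A `cohort_config`.
#' @export
perfect_information_config <- function(n_patients = 92L, seed = 1L) {
  cohort_config(
    n_patients = n_patients, seed = seed, p_progress = 1,
    truth_pfs_min_months = 1.5,
    steroid_lag_mean_months = 0, steroid_lag_sd_months = 0,
    report_lead_mean_months = 0, report_lead_sd_months = 0,
    volume_lead_mean_months = 0, volume_lead_sd_months = 0,
    p_report_detect = 1, ce_growth_rate_per_month = 4, ce_noise_cv = 0,
    frac_volume_silent = 0, frac_steroid_missing = 0,
    frac_report_silent = 0, p_distractor_report = 0,
    followup_max_months = Inf # complete follow-up: no study-window cap
  )
}

#' Draw true progression-free survival times
#'
#' Lognormal months with an optional floor; with defaults the large-sample
#' median is `exp(mu)` (~6.5 months) and the mean `exp(mu + sigma^2 / 2)`
#' (~13.3 months). Uses the current RNG state; seed via [set.seed()] or
#' [simulate_cohort()].
#'
#' @param config A [cohort_config()].
#' @param n Number of draws.
#' @return Numeric vector of months.
#' @export
sample_truth_pfs <- function(config, n = 1L) {
  config <- validate_config(config)
  pmax(
    stats::rlnorm(n, config$truth_pfs_log_mu, config$truth_pfs_log_sigma),
    config$truth_pfs_min_months
  )
}

months_to_days <- function(m) round(m * DAYS_PER_MONTH)

# Surveillance visit dates: integer-day gaps uniform over
# [2, 4] months (in whole days, so each gap is inside the bounds).
surveillance_schedule <- function(crt_end, horizon_months, config) {
  lo <- ceiling(config$report_interval_months_min * DAYS_PER_MONTH)
  hi <- floor(config$report_interval_months_max * DAYS_PER_MONTH)
  dates <- as.Date(character())
  t <- crt_end
  end <- crt_end + months_to_days(horizon_months)
  repeat {
    t <- t + sample(seq.int(lo, hi), 1L)
    if (t > end) break
    dates <- c(dates, t)
  }
  dates
}

# Report template sentence pools built from the default lexicon's stems plus
# neutral filler. Unmodified progression/stability counts are fixed by
# construction and carried as metadata so gold labels are exact.
report_templates <- function() {
  list(
    stability = c(
      "The examination is stable compared with the prior study.",
      "No evidence of tumor progression or new enhancement.",
      "Ventricles and sulci are unchanged.",
      "Previously noted enhancement is decreased."
    ),
    surgical =
      "Postsurgical changes in the resection cavity with peripheral enhancement.",
    progression = c(
      "There is increased enhancement in the left frontal lobe.",
      "Interval growth of the enhancing mass.",
      "New areas of abnormal enhancement consistent with tumor progression.",
      "Worsening mass effect with enlarging enhancement."
    ),
    single_stability = c(
      "The examination is stable compared with the prior study.",
      "Ventricles and sulci are unchanged."
    ),
    filler = c(
      "Axial T1 post contrast images of the brain were obtained.",
      "Comparison was made with the outside examination."
    )
  )
}

stability_report_text <- function(tpl) {
  body <- c(
    sample(tpl$filler, 1L),
    sample(tpl$stability, sample(2:3, 1L)),
    if (stats::runif(1) < 0.5) tpl$surgical
  )
  paste(body, collapse = " ")
}

progression_report_text <- function(tpl) {
  # one progression sentence (2-3 unmodified progression stems) against at
  # most one single-stem stability sentence keeps progression > stability
  body <- c(
    sample(tpl$filler, 1L),
    sample(tpl$progression, 1L),
    if (stats::runif(1) < 0.5) sample(tpl$single_stability, 1L),
    if (stats::runif(1) < 0.3) tpl$surgical
  )
  paste(body, collapse = " ")
}

#' Generate prescription records for one synthetic patient
#'
#' Emits (a) a short post-surgical dexamethasone course dated well before
#' one month after CRT end (exercising the downstream filter), (b) for
#' progressing patients without the steroid-missing flag, a
#' progression-triggered taper whose largest-dose order is dated
#' `clinical date + lag`, with the configured decreasing doses at the
#' configured spacing, and (c) non-steroid distractor orders.
#'
#' @param patient One synthetic patient row (needs `patient_id`,
#'   `surgery_date`, `crt_end_date`).
#' @param truth The patient's truth row from [simulate_cohort()] (needs
#'   `clinical_date`, `steroid_lag_months`, `steroid_missing`).
#' @param config A [cohort_config()].
#' @return Prescription data.frame.
#' @export
generate_prescriptions <- function(patient, truth, config) {
  rx <- function(drug, brand, dose, route, date) {
    data.frame(
      patient_id = patient$patient_id, drug_name = drug, brand_name = brand,
      dose_mg = dose, route = route, order_date = date,
      stringsAsFactors = FALSE
    )
  }
  out <- list(
    rx("dexamethasone", "Decadron", config$taper_doses_mg[1L], "oral",
      patient$surgery_date + 3L),
    rx("dexamethasone", "", config$taper_doses_mg[2L], "oral",
      patient$surgery_date + 10L),
    rx("temozolomide", "Temodar", 140, "oral", patient$crt_end_date - 40L),
    rx("levetiracetam", "Keppra", 500, "oral", patient$surgery_date + 5L),
    rx("ondansetron", "", 8, "oral", patient$crt_end_date - 30L)
  )
  if (!is.na(truth$clinical_date) && !truth$steroid_missing) {
    start <- truth$clinical_date +
      months_to_days(truth$steroid_lag_months)
    for (k in seq_along(config$taper_doses_mg)) {
      out[[length(out) + 1L]] <- rx(
        "dexamethasone", "", config$taper_doses_mg[k],
        if (k == 1L) "intravenous" else "oral",
        start + (k - 1L) * config$taper_spacing_days
      )
    }
  }
  do.call(rbind, out)
}

#' Generate surveillance radiology reports for one synthetic patient
#'
#' Reports follow the surveillance schedule; before the report-visible
#' onset they use stability templates (stability stems, negated progression
#' phrases, surgical-cavity sentences), after it progression templates with
#' probability `p_report_detect`. Each report carries its gold status.
#'
#' @inheritParams generate_prescriptions
#' @param dates Surveillance dates (from the cohort-level schedule).
#' @return List with `reports` (report data.frame) and `gold` (data.frame
#'   of `patient_id`, `report_date`, `gold_status`).
#' @export
generate_reports <- function(patient, truth, config, dates) {
  tpl <- report_templates()
  onset <- truth$report_onset_date
  detectable <- !is.na(onset) && !truth$report_silent
  is_prog <- vapply(dates, function(d) {
    detectable && d >= onset && stats::runif(1) < config$p_report_detect
  }, logical(1))
  texts <- vapply(seq_along(dates), function(i) {
    if (is_prog[i]) progression_report_text(tpl) else stability_report_text(tpl)
  }, character(1))
  reports <- data.frame(
    patient_id = patient$patient_id, report_date = dates,
    document_type = "MRI BRAIN-Perfusion (IP)", text = texts,
    stringsAsFactors = FALSE
  )
  gold <- data.frame(
    patient_id = patient$patient_id, report_date = dates,
    gold_status = ifelse(is_prog, "progression", "stability"),
    stringsAsFactors = FALSE
  )
  if (length(dates) && stats::runif(1) < config$p_distractor_report) {
    reports <- rbind(reports, data.frame(
      patient_id = patient$patient_id, report_date = dates[1L] + 10L,
      document_type = "DX Chest - PA + Lat",
      text = "Clear lungs. The cardiomediastinal silhouette is within normal limits.",
      stringsAsFactors = FALSE
    ))
  }
  list(reports = reports, gold = gold)
}

#' Generate scan-volume records for one synthetic patient
#'
#' One post-surgery, pre-CRT baseline scan plus follow-ups on the
#' surveillance schedule. The contrast-enhancing volume is the baseline
#' draw under multiplicative noise before the volume-visible onset and
#' grows at `ce_growth_rate_per_month` after it; patients drawn into the
#' volume-silent fraction are clamped so every ratio stays below 1.05.
#' Non-enhancing tumor and edema are carried as plausible correlated
#' volumes (they never drive classification).
#'
#' @inheritParams generate_reports
#' @return List with `volumes` (scan data.frame) and `gold` (data.frame of
#'   `patient_id`, `scan_date`, `gold_ratio`, `gold_flag`).
#' @export
generate_volumes <- function(patient, truth, config, dates) {
  baseline_date <- patient$surgery_date +
    sample(7:18, 1L) # pre-CRT window: CRT starts >= 21 days post-surgery
  base_ce <- stats::rlnorm(
    1, config$baseline_ce_log_mu, config$baseline_ce_log_sigma
  )
  noise <- function(n) {
    if (config$ce_noise_cv == 0) {
      rep(1, n)
    } else {
      s <- sqrt(log(1 + config$ce_noise_cv^2))
      stats::rlnorm(n, -s^2 / 2, s)
    }
  }
  onset <- truth$volume_onset_date
  growing <- !is.na(onset) && !truth$volume_silent
  all_dates <- c(baseline_date, dates)
  ce <- vapply(seq_along(all_dates), function(i) {
    d <- all_dates[i]
    if (i == 1L) {
      return(base_ce)
    }
    v <- base_ce
    if (growing && d > onset) {
      v <- v * (1 + config$ce_growth_rate_per_month)^
        (months_between(onset, d))
    }
    v * noise(1)
  }, numeric(1))
  if (!is.na(onset) && truth$volume_silent) {
    ce[-1L] <- pmin(ce[-1L], base_ce * 1.04) # ratio stays < 1.05
  }
  volumes <- data.frame(
    patient_id = patient$patient_id, scan_date = all_dates,
    ce_tumor_cm3 = ce,
    ne_tumor_cm3 = ce * stats::runif(length(ce), 0.8, 2.0),
    edema_cm3 = ce * stats::runif(length(ce), 2.0, 6.0),
    stringsAsFactors = FALSE
  )
  gold <- data.frame(
    patient_id = patient$patient_id, scan_date = all_dates,
    gold_ratio = ce / base_ce,
    gold_flag = ce / base_ce >= 1.05,
    stringsAsFactors = FALSE
  )
  list(volumes = volumes, gold = gold)
}

#' Simulate a synthetic EHR cohort with known ground truth
#'
#' Draws the full four-table cohort bundle plus the ground truth that
#' produced it. A pure function of the configuration (including its seed):
#' identical configs give byte-identical bundles.
#'
#' @param config A [cohort_config()].
#' @return A list with `cohort` (a [gbm_cohort()]), `truth` (data.frame of
#'   per-patient true progression parameters and modality flags),
#'   `report_gold`, `scan_gold` (per-record gold labels) and `config`.
#' @examples
#' sim <- simulate_cohort(cohort_config(n_patients = 5, seed = 42))
#' sim$cohort
#' @export
simulate_cohort <- function(config = cohort_config()) {
  config <- validate_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  patients <- vector("list", n)
  truth <- vector("list", n)
  rx <- list()
  reports <- list()
  report_gold <- list()
  volumes <- list()
  scan_gold <- list()
  era_start <- as.Date("2004-01-01")
  for (i in seq_len(n)) {
    pid <- sprintf("P%03d", i)
    diagnosis <- era_start + sample.int(19 * 365, 1L)
    surgery <- diagnosis + sample(3:21, 1L)
    crt_end <- surgery + sample(21:35, 1L) + 42L # CRT start lag + 6 weeks
    progressed <- stats::runif(1) < config$p_progress
    pfs <- if (progressed) sample_truth_pfs(config, 1L) else NA_real_
    clinical_date <- if (progressed) {
      crt_end + months_to_days(pfs)
    } else {
      as.Date(NA)
    }
    trunc_lead <- function(mean, sd) {
      if (!progressed) {
        return(NA_real_)
      }
      min(max(stats::rnorm(1, mean, sd), 0), pfs)
    }
    report_lead <- trunc_lead(
      config$report_lead_mean_months, config$report_lead_sd_months
    )
    volume_lead <- trunc_lead(
      config$volume_lead_mean_months, config$volume_lead_sd_months
    )
    tr <- data.frame(
      patient_id = pid, progressed = progressed,
      clinical_pfs_months = pfs, clinical_date = clinical_date,
      report_onset_date = if (progressed) {
        clinical_date - months_to_days(report_lead)
      } else {
        as.Date(NA)
      },
      volume_onset_date = if (progressed) {
        clinical_date - months_to_days(volume_lead)
      } else {
        as.Date(NA)
      },
      steroid_lag_months = if (progressed) {
        stats::rnorm(
          1, config$steroid_lag_mean_months, config$steroid_lag_sd_months
        )
      } else {
        NA_real_
      },
      steroid_missing = progressed &&
        stats::runif(1) < config$frac_steroid_missing,
      report_silent = progressed &&
        stats::runif(1) < config$frac_report_silent,
      volume_silent = progressed &&
        stats::runif(1) < config$frac_volume_silent,
      stringsAsFactors = FALSE
    )
    patient <- data.frame(
      patient_id = pid, diagnosis_date = diagnosis, surgery_date = surgery,
      crt_end_date = crt_end, clinical_progression_date = clinical_date,
      treatment_year = as.integer(format(diagnosis, "%Y")),
      followup_complete = TRUE, stringsAsFactors = FALSE
    )
    horizon <- if (progressed) {
      min(
        max(pfs + config$followup_extra_months, config$followup_min_months),
        config$followup_max_months
      )
    } else {
      config$followup_min_months
    }
    visits <- surveillance_schedule(crt_end, horizon, config)
    rep_out <- generate_reports(patient, tr, config, visits)
    vol_out <- generate_volumes(patient, tr, config, visits)
    patients[[i]] <- patient
    truth[[i]] <- tr
    rx[[i]] <- generate_prescriptions(patient, tr, config)
    reports[[i]] <- rep_out$reports
    report_gold[[i]] <- rep_out$gold
    volumes[[i]] <- vol_out$volumes
    scan_gold[[i]] <- vol_out$gold
  }
  cohort <- gbm_cohort(
    do.call(rbind, patients), do.call(rbind, rx),
    do.call(rbind, reports), do.call(rbind, volumes)
  )
  list(
    cohort = cohort, truth = do.call(rbind, truth),
    report_gold = do.call(rbind, report_gold),
    scan_gold = do.call(rbind, scan_gold), config = config
  )
}
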