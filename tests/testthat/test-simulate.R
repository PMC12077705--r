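test_that("truth PFS draws follow the configured lognormal", {
  cfg <- cohort_config(seed = 1)
  # degenerate sigma: every draw is exp(mu)
  set.seed(1)
  flat <- sample_truth_pfs(
    cohort_config(truth_pfs_log_sigma = 0), n = 20
  )
  expect_equal(flat, rep(exp(cfg$truth_pfs_log_mu), 20))
  # determinism under a fixed seed
  set.seed(99)
  a <- sample_truth_pfs(cfg, 50)
  set.seed(99)
  b <- sample_truth_pfs(cfg, 50)
  expect_identical(a, b)
  # large-sample median near the closed-form lognormal median
  set.seed(7)
  draws <- sample_truth_pfs(cfg, 1e5)
  expect_lt(abs(median(draws) - exp(cfg$truth_pfs_log_mu)), 0.3)
  expect_error(cohort_config(truth_pfs_log_sigma = -1))
})

test_that("generator calibration matches closed-form moments at large n", {
  cfg <- cohort_config(seed = 2)
  mu <- cfg$truth_pfs_log_mu
  s <- cfg$truth_pfs_log_sigma
  set.seed(2)
  draws <- sample_truth_pfs(cfg, 5000)
  m <- exp(mu + s^2 / 2)
  med <- exp(mu)
  sd_cf <- m * sqrt(exp(s^2) - 1)
  expect_lt(abs(mean(draws) - m) / m, 0.1)
  expect_lt(abs(median(draws) - med) / med, 0.1)
  expect_lt(abs(sd(draws) - sd_cf) / sd_cf, 0.1)
})

test_that("progression-triggered tapers are laid out from the truth date", {
  cfg <- cohort_config(
    steroid_lag_mean_months = 0, steroid_lag_sd_months = 0,
    taper_doses_mg = c(8, 4, 2), taper_spacing_days = 10L
  )
  patient <- make_patient(crt_end = d0 + 90)
  truth <- data.frame(
    patient_id = "P1", clinical_date = d0 + 300, steroid_lag_months = 0,
    steroid_missing = FALSE
  )
  rx <- generate_prescriptions(patient, truth, cfg)
  taper <- rx[rx$drug_name == "dexamethasone" &
    rx$order_date >= d0 + 300, ]
  expect_identical(taper$order_date[taper$dose_mg == 8], d0 + 300)
  expect_identical(taper$order_date[taper$dose_mg == 2], d0 + 320)

  # steroid-missing patients get no post-CRT dexamethasone
  truth$steroid_missing <- TRUE
  rx <- generate_prescriptions(patient, truth, cfg)
  dex <- filter_post_crt(select_dexamethasone(rx), patient$crt_end_date)
  expect_identical(nrow(dex), 0L)

  # the post-surgical course exists and predates CRT end + 1 month
  post_surg <- rx[rx$drug_name == "dexamethasone", ]
  expect_gte(nrow(post_surg), 1L)
  expect_true(all(post_surg$order_date < patient$crt_end_date + 31))
})

test_that("surveillance reports are template-pure with 2-4 month spacing", {
  sim <- simulate_cohort(cohort_config(n_patients = 10, seed = 17))
  lex <- default_lexicon()
  brain <- sim$cohort$reports[grepl("MRI", sim$cohort$reports$document_type), ]
  gold <- sim$report_gold
  expect_identical(nrow(brain), nrow(gold))
  for (i in seq_len(min(40, nrow(brain)))) {
    m <- extract_matches(brain$text[i], lex)
    unmod_prog <- sum(m$base_category == "progression" & !m$negated &
      !m$historical & !m$surgical)
    stab <- sum(m$base_category == "stability")
    if (gold$gold_status[i] == "stability") {
      expect_identical(unmod_prog, 0L)
    } else {
      expect_gt(unmod_prog, stab)
    }
  }
  # consecutive surveillance gaps stay inside the 2-4 month window
  for (pid in unique(gold$patient_id)) {
    dates <- sort(gold$report_date[gold$patient_id == pid])
    gaps <- months_between(dates[-length(dates)], dates[-1])
    expect_true(all(gaps >= 2 & gaps <= 4))
  }
})

test_that("volume trajectories honour silence clamps and growth closed form", {
  # volume-silent progressors never reach a 1.05 ratio
  sim <- simulate_cohort(cohort_config(n_patients = 30, seed = 23,
    frac_volume_silent = 1, p_progress = 1))
  expect_true(all(sim$scan_gold$gold_ratio < 1.05))
  # baselines are positive for every patient
  expect_true(all(sim$scan_gold$gold_ratio[!duplicated(
    sim$scan_gold$patient_id)] > 0))

  # noise off, 10%/month growth, scan one month after onset: ratio 1.10
  cfg <- cohort_config(ce_noise_cv = 0, ce_growth_rate_per_month = 0.10)
  patient <- make_patient(surgery = d0, crt_end = d0 + 70)
  onset <- d0 + 70 + round(6 * 30.4375)
  truth <- data.frame(
    patient_id = "P1", volume_onset_date = onset, volume_silent = FALSE
  )
  dates <- c(onset, onset + round(30.4375))
  vols <- generate_volumes(patient, truth, cfg, dates)
  # one month of 10%/month growth: ratio ~1.10, comfortably over 1.05
  expect_equal(vols$gold$gold_ratio, c(1, 1, 1.1), tolerance = 5e-3)
  expect_identical(vols$gold$gold_flag, c(FALSE, FALSE, TRUE))
})

test_that("cohort generation is deterministic and internally consistent", {
  cfg <- cohort_config(n_patients = 8, seed = 31)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth, b$truth)
  # serialised form is byte-identical too
  da <- withr::local_tempdir()
  db <- withr::local_tempdir()
  write_cohort(a$cohort, da)
  write_cohort(b$cohort, db)
  for (f in list.files(da)) {
    expect_identical(readLines(file.path(da, f)),
      readLines(file.path(db, f)))
  }
  # every patient row is emitted and referenced records exist
  expect_identical(nrow(a$cohort$patients), 8L)
  ids <- a$cohort$patients$patient_id
  expect_true(all(a$report_gold$patient_id %in% ids))
  expect_true(all(a$scan_gold$patient_id %in% ids))
  # the bundle passes eligibility for the full cohort
  expect_setequal(apply_eligibility(a$cohort), ids)
  expect_error(cohort_config(n_patients = 0))
})
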