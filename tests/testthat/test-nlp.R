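lex <- default_lexicon()

test_that("text normalisation collapses whitespace and is idempotent", {
  expect_identical(normalize_text("stable.\n\n\nNo  change"),
    "stable.\nNo change")
  x <- normalize_text("A  report.\r\n\r\n  With   spacing. ")
  expect_identical(normalize_text(x), x)
  expect_identical(normalize_text(""), "")
})

test_that("term matching attributes ConText-style modifiers within the sentence", {
  m <- extract_matches(
    "There is increased enhancement in the left frontal lobe.", lex
  )
  expect_gte(nrow(m), 1)
  expect_true(all(m$base_category == "progression"))
  expect_false(any(m$negated | m$historical | m$surgical | m$hypothetical))

  m <- extract_matches("No evidence of tumor progression.", lex)
  expect_identical(m$base_category, "progression")
  expect_true(all(m$negated))

  m <- extract_matches(
    "Expected postoperative changes in the resection cavity with enhancement.",
    lex
  )
  expect_true(any(m$base_category == "progression" & m$surgical))

  # spans are 0-based half-open into the normalised document
  m <- extract_matches("Stable exam.", lex)
  expect_identical(substr("Stable exam.", m$start + 1, m$end), "Stable")
})

test_that("terminator conjunctions cut trigger scope", {
  m <- extract_matches("No hemorrhage, but increased enhancement.", lex)
  inc <- m[m$surface_text == "increased", ]
  expect_false(inc$negated) # "but" terminates the forward negation scope
})

test_that("re-categorisation follows the precedence rule table", {
  # [prog plain, prog+NEGATED, stab plain] -> (1, 2, 0)
  m <- rbind(
    make_match("progression"),
    make_match("progression", negated = TRUE),
    make_match("stability")
  )
  expect_identical(recategorize(m),
    c(progression = 1L, stability = 2L, surgical = 0L))
  # [prog+SURGICAL, prog+SURGICAL+NEGATED] -> (0, 1, 1): negation outranks
  m <- rbind(
    make_match("progression", surgical = TRUE),
    make_match("progression", surgical = TRUE, negated = TRUE)
  )
  expect_identical(recategorize(m),
    c(progression = 0L, stability = 1L, surgical = 1L))
  expect_identical(recategorize(make_match()[0, ]),
    c(progression = 0L, stability = 0L, surgical = 0L))
})

test_that("re-categorisation agrees with an exhaustive rule-table oracle", {
  # independent oracle: spell the precedence table out per modifier subset
  oracle <- function(category, neg, hist, hypo, fam, surg) {
    if (category == "progression") {
      if (neg) return("stability")
      if (hist) return("stability")
      if (surg) return("surgical")
      if (hypo || fam) return("dropped")
      return("progression")
    }
    if (neg) return("dropped")
    if (hist || surg) return("stability")
    if (hypo || fam) return("dropped")
    "stability"
  }
  grid <- expand.grid(
    category = c("progression", "stability"),
    neg = c(FALSE, TRUE), hist = c(FALSE, TRUE), hypo = c(FALSE, TRUE),
    fam = c(FALSE, TRUE), surg = c(FALSE, TRUE), stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    counts <- recategorize(make_match(g$category, g$neg, g$hist, g$hypo,
      g$fam, g$surg))
    expected <- oracle(g$category, g$neg, g$hist, g$hypo, g$fam, g$surg)
    got <- if (sum(counts) == 0L) "dropped" else names(counts)[counts == 1L]
    expect_identical(got, expected,
      label = paste(unlist(g), collapse = "/"))
  }
})

test_that("document status requires strictly more progression than stability terms", {
  expect_identical(
    determine_status(c(progression = 3, stability = 1, surgical = 0)),
    "progression"
  )
  # tie: surgical weight joins the stability side
  expect_identical(
    determine_status(c(progression = 2, stability = 2, surgical = 1)),
    "no_progression"
  )
  expect_identical(
    determine_status(c(progression = 0, stability = 0, surgical = 0)),
    "no_progression"
  )
  expect_error(
    determine_status(c(progression = -1, stability = 0, surgical = 0)),
    "negative"
  )
})

test_that("document status equals a brute-force recount of the audit trail", {
  sim <- simulate_cohort(cohort_config(n_patients = 8, seed = 21))
  reports <- sim$cohort$reports
  reports <- reports[grepl("MRI", reports$document_type), ]
  for (i in seq_len(min(nrow(reports), 60))) {
    a <- assess_document(reports$text[i], lex)
    m <- a$matches
    # recount categories row by row, straight from the audit trail
    tally <- c(progression = 0L, stability = 0L, surgical = 0L)
    for (j in seq_len(nrow(m))) {
      r <- m[j, ]
      if (r$base_category == "progression") {
        if (r$negated || r$historical) {
          tally["stability"] <- tally["stability"] + 1L
        } else if (r$surgical) {
          tally["surgical"] <- tally["surgical"] + 1L
        } else if (!r$hypothetical && !r$family) {
          tally["progression"] <- tally["progression"] + 1L
        }
      } else if (!r$negated && !(r$hypothetical || r$family) ||
        (!r$negated && (r$historical || r$surgical))) {
        tally["stability"] <- tally["stability"] + 1L
      }
    }
    expect_identical(a$counts, tally)
    expect_identical(
      a$status,
      if (tally[["progression"]] > tally[["stability"]]) {
        "progression"
      } else {
        "no_progression"
      }
    )
  }
})

test_that("brain-MRI report selection filters by type and radiotherapy end date", {
  rt_end <- d0 + 90
  reports <- rbind(
    make_report(date = rt_end + 30, type = "MRI BRAIN-Perfusion (IP)"),
    make_report(date = rt_end + 40, type = "DX Chest - PA + Lat"),
    make_report(date = rt_end - 10, type = "MRI BRAIN-Perfusion (IP)"),
    make_report(date = rt_end + 50, type = "IP Perfusion")
  )
  kept <- select_brain_mri_reports(reports, rt_end)
  expect_identical(as.integer(kept$report_date - rt_end), c(30L, 50L))
})

test_that("report endpoint takes the earliest progression-status document", {
  patient <- make_patient(crt_end = d0)
  prog_text <- "New areas of abnormal enhancement consistent with tumor progression."
  stab_text <- "The examination is stable compared with the prior study."
  reports <- rbind(
    make_report(date = d0 + 61, text = stab_text),
    make_report(date = d0 + 152, text = prog_text),
    make_report(date = d0 + 243, text = prog_text)
  )
  res <- nlp_pfs(patient, reports, lex)
  expect_true(res$progressed)
  expect_identical(res$progression_date, d0 + 152)

  res <- nlp_pfs(patient, reports[1, , drop = FALSE], lex)
  expect_false(res$progressed)

  res <- nlp_pfs(patient, make_report(date = d0 + 30, text = prog_text), lex)
  expect_identical(res$progression_date, d0 + 30)
})

test_that("appending an unmodified progression sentence never flips progression off", {
  docs <- c(
    "There is increased enhancement in the left frontal lobe.",
    "The examination is stable. Interval growth of the enhancing mass. Worsening mass effect.",
    "No evidence of tumor progression. Enlarging enhancing mass."
  )
  for (doc in docs) {
    before <- assess_document(doc, lex)$status
    after <- assess_document(
      paste(doc, "Interval growth of the enhancing mass."), lex
    )$status
    if (before == "progression") expect_identical(after, "progression")
  }
  # and the pipeline is deterministic
  expect_identical(assess_document(docs[2], lex)$counts,
    assess_document(docs[2], lex)$counts)
})

test_that("lexicons survive a YAML round trip", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_lexicon(lex, path)
  back <- read_lexicon(path)
  expect_identical(back$progression_stems, lex$progression_stems)
  expect_identical(back$negation_triggers, lex$negation_triggers)
  txt <- "No evidence of tumor progression. Enlarging enhancing mass."
  expect_identical(assess_document(txt, back)$counts,
    assess_document(txt, lex)$counts)
})
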