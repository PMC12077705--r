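#' Normalise report text
#'
#' Standardises paragraph formatting and spacing before analysis: runs of
#' spaces/tabs collapse to one space, runs of blank lines collapse to a
#' single line break, and surrounding whitespace on each line is trimmed.
#' Idempotent: `normalize_text(normalize_text(x)) == normalize_text(x)`.
#'
#' @param text Character vector of raw report text.
#' @return Normalised character vector.
#' @export
normalize_text <- function(text) {
  text <- gsub("\r\n?", "\n", text)
  text <- gsub("[ \t]+", " ", text)
  text <- gsub(" ?\n ?", "\n", text)
  text <- gsub("\n{2,}", "\n", text)
  trimws(text)
}

# Sentence segmentation on normalised text: boundaries after [.!?] followed
# by whitespace, and at line breaks. Returns 1-based inclusive character
# intervals into `text` plus the sentence strings.
segment_sentences <- function(text) {
  n <- nchar(text)
  if (n == 0L) {
    return(data.frame(start = integer(), end = integer(),
      text = character()))
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  boundary <- logical(n) # position i TRUE => sentence ends at i
  for (i in seq_len(n)) {
    if (chars[i] == "\n") {
      boundary[i] <- TRUE
    } else if (chars[i] %in% c(".", "!", "?") &&
      (i == n || chars[i + 1L] %in% c(" ", "\n"))) {
      boundary[i] <- TRUE
    }
  }
  boundary[n] <- TRUE
  ends <- which(boundary)
  starts <- c(1L, ends[-length(ends)] + 1L)
  keep <- mapply(function(s, e) {
    nzchar(trimws(substr(text, s, e)))
  }, starts, ends)
  data.frame(
    start = starts[keep], end = ends[keep],
    text = substring(text, starts[keep], ends[keep]),
    stringsAsFactors = FALSE
  )
}

# Compile a trigger set into one alternation regex per direction
# (longest phrase first, so multiword triggers win at a shared prefix).
compile_triggers <- function(triggers) {
  out <- list()
  for (dir in unique(triggers$direction)) {
    phr <- triggers$phrase[triggers$direction == dir]
    phr <- phr[order(-nchar(phr))]
    esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", phr)
    out[[dir]] <- paste0("\\b(?:", paste(esc, collapse = "|"), ")\\b")
  }
  out
}

# Locate trigger occurrences of a compiled trigger set in a lower-cased
# sentence; returns start/end (1-based, inclusive) and direction per hit.
locate_triggers <- function(sentence_lc, compiled) {
  hits <- list()
  for (dir in names(compiled)) {
    m <- gregexpr(compiled[[dir]], sentence_lc, perl = TRUE)[[1L]]
    if (m[1L] != -1L) {
      hits[[length(hits) + 1L]] <- list(
        start = as.integer(m),
        end = as.integer(m) + attr(m, "match.length") - 1L,
        direction = rep(dir, length(m))
      )
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), end = integer(),
      direction = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    start = unlist(lapply(hits, `[[`, "start")),
    end = unlist(lapply(hits, `[[`, "end")),
    direction = unlist(lapply(hits, `[[`, "direction")),
    stringsAsFactors = FALSE
  )
}

# Scope interval of a trigger occurrence within a sentence, bounded by
# terminator conjunctions; returns c(lo, hi) character positions.
trigger_scope <- function(hit, term_pos, sentence_len) {
  after <- term_pos[term_pos > hit$end]
  before <- term_pos[term_pos < hit$start]
  hi <- if (length(after)) min(after) - 1L else sentence_len
  lo <- if (length(before)) max(before) + 1L else 1L
  switch(hit$direction,
    forward = c(hit$end + 1L, hi),
    backward = c(lo, hit$start - 1L),
    bidirectional = c(lo, hi)
  )
}

#' Extract lexicon term matches with context modifiers
#'
#' Sentence-segments normalised text, matches tokens whose lower-cased form
#' begins with a progression or stability stem, and assigns each match the
#' ConText-style modifiers (`NEGATED`, `HISTORICAL`, `HYPOTHETICAL`,
#' `FAMILY`, `SURGICAL`) of every trigger whose directional, sentence-bounded
#' scope covers it. Trigger scopes are cut at terminator conjunctions
#' (`but`, `however`, ...).
#'
#' @param text A single report text (normalised internally).
#' @param lexicon A `term_lexicon`, e.g. [default_lexicon()].
#' @return A data.frame with one row per match: `surface_text`,
#'   `matched_stem`, `base_category` (`"progression"`/`"stability"`),
#'   logical modifier columns `negated`, `historical`, `hypothetical`,
#'   `family`, `surgical`, plus `sentence_index` and the 0-based half-open
#'   span (`start`, `end`) in the normalised document.
#' @export
extract_matches <- function(text, lexicon) {
  lexicon <- validate_lexicon(lexicon)
  text <- normalize_text(text)
  sentences <- segment_sentences(text)
  empty <- data.frame(
    surface_text = character(), matched_stem = character(),
    base_category = character(), negated = logical(),
    historical = logical(), hypothetical = logical(), family = logical(),
    surgical = logical(), sentence_index = integer(), start = integer(),
    end = integer(), stringsAsFactors = FALSE
  )
  if (!nrow(sentences)) {
    return(empty)
  }
  mod_sets <- c(
    negated = "negation_triggers", historical = "historical_triggers",
    hypothetical = "hypothetical_triggers", family = "family_triggers",
    surgical = "surgical_triggers"
  )
  compiled <- lapply(mod_sets, function(set) {
    compile_triggers(lexicon[[set]])
  })
  term_pat <- paste0("\\b(?:", paste(lexicon$terminators, collapse = "|"),
    ")\\b")
  rows <- list()
  for (si in seq_len(nrow(sentences))) {
    sent <- sentences$text[si]
    sent_lc <- tolower(sent)
    offset <- sentences$start[si] - 1L
    tok <- gregexpr("[a-z']+", sent_lc, perl = TRUE)[[1L]]
    if (tok[1L] == -1L) next
    tok_start <- as.integer(tok)
    tok_end <- tok_start + attr(tok, "match.length") - 1L
    tokens <- substring(sent_lc, tok_start, tok_end)
    is_prog <- vapply(tokens, function(t) {
      any(startsWith(t, lexicon$progression_stems))
    }, logical(1), USE.NAMES = FALSE)
    is_stab <- !is_prog & vapply(tokens, function(t) {
      any(startsWith(t, lexicon$stability_stems))
    }, logical(1), USE.NAMES = FALSE)
    hit_idx <- which(is_prog | is_stab)
    if (!length(hit_idx)) next
    tm <- gregexpr(term_pat, sent_lc, perl = TRUE)[[1L]]
    term_pos <- if (tm[1L] == -1L) integer() else as.integer(tm)
    mods <- matrix(FALSE, length(hit_idx), length(mod_sets),
      dimnames = list(NULL, names(mod_sets)))
    for (mod in names(mod_sets)) {
      hits <- locate_triggers(sent_lc, compiled[[mod]])
      for (h in seq_len(nrow(hits))) {
        sc <- trigger_scope(hits[h, ], term_pos, nchar(sent))
        covered <- tok_start[hit_idx] >= sc[1L] & tok_end[hit_idx] <= sc[2L]
        mods[, mod] <- mods[, mod] | covered
      }
    }
    stem_of <- vapply(hit_idx, function(ti) {
      stems <- if (is_prog[ti]) {
        lexicon$progression_stems
      } else {
        lexicon$stability_stems
      }
      stems[startsWith(tokens[ti], stems)][1L]
    }, character(1))
    rows[[length(rows) + 1L]] <- data.frame(
      surface_text = substring(sent, tok_start[hit_idx], tok_end[hit_idx]),
      matched_stem = stem_of,
      base_category = ifelse(is_prog[hit_idx], "progression", "stability"),
      negated = mods[, "negated"], historical = mods[, "historical"],
      hypothetical = mods[, "hypothetical"], family = mods[, "family"],
      surgical = mods[, "surgical"], sentence_index = si,
      start = offset + tok_start[hit_idx] - 1L, # 0-based half-open span
      end = offset + tok_end[hit_idx],
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(empty)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Re-categorise context-modified matches into document counts
#'
#' Applies the modifier rule table with precedence
#' `NEGATED > HISTORICAL > SURGICAL > HYPOTHETICAL/FAMILY`:
#' * progression, unmodified -> progression count;
#' * progression + NEGATED or HISTORICAL -> stability count;
#' * progression + SURGICAL (no negation/history) -> surgical count;
#' * progression + only HYPOTHETICAL/FAMILY -> dropped;
#' * stability, unmodified (or historical/surgical) -> stability count;
#' * stability + NEGATED, or only hypothetical/family context -> dropped.
#'
#' @param matches Output of [extract_matches()].
#' @return Named integer vector `c(progression, stability, surgical)`.
#' @export
recategorize <- function(matches) {
  prog <- matches$base_category == "progression"
  bucket <- ifelse(prog,
    ifelse(matches$negated | matches$historical, "stability",
      ifelse(matches$surgical, "surgical",
        ifelse(matches$hypothetical | matches$family, NA, "progression")
      )
    ),
    ifelse(matches$negated, NA,
      ifelse(matches$historical | matches$surgical, "stability",
        ifelse(matches$hypothetical | matches$family, NA, "stability")
      )
    )
  )
  c(
    progression = sum(bucket %in% "progression"),
    stability = sum(bucket %in% "stability"),
    surgical = sum(bucket %in% "surgical")
  )
}

#' Document-level progression status from category counts
#'
#' A document indicates progression when unmodified progression terms
#' strictly outnumber stability terms (one-to-one weighting). On a tie the
#' surgical-context count joins the stability side — surgical-cavity change
#' reads as pseudoprogression, i.e. stability — so ties always yield
#' `no_progression`, as do documents with no matched terms at all.
#'
#' @param counts Named vector from [recategorize()] (elements `progression`,
#'   `stability`, `surgical`).
#' @return `"progression"` or `"no_progression"`.
#' @export
determine_status <- function(counts) {
  p <- counts[["progression"]]
  s <- counts[["stability"]]
  g <- counts[["surgical"]]
  if (any(c(p, s, g) < 0)) stop("negative category count", call. = FALSE)
  if (p > s) "progression" else "no_progression"
}

#' Assess one radiology report
#'
#' Runs the full document pipeline (normalise, match, attribute context,
#' re-categorise, decide) and returns an auditable assessment.
#'
#' @param text Report free text.
#' @param lexicon A `term_lexicon`.
#' @param report_date Optional report date carried into the assessment.
#' @return A list of class `document_assessment` with `report_date`,
#'   `counts`, `status` and the `matches` audit table.
#' @export
assess_document <- function(text, lexicon = default_lexicon(),
                            report_date = NULL) {
  matches <- extract_matches(text, lexicon)
  counts <- recategorize(matches)
  structure(
    list(
      report_date = report_date, counts = counts,
      status = determine_status(counts), matches = matches
    ),
    class = "document_assessment"
  )
}

#' @export
print.document_assessment <- function(x, ...) {
  cat(sprintf(
    "Report assessment%s: %s (progression %d, stability %d, surgical %d)\n",
    if (is.null(x$report_date)) "" else paste0(" ", format(x$report_date)),
    x$status, x$counts[["progression"]], x$counts[["stability"]],
    x$counts[["surgical"]]
  ))
  invisible(x)
}

#' Select post-treatment brain-MRI reports
#'
#' Keeps reports whose document type matches a brain-MRI pattern and whose
#' date falls strictly after the end of the patient's radiotherapy course
#' (earlier documents reflect the pre-treatment or on-treatment period).
#'
#' @param reports Report table rows for one patient.
#' @param rt_end_date The patient's last day of radiotherapy.
#' @param patterns Case-insensitive regular expressions recognising
#'   brain-MRI document types; defaults to [brain_mri_patterns()].
#' @return The matching subset of `reports`.
#' @export
select_brain_mri_reports <- function(reports, rt_end_date,
                                     patterns = brain_mri_patterns()) {
  if (!nrow(reports)) {
    return(reports)
  }
  type_lc <- tolower(reports$document_type)
  is_brain <- Reduce(`|`, lapply(patterns, grepl, x = type_lc))
  keep <- is_brain & !is.na(reports$report_date) &
    reports$report_date > as_date_strict(rt_end_date, "rt_end_date")
  reports[keep, , drop = FALSE]
}

#' Report-derived progression endpoint for one patient
#'
#' Filters to post-radiotherapy brain-MRI reports, assesses each document,
#' and calls progression at the date of the earliest report whose status is
#' `progression`. The per-report assessments are attached as evidence so the
#' determination can be audited against the source text.
#'
#' @param patient One row of the patient table.
#' @param reports The patient's report records.
#' @param lexicon A `term_lexicon`.
#' @param patterns Document-type patterns for [select_brain_mri_reports()].
#' @return A one-row endpoint data.frame (see [derive_pfs()]).
#' @export
nlp_pfs <- function(patient, reports, lexicon = default_lexicon(),
                    patterns = brain_mri_patterns()) {
  reports <- select_brain_mri_reports(reports, patient$crt_end_date, patterns)
  reports <- reports[order(reports$report_date), , drop = FALSE]
  assessments <- lapply(seq_len(nrow(reports)), function(i) {
    assess_document(reports$text[i], lexicon, reports$report_date[i])
  })
  statuses <- vapply(assessments, `[[`, "", "status")
  hit <- which(statuses == "progression")
  if (length(hit)) {
    endpoint_row(patient, "nlp", TRUE, reports$report_date[hit[1L]],
      evidence = assessments
    )
  } else {
    endpoint_row(patient, "nlp", FALSE, evidence = assessments)
  }
}
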