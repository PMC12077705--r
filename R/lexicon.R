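#' Default progression/stability term lexicon
#'
#' The term lists and context triggers driving the rule-based report
#' analysis. Progression and stability entries are *stems*, matched by
#' prefix against lower-cased tokens (so `enhanc` matches "enhancement" and
#' "enhancing"). Context triggers are phrases with a declared direction
#' (`forward`, `backward`, `bidirectional`); their scope is bounded by the
#' sentence and by terminator conjunctions. The negation list is expanded
#' with no-change phrasing common in surveillance radiology, and a custom
#' surgical trigger set separates post-operative cavity changes (a frequent
#' pseudoprogression mimic) from true progression language.
#'
#' This default is a reconstruction from RANO response-assessment language
#' and term-frequency patterns typical of brain-MRI surveillance reports; it
#' is intentionally editable ([write_lexicon()] / [read_lexicon()]) because
#' report phrasing is institution-specific and results depend on it.
#'
#' @return A list of class `term_lexicon` with elements `progression_stems`,
#'   `stability_stems`, `negation_triggers`, `historical_triggers`,
#'   `hypothetical_triggers`, `family_triggers`, `surgical_triggers` (each
#'   trigger set a data.frame of `phrase`, `direction`) and `terminators`.
#' @export
default_lexicon <- function() {
  trig <- function(phrases, direction) {
    data.frame(phrase = phrases, direction = direction,
      stringsAsFactors = FALSE)
  }
  lex <- list(
    progression_stems = c(
      "progress", "recurr", "increas", "enlarg", "grow", "worsen",
      "expand", "enhanc", "abnormal"
    ),
    stability_stems = c(
      "stable", "stabil", "unchanged", "decreas", "improv", "resolv",
      "reduc", "shrink", "diminish"
    ),
    negation_triggers = rbind(
      trig(c(
        "no", "not", "without", "no evidence of", "negative for",
        "absence of", "free of", "resolution of", "rules out", "no new",
        "no interval", "no significant", "no appreciable", "no definite"
      ), "forward"),
      trig(c("is ruled out", "not identified", "not seen", "unlikely"),
        "backward")
    ),
    historical_triggers = rbind(
      trig(c("history of", "prior", "previous", "previously", "known"),
        "forward"),
      trig("in the past", "backward")
    ),
    hypothetical_triggers = trig(c(
      "if", "may represent", "could represent", "question of",
      "questionable", "cannot exclude", "possible", "possibly"
    ), "forward"),
    family_triggers = trig(
      c("family history of", "mother", "father", "sibling"), "forward"
    ),
    surgical_triggers = rbind(
      trig(c(
        "postoperative", "post-operative", "postsurgical", "post-surgical"
      ), "forward"),
      trig(c(
        "resection cavity", "surgical cavity", "surgical bed", "craniotomy",
        "operative site", "resection site"
      ), "bidirectional")
    ),
    terminators = c(
      "but", "however", "although", "though", "whereas", "aside"
    )
  )
  validate_lexicon(lex)
}

validate_lexicon <- function(lex) {
  if (inherits(lex, "term_lexicon")) {
    return(lex) # already validated/normalised
  }
  needed <- c(
    "progression_stems", "stability_stems", "negation_triggers",
    "historical_triggers", "hypothetical_triggers", "family_triggers",
    "surgical_triggers", "terminators"
  )
  miss <- setdiff(needed, names(lex))
  if (length(miss)) {
    stop("lexicon is missing element(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  lex$progression_stems <- tolower(lex$progression_stems)
  lex$stability_stems <- tolower(lex$stability_stems)
  if (length(intersect(lex$progression_stems, lex$stability_stems))) {
    stop("progression and stability stem sets must be disjoint",
      call. = FALSE
    )
  }
  for (set in grep("_triggers$", needed, value = TRUE)) {
    tr <- as.data.frame(lex[[set]])
    if (!all(c("phrase", "direction") %in% names(tr))) {
      stop(set, " must have columns 'phrase' and 'direction'", call. = FALSE)
    }
    tr$phrase <- tolower(tr$phrase)
    if (!all(tr$direction %in% c("forward", "backward", "bidirectional"))) {
      stop(set, ": direction must be forward, backward or bidirectional",
        call. = FALSE
      )
    }
    lex[[set]] <- tr
  }
  lex$terminators <- tolower(lex$terminators)
  class(lex) <- "term_lexicon"
  lex
}

#' Read or write a term lexicon as YAML
#'
#' @param path YAML file path.
#' @param lexicon A `term_lexicon` (see [default_lexicon()]).
#' @return `read_lexicon()` returns a validated `term_lexicon`;
#'   `write_lexicon()` returns `path` invisibly.
#' @export
read_lexicon <- function(path) {
  raw <- yaml::read_yaml(path)
  for (set in grep("_triggers$", names(raw), value = TRUE)) {
    raw[[set]] <- data.frame(
      phrase = vapply(raw[[set]], `[[`, "", "phrase"),
      direction = vapply(raw[[set]], `[[`, "", "direction"),
      stringsAsFactors = FALSE
    )
  }
  validate_lexicon(raw)
}

#' @rdname read_lexicon
#' @export
write_lexicon <- function(lexicon, path) {
  lex <- unclass(validate_lexicon(lexicon))
  for (set in grep("_triggers$", names(lex), value = TRUE)) {
    tr <- lex[[set]]
    lex[[set]] <- lapply(seq_len(nrow(tr)), function(i) {
      list(phrase = tr$phrase[i], direction = tr$direction[i])
    })
  }
  yaml::write_yaml(lex, path)
  invisible(path)
}

#' Default brain-MRI document-type patterns
#'
#' Case-insensitive regular expressions used to recognise brain-MRI report
#' types (e.g. "MRI BRAIN-Perfusion (IP)", "IP Perfusion"); chest films, CT
#' and other modalities are dropped by [select_brain_mri_reports()].
#'
#' @return Character vector of regular expressions.
#' @export
brain_mri_patterns <- function() {
  c("mri[ -]*brain", "brain[ -]*mri", "ip perfusion", "mr brain")
}
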