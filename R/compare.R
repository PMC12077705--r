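#' Aggregate long endpoint results into a patient-by-method table
#'
#' @param results Long results data.frame from [derive_pfs()] (`$results`).
#' @return Wide data.frame with one row per patient and one `pfs_months`
#'   column per method; `NA` where a method found no progression or was not
#'   evaluable. Errors on duplicate (patient, method) rows.
#' @export
aggregate_pfs <- function(results) {
  key <- paste(results$patient_id, results$method, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (patient, method) result rows", call. = FALSE)
  }
  ids <- unique(results$patient_id)
  methods <- unique(results$method)
  wide <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (m in methods) {
    sub <- results[results$method == m, ]
    wide[[m]] <- sub$pfs_months[match(ids, sub$patient_id)]
  }
  wide
}

#' Descriptive statistics for one method
#'
#' Table-style summary: the progression percentage is taken over the full
#' cohort (rounded to the nearest integer), while the PFS moments (months)
#' are computed over progressed patients only.
#'
#' @param results Long results rows (any subset of methods).
#' @param cohort_n Cohort size for the percentage denominator.
#' @param method Optional single method to summarise; default summarises
#'   each method present.
#' @return Data.frame with one row per method: `method`, `n_progressed`,
#'   `percent_progressed`, `mean_pfs`, `sd_pfs`, `median_pfs`, `min_pfs`,
#'   `max_pfs`.
#' @export
summarize_methods <- function(results, cohort_n, method = NULL) {
  stopifnot(cohort_n > 0)
  methods <- if (is.null(method)) unique(results$method) else method
  out <- do.call(rbind, lapply(methods, function(m) {
    pfs <- results$pfs_months[results$method == m &
      results$progressed %in% TRUE]
    n <- length(pfs)
    data.frame(
      method = m, n_progressed = n,
      percent_progressed = round(100 * n / cohort_n),
      mean_pfs = if (n) mean(pfs) else NA_real_,
      sd_pfs = if (n > 1) stats::sd(pfs) else NA_real_,
      median_pfs = if (n) stats::median(pfs) else NA_real_,
      min_pfs = if (n) min(pfs) else NA_real_,
      max_pfs = if (n) max(pfs) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Paired differences between an automated and the clinical endpoint
#'
#' Differences are `method PFS - clinical PFS` in months over patients with
#' both dates; negative values mean the automated date occurred before the
#' clinical-standard date.
#'
#' @param method_pfs,clinical_pfs Numeric PFS vectors aligned by patient
#'   (`NA` where absent).
#' @return A one-row data.frame `n_pairs`, `mean_diff`, `sd_diff`,
#'   `median_diff`, `min_diff`, `max_diff`, or `NULL` when no patient has
#'   both dates.
#' @export
difference_stats <- function(method_pfs, clinical_pfs) {
  d <- method_pfs - clinical_pfs
  d <- d[!is.na(d)]
  if (!length(d)) {
    return(NULL)
  }
  data.frame(
    n_pairs = length(d), mean_diff = mean(d),
    sd_diff = if (length(d) > 1) stats::sd(d) else NA_real_,
    median_diff = stats::median(d), min_diff = min(d), max_diff = max(d)
  )
}

#' Kruskal-Wallis omnibus test across methods
#'
#' Rank-based one-way comparison of PFS distributions across methods, with
#' the usual tie correction and a chi-squared reference distribution on
#' k - 1 degrees of freedom (delegates to [stats::kruskal.test()]). The
#' degenerate case where every pooled observation is identical returns
#' `H = 0, p = 1`.
#'
#' @param groups Named list of numeric vectors (one per method).
#' @return List with `H`, `df`, `p_value`, `n`.
#' @export
kruskal_omnibus <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 1))
  pooled <- unlist(groups, use.names = FALSE)
  k <- length(groups)
  if (length(unique(pooled)) == 1L) {
    return(list(H = 0, df = k - 1L, p_value = 1, n = length(pooled)))
  }
  kt <- stats::kruskal.test(groups)
  list(
    H = unname(kt$statistic), df = unname(kt$parameter),
    p_value = kt$p.value, n = length(pooled)
  )
}

#' Wilcoxon signed-rank test for paired PFS timelines
#'
#' Classic signed-rank variant: zero differences are discarded, absolute
#' differences are ranked with midranks for ties, and the reported statistic
#' `W` is the rank sum of the less frequent sign. For `n <= exact_limit`
#' non-zero differences the two-sided p-value is exact, by enumeration of
#' all `2^n` sign patterns of the observed (possibly tied) ranks:
#' `p = P(min(W+, W-) <= observed)`. For larger `n` a normal approximation
#' with tie correction and a 0.5 continuity correction is used. All
#' differences zero is a degenerate result (`degenerate = TRUE`), reported
#' rather than thrown.
#'
#' @param x,y Paired numeric vectors (differences are `x - y`), or `y`
#'   omitted to pass differences directly as `x`.
#' @param exact_limit Largest `n` for exact enumeration (default 12).
#' @return List with `W`, `p_value`, `n` (non-zero pairs), `method`
#'   (`"exact"`/`"normal"`) and `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 12L) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0] # classic zero-discard
  n <- length(d)
  if (n == 0L) {
    return(list(
      W = NA_real_, p_value = NA_real_, n = 0L, method = "degenerate",
      degenerate = TRUE
    ))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w_obs <- min(w_pos, w_neg)
  if (n <= exact_limit) {
    # enumerate every sign assignment over the observed rank multiset
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_plus <- as.vector(signs %*% r)
    total <- sum(r)
    w_min <- pmin(w_plus, total - w_plus)
    p <- mean(w_min <= w_obs + 1e-9)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_obs - mu + 0.5) / sqrt(sigma2) # w_obs <= mu by construction
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal"
  }
  list(
    W = w_obs, p_value = p, n = n, method = method, degenerate = FALSE,
    W_pos = w_pos, W_neg = w_neg
  )
}

#' Pairwise signed-rank tests with Bonferroni correction
#'
#' Runs [wilcoxon_signed_rank()] on each method pair's own complete cases
#' and Bonferroni-adjusts the p-values (`min(1, p * m)`).
#'
#' @param wide Patient-by-method PFS table from [aggregate_pfs()].
#' @param pairs List of 2-element character vectors naming method columns;
#'   default: every unordered pair of methods in `wide`.
#' @param m Bonferroni family size; defaults to the number of pairs.
#' @return Data.frame with `method_a`, `method_b`, `n_pairs`, `W`, `p_raw`,
#'   `p_adjusted`, `degenerate`.
#' @export
pairwise_wilcoxon <- function(wide, pairs = NULL, m = NULL) {
  methods <- setdiff(names(wide), "patient_id")
  if (is.null(pairs)) {
    pairs <- utils::combn(methods, 2, simplify = FALSE)
  }
  if (is.null(m)) m <- length(pairs)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    test <- wilcoxon_signed_rank(wide[[pr[1L]]], wide[[pr[2L]]])
    data.frame(
      method_a = pr[1L], method_b = pr[2L], n_pairs = test$n, W = test$W,
      p_raw = test$p_value,
      p_adjusted = if (is.na(test$p_value)) {
        NA_real_
      } else {
        stats::p.adjust(test$p_value, method = "bonferroni", n = m)
      },
      degenerate = test$degenerate, stringsAsFactors = FALSE
    )
  }))
  attr(out, "bonferroni_m") <- m
  rownames(out) <- NULL
  out
}

#' Fraction of automated dates within a window of the clinical date
#'
#' @param method_pfs,clinical_pfs Aligned PFS vectors in months.
#' @param window Agreement window in months (default 2, boundary inclusive).
#' @return Fraction in `[0, 1]`, or `NA` when no pairs exist.
#' @export
agreement_within <- function(method_pfs, clinical_pfs, window = 2) {
  d <- method_pfs - clinical_pfs
  d <- d[!is.na(d)]
  if (!length(d)) {
    return(NA_real_)
  }
  mean(abs(d) <= window)
}

#' Ordinary least squares trendline
#'
#' Simple linear fit (via [stats::lm()]) used for method-versus-clinical
#' trendlines and the treatment-year trend check.
#'
#' @param x,y Numeric vectors; pairs with missing values are dropped.
#' @return List with `slope`, `intercept`, `r_squared`, `F`, `df`
#'   (numerator, denominator), `p_value`, `n`.
#' @export
ols_trend <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("ols_trend() needs at least 3 points", call. = FALSE)
  if (length(unique(x)) == 1L) {
    stop("ols_trend(): x is constant, fit undefined", call. = FALSE)
  }
  if (stats::var(y) == 0) { # flat response: slope 0, nothing explained
    return(list(
      slope = 0, intercept = y[1L], r_squared = 0, F = 0,
      df = c(1L, length(x) - 2L), p_value = 1, n = length(x)
    ))
  }
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit)) # silence the perfect-fit warning
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) { # y constant: no variance to explain
    1
  } else {
    stats::pf(fstat[[1L]], fstat[[2L]], fstat[[3L]], lower.tail = FALSE)
  }
  list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = sm$r.squared,
    F = if (is.null(fstat)) 0 else unname(fstat[1L]),
    df = c(1L, length(x) - 2L), p_value = p, n = length(x)
  )
}

#' Summarise derived endpoints with comparative statistics
#'
#' Produces the full comparison: per-method descriptive statistics,
#' paired differences from the clinical standard, the agreement fraction
#' within `window` months, the Kruskal-Wallis omnibus test over patients
#' progressing by all methods, and Bonferroni-corrected pairwise Wilcoxon
#' signed-rank tests on each pair's complete cases.
#'
#' @param object A `pfs_endpoints` object from [derive_pfs()].
#' @param window Agreement window in months (default 2).
#' @param bonferroni_m Bonferroni family size (default 6: three methods
#'   against the clinical standard plus the three automated pairs).
#' @param ... Unused.
#' @return A list of class `summary.pfs_endpoints` with elements
#'   `methods` (descriptives), `differences`, `agreement`, `omnibus`,
#'   `pairwise`, `trends` (OLS of each automated method on clinical PFS)
#'   and `cohort_n`.
#' @export
summary.pfs_endpoints <- function(object, window = 2, bonferroni_m = 6, ...) {
  res <- object$results
  wide <- aggregate_pfs(res)
  auto <- setdiff(object$methods, "clinical")
  has_clin <- "clinical" %in% object$methods

  differences <- NULL
  agreement <- NULL
  trends <- list()
  if (has_clin) {
    differences <- do.call(rbind, lapply(auto, function(m) {
      ds <- difference_stats(wide[[m]], wide$clinical)
      if (is.null(ds)) {
        return(NULL)
      }
      cbind(data.frame(method = m, stringsAsFactors = FALSE), ds)
    }))
    agreement <- data.frame(
      method = auto,
      fraction_within = vapply(auto, function(m) {
        agreement_within(wide[[m]], wide$clinical, window)
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
    for (m in auto) {
      ok <- !is.na(wide[[m]]) & !is.na(wide$clinical)
      if (sum(ok) >= 3 && length(unique(wide$clinical[ok])) > 1) {
        trends[[m]] <- ols_trend(wide$clinical, wide[[m]])
      }
    }
  }

  complete <- wide[stats::complete.cases(wide[, object$methods]), ,
    drop = FALSE
  ]
  omnibus <- if (nrow(complete) >= 2 && length(object$methods) >= 2) {
    kruskal_omnibus(as.list(complete[, object$methods]))
  } else {
    NULL
  }
  pw_pairs <- c(
    if (has_clin) lapply(auto, function(m) c(m, "clinical")),
    utils::combn(auto, 2, simplify = FALSE)
  )
  pairwise <- pairwise_wilcoxon(wide, pairs = pw_pairs, m = bonferroni_m)

  structure(
    list(
      methods = summarize_methods(res, object$cohort_n),
      differences = differences, agreement = agreement, omnibus = omnibus,
      pairwise = pairwise, trends = trends, cohort_n = object$cohort_n,
      window = window
    ),
    class = "summary.pfs_endpoints"
  )
}

#' @export
print.summary.pfs_endpoints <- function(x, ...) {
  fmt1 <- function(v) ifelse(is.na(v), "-", formatC(v, format = "f",
    digits = 1))
  cat(sprintf("PFS endpoints over %d eligible patients\n\n", x$cohort_n))
  cat("Per-method descriptive statistics (months):\n")
  md <- x$methods
  for (i in seq_len(nrow(md))) {
    cat(sprintf(
      "  %-10s %d%% progressed (n=%d)  mean %s  sd %s  median %s  range %s-%s\n",
      md$method[i], md$percent_progressed[i], md$n_progressed[i],
      fmt1(md$mean_pfs[i]), fmt1(md$sd_pfs[i]), fmt1(md$median_pfs[i]),
      fmt1(md$min_pfs[i]), fmt1(md$max_pfs[i])
    ))
  }
  if (!is.null(x$differences)) {
    cat("\nDifference from clinical standard (months; negative = earlier):\n")
    dd <- x$differences
    for (i in seq_len(nrow(dd))) {
      cat(sprintf(
        "  %-10s mean %s  sd %s  median %s  range %s-%s (n=%d)\n",
        dd$method[i], fmt1(dd$mean_diff[i]), fmt1(dd$sd_diff[i]),
        fmt1(dd$median_diff[i]), fmt1(dd$min_diff[i]), fmt1(dd$max_diff[i]),
        dd$n_pairs[i]
      ))
    }
  }
  if (!is.null(x$agreement)) {
    cat(sprintf("\nAgreement within %g months of clinical date:\n", x$window))
    for (i in seq_len(nrow(x$agreement))) {
      cat(sprintf(
        "  %-10s %d%%\n", x$agreement$method[i],
        round(100 * x$agreement$fraction_within[i])
      ))
    }
  }
  if (!is.null(x$omnibus)) {
    cat(sprintf(
      "\nKruskal-Wallis (complete cases, n=%d per method): H = %.1f, df = %d, p = %.2g\n",
      x$omnibus$n / nrow(x$methods), x$omnibus$H, x$omnibus$df,
      x$omnibus$p_value
    ))
  }
  if (!is.null(x$pairwise) && nrow(x$pairwise)) {
    cat(sprintf(
      "\nPairwise Wilcoxon signed-rank (Bonferroni m = %d):\n",
      attr(x$pairwise, "bonferroni_m")
    ))
    pw <- x$pairwise
    for (i in seq_len(nrow(pw))) {
      cat(sprintf(
        "  %-10s vs %-10s W = %s, p = %s (adj %s, n=%d)\n",
        pw$method_a[i], pw$method_b[i],
        ifelse(is.na(pw$W[i]), "-", formatC(pw$W[i], format = "f",
          digits = 1)),
        ifelse(is.na(pw$p_raw[i]), "-", formatC(pw$p_raw[i], format = "g",
          digits = 2)),
        ifelse(is.na(pw$p_adjusted[i]), "-",
          formatC(pw$p_adjusted[i], format = "g", digits = 2)),
        pw$n_pairs[i]
      ))
    }
  }
  invisible(x)
}
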