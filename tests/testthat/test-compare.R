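test_that("aggregation pivots results wide and rejects duplicates", {
  res <- data.frame(
    patient_id = c("A", "A", "B", "B"),
    method = c("clinical", "nlp", "clinical", "nlp"),
    progressed = c(TRUE, TRUE, TRUE, FALSE),
    progression_date = as.Date(NA),
    pfs_months = c(6, 4, 10, NA)
  )
  wide <- aggregate_pfs(res)
  expect_identical(dim(wide), c(2L, 3L))
  expect_equal(wide$nlp, c(4, NA))
  expect_error(aggregate_pfs(rbind(res, res[1, ])), "duplicate")
})

test_that("method summaries follow Table-style rounding conventions", {
  res <- data.frame(
    patient_id = sprintf("P%02d", 1:58), method = "steroid",
    progressed = TRUE, progression_date = as.Date(NA),
    pfs_months = runif(58, 1, 80)
  )
  sm <- summarize_methods(res, cohort_n = 92)
  expect_identical(sm$percent_progressed, 63) # 58 of 92

  res3 <- data.frame(
    patient_id = c("A", "B", "C"), method = "nlp", progressed = TRUE,
    progression_date = as.Date(NA), pfs_months = c(2, 4, 6)
  )
  sm <- summarize_methods(res3, cohort_n = 3)
  expect_equal(sm$mean_pfs, 4)
  expect_equal(sm$median_pfs, 4)

  none <- summarize_methods(res3[0, ], cohort_n = 10, method = "nlp")
  expect_identical(none$percent_progressed, 0)
  expect_true(is.na(none$mean_pfs))
})

test_that("difference summaries use the automated-minus-clinical sign convention", {
  expect_equal(difference_stats(4, 6)$mean_diff, -2)
  d <- difference_stats(c(1, 2, 3), c(1, 2, 3))
  expect_equal(d$mean_diff, 0)
  expect_equal(d$sd_diff, 0)
  d <- difference_stats(c(-2, -1, 0, 1) + 10, rep(10, 4))
  expect_equal(d$mean_diff, -0.5)
  expect_equal(d$median_diff, -0.5)
  expect_null(difference_stats(c(NA, NA), c(1, 2)))
  # every automated date earlier => strictly negative mean
  expect_lt(difference_stats(c(3, 5, 1), c(4, 9, 2))$mean_diff, 0)
})

test_that("Kruskal-Wallis handles degenerate groups and matches the rank formula", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_equal(kruskal_omnibus(same)$H, 0)
  flat <- list(a = c(5, 5), b = c(5, 5, 5))
  expect_equal(kruskal_omnibus(flat)$H, 0)
  expect_equal(kruskal_omnibus(flat)$p_value, 1)

  # closed-form H on ranks, with tie correction (independent oracle)
  oracle_H <- function(groups) {
    x <- unlist(groups)
    g <- rep(seq_along(groups), lengths(groups))
    r <- rank(x)
    n <- length(x)
    h <- 12 / (n * (n + 1)) *
      sum(tapply(r, g, sum)^2 / tapply(r, g, length)) - 3 * (n + 1)
    ties <- table(x)
    h / (1 - sum(ties^3 - ties) / (n^3 - n))
  }
  grp <- list(c(1, 2), c(3, 4), c(5, 6))
  expect_equal(kruskal_omnibus(grp)$H, oracle_H(grp), tolerance = 1e-12)
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(5)
  for (i in 1:10) {
    groups <- lapply(1:3, function(j) sample(1:6, sample(2:5, 1),
      replace = TRUE))
    if (length(unique(unlist(groups))) == 1L) next
    h1 <- kruskal_omnibus(groups)$H
    h2 <- kruskal_omnibus(lapply(groups, function(g) exp(g)))$H
    expect_equal(h1, h2, tolerance = 1e-10)
  }
})

test_that("signed-rank test reports W of the less frequent sign with exact p", {
  # {1, 2, -3}: min(W+, W-) = 3 is the maximum the minimum can take,
  # so all 8 sign patterns are at least as extreme: p = 1
  t <- wilcoxon_signed_rank(c(1, 2, -3))
  expect_equal(t$W, 3)
  expect_equal(t$p_value, 1)
  expect_identical(t$method, "exact")

  # all-positive differences agree with the classical exact test
  t <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  ref <- wilcox.test(c(1, 2, 3, 4, 5), exact = TRUE)
  expect_equal(t$p_value, ref$p.value)

  # all differences zero: degenerate, reported not thrown
  t <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_true(t$degenerate)
  expect_true(is.na(t$p_value))
})

test_that("exact signed-rank p agrees with wilcox.test on tie-free data", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    d <- sample(1:20, n) * sample(c(-1, 1), n, replace = TRUE) # untied |d|
    mine <- wilcoxon_signed_rank(d)
    ref <- wilcox.test(d, exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Bonferroni adjustment multiplies and caps at one", {
  wide <- data.frame(
    patient_id = sprintf("P%d", 1:8),
    a = c(1, 2, 3, 4, 5, 6, 7, 8),
    b = c(2, 3, 4, 5, 6, 7, 8, 10)
  )
  pw <- pairwise_wilcoxon(wide, m = 6)
  expect_equal(pw$p_adjusted, min(1, pw$p_raw * 6))
  pw <- pairwise_wilcoxon(wide, m = 200)
  expect_equal(pw$p_adjusted, 1)
})

test_that("agreement fraction uses an inclusive window and is monotone", {
  clin <- c(10, 10, 10)
  auto <- c(10, 11.9, 12.1)
  expect_equal(agreement_within(auto, clin, 2), 2 / 3)
  expect_equal(agreement_within(clin, clin, 2), 1)
  expect_equal(agreement_within(clin + 5, clin, 2), 0)
  ws <- seq(0, 6, by = 0.5)
  fr <- vapply(ws, function(w) agreement_within(auto, clin, w), numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("OLS trendlines match the normal equations", {
  x <- c(1, 2, 3, 4, 5)
  fit <- ols_trend(x, 2 * x)
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)

  fit <- ols_trend(x, rep(3, 5))
  expect_equal(fit$slope, 0)
  expect_equal(fit$r_squared, 0)

  y <- c(2.1, 3.9, 6.2, 7.8, 10.3)
  fit <- ols_trend(x, y)
  # closed-form normal equations
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  expect_equal(fit$slope, beta, tolerance = 1e-10)
  expect_equal(fit$intercept, alpha, tolerance = 1e-10)
  expect_error(ols_trend(rep(1, 5), y), "constant")
})

test_that("summary() assembles descriptives, differences, tests and trends", {
  sim <- simulate_cohort(cohort_config(n_patients = 25, seed = 41))
  fit <- derive_pfs(sim$cohort)
  sm <- summary(fit)
  expect_s3_class(sm, "summary.pfs_endpoints")
  expect_setequal(sm$methods$method,
    c("clinical", "steroid", "nlp", "volumetric"))
  expect_true(all(sm$pairwise$n_pairs >= 0))
  expect_identical(attr(sm$pairwise, "bonferroni_m"), 6)
  expect_output(print(sm), "Kruskal-Wallis")
  # residuals() mirrors the difference sign convention
  r <- residuals(fit)
  wide <- aggregate_pfs(fit$results)
  one <- r[r$method == "nlp", ]
  expect_equal(
    one$difference_months,
    (wide$nlp - wide$clinical)[match(one$patient_id, wide$patient_id)]
  )
})
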