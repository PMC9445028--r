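test_that("expected onset follows the published CAG-onset relation", {
  # independent evaluation of the published parametric formula
  expect_equal(expected_onset(43), 21.54 + exp(9.556 - 0.146 * 43))
  expect_gt(expected_onset(42), expected_onset(45))
  expect_error(expected_onset(30), "range")
  expect_equal(expected_onset(c(40, 45)),
               21.54 + exp(9.556 - 0.146 * c(40, 45)))
})

test_that("residuals are observed minus expected, positive = later", {
  cag <- 43L
  expect_equal(residual_onset(expected_onset(cag), cag), 0)
  expect_equal(residual_onset(expected_onset(cag) + 10, cag), 10)
})

test_that("simulated residual noise reproduces the population SD", {
  co <- simulate_cohort(n = 4000, beta1 = 0, selection = NULL, seed = 31)
  expect_equal(stats::sd(co$residual), 7.02, tolerance = 0.05)
})

test_that("repeat statistics from the two allelic unit counts", {
  st <- repeat_statistics(38L, 35L)
  expect_identical(st$n_sum, 73L)
  expect_identical(st$n_diff, 3L)
  expect_identical(st$n_min, 35L)
  expect_identical(st$n_max, 38L)
  expect_identical(st$n_3rep, 1L)

  expect_identical(repeat_statistics(38L, 38L)$n_diff, 0L)
  expect_identical(repeat_statistics(38L, 38L)$n_3rep, 0L)
  expect_identical(repeat_statistics(35L, 35L)$n_3rep, 2L)
  # with STR lengths supplied, the 3-repeat dosage uses them
  expect_identical(repeat_statistics(35L, 38L, str_a = 3L, str_b = 6L)$n_3rep,
                   1L)
})

test_that("repeat statistic identities hold over random genotypes", {
  set.seed(5)
  qa <- sample(30:45, 50, TRUE); qb <- sample(30:45, 50, TRUE)
  st <- repeat_statistics(qa, qb)
  expect_identical(st$n_sum, st$n_min + st$n_max)
  expect_identical(st$n_diff, st$n_max - st$n_min)
  expect_true(all(st$n_min <= st$n_max))
})

test_that("OLS association interpolates noiseless linear data exactly", {
  df <- tibble::tibble(n_sum = c(70, 72, 74, 76, 79),
                       residual = 2 - 1 * c(70, 72, 74, 76, 79))
  fit <- suppressWarnings(ols_association(df, "n_sum"))  # perfect fit
  expect_equal(fit$beta0, 2)
  expect_equal(fit$beta1, -1)
  expect_error(ols_association(tibble::tibble(n_sum = rep(70, 5),
                                              residual = rnorm(5)),
                               "n_sum"),
               "constant")
})

test_that("OLS p-values are calibrated under the null", {
  set.seed(8)
  ps <- replicate(300, {
    df <- tibble::tibble(n_sum = sample(70:80, 60, TRUE),
                         residual = rnorm(60, 0, 7))
    ols_association(df, "n_sum")$lrt_p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.035)
})

test_that("OLS on a selected cohort overestimates the effect size", {
  set.seed(9)
  b <- replicate(10, {
    co <- simulate_cohort(n = 400, seed = sample.int(1e6, 1))
    ols_association(co, "n_sum")$beta1
  })
  expect_gt(mean(abs(b)), 1)
})

test_that("logistic regression on dichotomized extremes", {
  co <- simulate_cohort(n = 600, seed = 32)
  fit <- dichotomize_and_logistic(co, "n_sum", threshold = 0)
  expect_lt(fit$beta1, 0)
  expect_lt(fit$lrt_p, 0.05)
  expect_identical(fit$n, 600L)

  fit13 <- dichotomize_and_logistic(co, "n_sum", threshold = 13)
  expect_lt(fit13$n, 600L)

  expect_error(dichotomize_and_logistic(co, "n_sum", threshold = 1e6),
               "excludes every record|class")
})

test_that("Bonferroni adjustment", {
  expect_equal(bonferroni_adjust(5.0e-9, 4), 2.0e-8)
  expect_equal(bonferroni_adjust(0.5, 4), 1)
  expect_equal(bonferroni_adjust(0.123, 1), 0.123)
  expect_error(bonferroni_adjust(0.1, 0), "k must")
})

test_that("nested-model comparison flags duplicates and collinearity", {
  co <- simulate_cohort(n = 400, seed = 33)
  co$n_sum_copy <- co$n_sum
  cmp <- compare_statistics(co, c("n_sum", "n_sum_copy", "n_diff"))
  dup <- cmp$pairs[cmp$pairs$baseline == "n_sum" &
                     cmp$pairs$added == "n_sum_copy", ]
  expect_true(dup$collinear || dup$p > 0.99)
  # n_min + n_max jointly reconstruct n_sum: adding n_sum to both is
  # rank-deficient, reported rather than crashed
  cmp2 <- compare_statistics(co, c("n_min", "n_max", "n_sum"))
  expect_s3_class(cmp2, "qtr_model_comparison")
})

test_that("an independent noise statistic adds no explanatory power", {
  set.seed(10)
  ps <- replicate(40, {
    co <- simulate_cohort(n = 250, seed = sample.int(1e6, 1))
    co$noise <- rnorm(nrow(co))
    cmp <- compare_statistics(co, c("n_sum", "noise"))
    cmp$pairs$p[cmp$pairs$baseline == "n_sum" & cmp$pairs$added == "noise"]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("conditional association flags identical columns", {
  co <- simulate_cohort(n = 100, seed = 34)
  co$dup <- co$n_sum
  out <- conditional_association(co, "n_sum", "dup")
  expect_true(all(out$collinear))
  expect_error(conditional_association(co, "n_sum", "n_sum"), "same column")
})

test_that("conditioning a covariate independent of outcome and statistic", {
  co <- simulate_cohort(n = 400, seed = 35)
  co$junk <- rnorm(nrow(co))
  raw <- ols_association(co, "n_sum")
  cond <- conditional_association(co, "n_sum", "junk")
  p_raw <- raw$lrt_p
  p_cond <- cond$p[cond$term == "n_sum"]
  expect_lt(abs(log10(p_cond) - log10(p_raw)), 1)
})
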