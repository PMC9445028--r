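m_paper <- selection_model(7.02, 17.6, 3.30)

test_that("selection function and its hard-threshold limit", {
  expect_equal(selection_function(17.6, m_paper), 0.5)
  expect_equal(selection_function(-17.6, m_paper), 0.5)
  expect_equal(selection_function(0, m_paper), 1 / (1 + exp(17.6 / 3.3)))
  m0 <- selection_model(7.02, 17.6, 0)
  expect_identical(selection_function(c(-20, -10, 17.6, 20), m0),
                   c(1, 0, 0.5, 1))
  expect_error(selection_model(sigma = -1), "sigma")
  expect_error(selection_model(delta = -1), "delta")
})

test_that("selected density is a proper, symmetric density", {
  v <- stats::integrate(function(r) selected_density(r, m_paper),
                        -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(v, 1, tolerance = 1e-8)
  r <- c(3.7, 11.2, 19.5)
  expect_equal(selected_density(r, m_paper), selected_density(-r, m_paper))
  # with S == 1 (threshold pushed to -Inf) the density is the plain normal
  m1 <- selection_model(7.02, -1e6, 1)
  expect_equal(selected_density(r, m1), stats::dnorm(r, 0, 7.02),
               tolerance = 1e-8)
})

test_that("normalizer methods agree with each other and with Monte Carlo", {
  mu <- c(-6.3, -1, 0, 2.4, 8.8)
  a <- qtronset:::.sel_normalizer(mu, 7.02, m_paper, "simpson")
  b <- qtronset:::.sel_normalizer(mu, 7.02, m_paper, "quadrature")
  expect_equal(a, b, tolerance = 1e-8)
  # independent Monte Carlo integration
  set.seed(2)
  z <- rnorm(1e6)
  mc <- vapply(mu, function(m)
    mean(selection_function(m + 7.02 * z, m_paper)), numeric(1))
  expect_equal(b, mc, tolerance = 2e-3)
  # closed form at delta ~ 0 matches quadrature at tiny delta
  m_eps <- selection_model(7.02, 17.6, 1e-6)
  closed <- qtronset:::.sel_normalizer(mu, 7.02,
                                       selection_model(7.02, 17.6, 0))
  quad <- vapply(mu, function(mm) {
    stats::integrate(function(R) {
      stats::dnorm(R, mm, 7.02) * selection_function(R, m_eps)
    }, -Inf, Inf, rel.tol = 1e-10)$value
  }, numeric(1))
  expect_equal(closed, quad, tolerance = 1e-6)
})

test_that("per-record likelihood reduces to the OLS term when S == 1", {
  m1 <- selection_model(7.02, -1e6, 1)
  set.seed(3)
  r <- rnorm(50, 1, 7)
  x <- sample(70:80, 50, TRUE)
  got <- selection_loglik(r, x, 1.5, -0.8, 6.5, m1)
  want <- stats::dnorm(r - (1.5 - 0.8 * x), 0, 6.5, log = TRUE)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("denominator caching does not change the likelihood", {
  co <- simulate_cohort(n = 200, seed = 36)
  ll1 <- selection_loglik(co$residual, co$n_sum, 0, -1, 7, m_paper,
                          method = "quadrature")
  # force record-by-record evaluation (no shared cache across records)
  ll2 <- vapply(seq_len(nrow(co)), function(i)
    selection_loglik(co$residual[i], co$n_sum[i], 0, -1, 7, m_paper,
                     method = "quadrature"), numeric(1))
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("selection fit warns on tiny samples and rejects degenerate input", {
  expect_warning(fit_selection_model(rnorm(10, 0, 5) + 20), "unstable")
  expect_error(fit_selection_model(rep(1, 100)), "distinct")
})

test_that("unselected normal residuals drive the fit towards S == 1", {
  set.seed(4)
  r <- rnorm(800, 0, 5)
  fit <- suppressWarnings(fit_selection_model(r))
  ks <- suppressWarnings(stats::ks.test(abs(r), function(q)
    2 * stats::pnorm(q, 0, fit$model$sigma) - 1))
  # the fitted distance cannot beat the best folded-normal fit by much,
  # and the selection must be inactive over the data range
  expect_lt(fit$D, unname(ks$statistic) + 0.02)
  expect_gt(min(selection_function(abs(r), fit$model)), 0.2)
})

test_that("regression with selection equals OLS when S == 1", {
  m1 <- selection_model(7.02, -1e6, 1)
  co <- simulate_cohort(n = 300, selection = NULL, seed = 37)
  sel <- fit_regression_with_selection(co, "n_sum", model = m1, ci = FALSE)
  ols <- stats::lm(residual ~ n_sum, data = co)
  expect_equal(sel$beta0, unname(stats::coef(ols)[1]), tolerance = 1e-5)
  expect_equal(sel$beta1, unname(stats::coef(ols)[2]), tolerance = 1e-5)
  expect_equal(sel$sigma, sqrt(mean(stats::residuals(ols)^2)),
               tolerance = 1e-5)
})

test_that("regression with selection recovers the simulated effect", {
  co <- simulate_cohort(n = 610, seed = 38)
  fit <- fit_regression_with_selection(co, "n_sum", model = m_paper,
                                       ci = TRUE)
  expect_lt(fit$ci_beta1[1], -1)
  expect_gt(fit$ci_beta1[2], -1)
  expect_lt(fit$lrt_p, 1e-4)
  # the naive OLS slope on the same selected cohort is steeper
  expect_gt(abs(ols_association(co, "n_sum")$beta1), abs(fit$beta1))
})

test_that("tidiers return well-formed tibbles", {
  co <- simulate_cohort(n = 200, seed = 39)
  fit <- fit_regression_with_selection(co, "n_sum", model = m_paper,
                                       ci = FALSE)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "p_value") %in% names(td)))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$method, "selection")
  sf <- suppressWarnings(fit_selection_model(co$residual))
  expect_identical(tidy(sf)$term, c("sigma", "r_thr", "delta"))
  expect_s3_class(autoplot(sf), "ggplot")
  expect_s3_class(autoplot(fit, co), "ggplot")
})
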