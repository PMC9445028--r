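# Association tests of residual age at onset with repeat statistics:
# ordinary least squares (biased under extreme-residual ascertainment, but
# comparable across models), logistic regression on dichotomized extremes,
# nested-model comparison of statistics, and conditional analysis.

#' Linear (OLS) association of residual onset with a repeat statistic
#'
#' Plain least-squares regression of the residual on the statistic. Under
#' extreme-phenotype selection this overestimates the absolute effect size
#' (use [fit_regression_with_selection()] for a corrected estimate), but
#' its p-values remain useful for comparing models.
#'
#' @param data Cohort tibble with `residual` and the statistic column.
#' @param statistic Column name of the repeat statistic.
#' @param covariates Optional adjustment columns.
#' @return A `qtr_assoc` object with `method = "ols"`. The p-value is the
#'   likelihood-ratio test of the statistic's coefficient.
#' @export
ols_association <- function(data, statistic = "n_sum", covariates = NULL) {
  if (nrow(data) < 3L) stop("need at least 3 records")
  x <- data[[statistic]]
  if (is.null(x)) stop("statistic column '", statistic, "' not found")
  if (stats::sd(x) == 0) stop("statistic '", statistic, "' is constant")
  rhs <- paste(c(covariates, statistic), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("residual ~", rhs)), data = data)
  rhs0 <- if (is.null(covariates)) "1" else
    paste(covariates, collapse = " + ")
  fit0 <- stats::lm(stats::as.formula(paste("residual ~", rhs0)),
                    data = data)
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(fit0))
  lrt <- max(0, 2 * (ll - ll0))
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  coefs <- tibble::tibble(term = names(cf), estimate = unname(cf),
                          std_error = unname(se))
  ci <- tryCatch(stats::confint(fit)[statistic, ],
                 error = function(e) c(NA_real_, NA_real_))
  .assoc_obj("ols", statistic, coefs,
             sqrt(mean(stats::residuals(fit)^2)), ll, ll0, lrt,
             stats::pchisq(lrt, 1L, lower.tail = FALSE),
             unname(ci), nrow(data),
             extra = list(lm = fit, covariates = covariates,
                          beta0 = unname(cf[1L]),
                          beta1 = unname(cf[statistic])))
}

#' Logistic association of extreme-onset class with a repeat statistic
#'
#' Dichotomizes the cohort into extreme-late (`residual > threshold`) and
#' extreme-early (`residual < -threshold`) onset, drops the middle, and
#' fits a logistic regression of class (late = 1) on the statistic.
#' Perfect separation is flagged rather than treated as an error.
#'
#' @param data Cohort tibble with `residual` and the statistic column.
#' @param statistic Column name of the repeat statistic.
#' @param threshold Residual threshold in years (0, 13 and 20 are the
#'   conventional choices).
#' @return A `qtr_assoc` object with `method = "logistic"`; `n` is the
#'   number of records kept after dichotomization.
#' @export
dichotomize_and_logistic <- function(data, statistic = "n_sum",
                                     threshold = 0) {
  cls <- ifelse(data$residual > threshold, 1L,
                ifelse(data$residual < -threshold, 0L, NA_integer_))
  keep <- !is.na(cls)
  if (!any(keep)) stop("threshold excludes every record")
  d <- data[keep, ]
  y <- cls[keep]
  if (length(unique(y)) < 2L) {
    stop("one extreme class is empty at threshold ", threshold)
  }
  x <- d[[statistic]]
  if (stats::sd(x) == 0) stop("statistic '", statistic, "' is constant")
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  fit0 <- stats::glm(y ~ 1, family = stats::binomial())
  lrt <- max(0, fit0$deviance - fit$deviance)
  cf <- stats::coef(fit)
  coefs <- tibble::tibble(term = c("(Intercept)", statistic),
                          estimate = unname(cf))
  .assoc_obj("logistic", statistic, coefs, NA_real_,
             as.numeric(stats::logLik(fit)),
             as.numeric(stats::logLik(fit0)), lrt,
             stats::pchisq(lrt, 1L, lower.tail = FALSE),
             c(NA_real_, NA_real_), length(y),
             extra = list(glm = fit, threshold = threshold,
                          separated = separated,
                          beta0 = unname(cf[1L]), beta1 = unname(cf[2L])))
}

#' Pairwise nested-model comparison of repeat statistics
#'
#' For every ordered pair (A, B) of statistics, fits the baseline linear
#' model `residual ~ A` and tests whether adding B significantly improves
#' the fit (nested-model F test). A statistic is "best fitting" when no
#' other statistic adds significant improvement at level `alpha`.
#' Collinear additions (no residual degrees of freedom gained) are
#' reported with `collinear = TRUE` and an NA p-value.
#'
#' @param data Cohort tibble with `residual` and the statistic columns.
#' @param statistics Character vector of statistic column names.
#' @param alpha Significance level for the best-set definition.
#' @return An object of class `qtr_model_comparison`: tibble `pairs`
#'   (`baseline`, `added`, `f`, `p`, `collinear`) plus `best`, the
#'   best-fitting set.
#' @export
compare_statistics <- function(data,
                               statistics = c("n_sum", "n_diff", "n_min",
                                              "n_max", "n_3rep"),
                               alpha = 0.05) {
  statistics <- statistics[vapply(statistics, function(s)
    stats::sd(data[[s]]) > 0, logical(1))]
  if (length(statistics) < 2L) stop("need at least two varying statistics")
  rows <- list()
  for (a in statistics) {
    fa <- stats::lm(stats::as.formula(paste("residual ~", a)), data = data)
    for (b in setdiff(statistics, a)) {
      fab <- stats::lm(stats::as.formula(paste("residual ~", a, "+", b)),
                       data = data)
      collinear <- fab$df.residual >= fa$df.residual ||
        any(is.na(stats::coef(fab)))
      if (collinear) {
        rows[[paste(a, b)]] <- tibble::tibble(
          baseline = a, added = b, f = NA_real_, p = NA_real_,
          collinear = TRUE)
      } else {
        an <- stats::anova(fa, fab)
        rows[[paste(a, b)]] <- tibble::tibble(
          baseline = a, added = b, f = an$F[2L], p = an$`Pr(>F)`[2L],
          collinear = FALSE)
      }
    }
  }
  pairs <- dplyr::bind_rows(rows)
  best <- vapply(statistics, function(a) {
    ps <- pairs$p[pairs$baseline == a]
    all(is.na(ps) | ps > alpha)
  }, logical(1))
  structure(list(pairs = pairs, best = statistics[best],
                 statistics = statistics, alpha = alpha),
            class = "qtr_model_comparison")
}

#' @export
print.qtr_model_comparison <- function(x, ...) {
  cat("<qtr_model_comparison> best fitting:",
      if (length(x$best)) paste(x$best, collapse = ", ") else "(none)",
      "\n")
  print(x$pairs)
  invisible(x)
}

#' Conditional association of a primary statistic and a covariate
#'
#' Tests each of `primary` and `covariate` for association with residual
#' onset while conditioning on the other, in both directions: the partial
#' p-value of `covariate` given `primary` answers whether the covariate
#' (e.g. a tagging SNV dosage) carries signal beyond the repeat statistic,
#' and vice versa. Engines: `"ols"` or `"selection"`.
#'
#' @param data Cohort tibble with `residual` and both columns.
#' @param primary Column name of the primary statistic.
#' @param covariate Column name of the conditioning variable.
#' @param engine `"ols"` or `"selection"`.
#' @param model Optional [selection_model()] for the selection engine.
#' @return A tibble with one row per direction: `term`, `conditioned_on`,
#'   `estimate`, `p`, `collinear`.
#' @export
conditional_association <- function(data, primary = "n_sum",
                                    covariate = "marker_dosage",
                                    engine = c("ols", "selection"),
                                    model = NULL) {
  engine <- match.arg(engine)
  if (identical(primary, covariate)) {
    stop("primary and covariate are the same column")
  }
  cr <- stats::cor(data[[primary]], data[[covariate]])
  if (isTRUE(abs(cr) > 1 - 1e-12)) {
    return(tibble::tibble(term = c(primary, covariate),
                          conditioned_on = c(covariate, primary),
                          estimate = NA_real_, p = NA_real_,
                          collinear = TRUE))
  }
  if (engine == "selection" && is.null(model)) {
    model <- fit_selection_model(data$residual)$model
  }
  one <- function(term, given) {
    fit <- if (engine == "ols") {
      ols_association(data, statistic = term, covariates = given)
    } else {
      fit_regression_with_selection(data, statistic = term, model = model,
                                    covariates = given, ci = FALSE)
    }
    tibble::tibble(term = term, conditioned_on = given,
                   estimate = fit$beta1, p = fit$lrt_p, collinear = FALSE)
  }
  dplyr::bind_rows(one(primary, covariate), one(covariate, primary))
}

#' Bonferroni adjustment
#'
#' `min(1, k * p)`; the default `k = 4` corresponds to testing the four
#' repeat statistics (sum, difference, minimum, maximum).
#'
#' @param p P-values.
#' @param k Number of tests.
#' @return Adjusted p-values.
#' @examples
#' bonferroni_adjust(5.0e-9, 4) # 2.0e-8
#' @export
bonferroni_adjust <- function(p, k = 4L) {
  if (k < 1L) stop("k must be >= 1")
  base::pmin(1, k * p)
}
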