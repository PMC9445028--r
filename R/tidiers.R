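# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an association fit
#'
#' @param x A `qtr_assoc` from [ols_association()],
#'   [dichotomize_and_logistic()] or [fit_regression_with_selection()].
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @method tidy qtr_assoc
#' @export
tidy.qtr_assoc <- function(x, ...) {
  out <- x$coefficients
  out$method <- x$method
  is_stat <- out$term == x$statistic
  out$p_value <- ifelse(is_stat, x$lrt_p, NA_real_)
  out$conf_low <- ifelse(is_stat, x$ci_beta1[1L], NA_real_)
  out$conf_high <- ifelse(is_stat, x$ci_beta1[2L], NA_real_)
  out
}

#' One-row model summary of an association fit
#'
#' @param x A `qtr_assoc`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance qtr_assoc
#' @export
glance.qtr_assoc <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 beta1 = x$beta1, sigma = x$sigma, logLik = x$logLik,
                 null_logLik = x$null_logLik, lrt_stat = x$lrt_stat,
                 p_value = x$lrt_p, n = x$n)
}

#' Tidy a selection-model fit
#'
#' @param x A `selection_fit` from [fit_selection_model()].
#' @param ... Unused.
#' @return A tibble with one row per parameter.
#' @method tidy selection_fit
#' @export
tidy.selection_fit <- function(x, ...) {
  tibble::tibble(term = c("sigma", "r_thr", "delta"),
                 estimate = c(x$model$sigma, x$model$r_thr, x$model$delta))
}

#' One-row summary of a selection-model fit
#'
#' @param x A `selection_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the parameters, distance `D` and the
#'   approximate KS p-value.
#' @method glance selection_fit
#' @export
glance.selection_fit <- function(x, ...) {
  tibble::tibble(sigma = x$model$sigma, r_thr = x$model$r_thr,
                 delta = x$model$delta, D = x$D,
                 ks_p_approx = x$ks_p_approx, n = x$n)
}

#' Tidy a model comparison
#'
#' @param x A `qtr_model_comparison` from [compare_statistics()].
#' @param ... Unused.
#' @return The pairwise improvement table.
#' @method tidy qtr_model_comparison
#' @export
tidy.qtr_model_comparison <- function(x, ...) x$pairs

#' Diagnostic plot of a selection-model fit
#'
#' Empirical versus fitted cumulative distribution of the folded residual
#' `|R|`; the maximum vertical gap is the minimised distance `D`.
#'
#' @param object A `selection_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot selection_fit
#' @export
autoplot.selection_fit <- function(object, ...) {
  r <- sort(abs(object$residuals))
  df <- tibble::tibble(
    abs_residual = r,
    empirical = seq_along(r) / length(r),
    fitted = .folded_cdf(r, object$model))
  df_long <- tidyr::pivot_longer(df, c("empirical", "fitted"),
                                 names_to = "cdf", values_to = "value")
  ggplot2::ggplot(df_long,
                  ggplot2::aes(x = .data$abs_residual, y = .data$value,
                               colour = .data$cdf)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "|residual age at onset| (years)",
                  y = "cumulative probability",
                  title = sprintf("Selection fit: D = %.3f, KS p ~ %.2f",
                                  object$D, object$ks_p_approx)) +
    ggplot2::theme_minimal()
}

#' Effect plot of an association fit
#'
#' Residual age at onset against the repeat statistic with the fitted
#' regression line; for a selection fit the (biased) OLS line is shown for
#' comparison.
#'
#' @param object A `qtr_assoc` fitted with the OLS or selection engine.
#' @param data The cohort tibble the model was fitted to.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qtr_assoc
#' @export
autoplot.qtr_assoc <- function(object, data, ...) {
  if (object$method == "logistic") {
    stop("autoplot is available for ols and selection fits")
  }
  x <- data[[object$statistic]]
  p <- ggplot2::ggplot(data,
                       ggplot2::aes(x = .data[[object$statistic]],
                                    y = .data$residual)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4) +
    ggplot2::geom_abline(intercept = object$beta0, slope = object$beta1,
                         linewidth = 0.8) +
    ggplot2::labs(x = object$statistic,
                  y = "residual age at onset (years)",
                  title = sprintf("%s fit: %.2f y per unit (p = %.2g)",
                                  object$method, object$beta1,
                                  object$lrt_p)) +
    ggplot2::theme_minimal()
  if (object$method == "selection") {
    ols <- stats::lm(data$residual ~ x)
    p <- p + ggplot2::geom_abline(intercept = stats::coef(ols)[1L],
                                  slope = stats::coef(ols)[2L],
                                  linetype = "dashed", colour = "grey50")
  }
  p
}

#' Genotype-support plot for a repeat call
#'
#' Read support for the two called alleles of a sample.
#'
#' @param object A `qtr_call`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qtr_call
#' @export
autoplot.qtr_call <- function(object, ...) {
  df <- tibble::tibble(
    allele = c(object$allele_a$matched %||% "allele A",
               object$allele_b$matched %||% "allele B"),
    qtr_units = c(object$allele_a$qtr_units, object$allele_b$qtr_units),
    support = c(object$allele_a$support, object$allele_b$support))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$allele, y = .data$support)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::labs(title = sprintf("%s: QTR %s/%s (depth %d)",
                                  object$sample, df$qtr_units[1L],
                                  df$qtr_units[2L], object$depth),
                  y = "supporting reads") +
    ggplot2::theme_minimal()
}
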