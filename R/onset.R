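# Residual age at motor onset and per-individual repeat statistics.

#' Expected age at motor onset from CAG repeat length
#'
#' The parametric CAG-onset relation of Langbehn et al. (2004):
#' `E[onset] = 21.54 + exp(9.556 - 0.146 * CAG)` years. Any alternative
#' onset-expectation model can be supplied via `params`.
#'
#' @param cag Integer vector of uninterrupted CAG unit counts.
#' @param params Model parameters `intercept`, `a`, `b` and the validated
#'   CAG `range`.
#' @return Expected ages at onset in years.
#' @examples
#' expected_onset(43)
#' @export
expected_onset <- function(cag,
                           params = list(intercept = 21.54, a = 9.556,
                                         b = 0.146, range = c(36L, 60L))) {
  if (any(cag < params$range[1L] | cag > params$range[2L])) {
    stop("CAG length outside the validated range [", params$range[1L], ", ",
         params$range[2L], "]; adjust params$range if this is intended")
  }
  params$intercept + exp(params$a - params$b * cag)
}

#' Residual age at motor onset
#'
#' Observed minus expected onset for the individual's CAG length: positive
#' residuals mean later onset than expected, negative earlier.
#'
#' @param onset Observed ages at motor onset (years).
#' @param cag CAG unit counts.
#' @param params Passed to [expected_onset()].
#' @return Residuals in years.
#' @export
residual_onset <- function(onset, cag, params = NULL) {
  expct <- if (is.null(params)) expected_onset(cag) else
    expected_onset(cag, params)
  onset - expct
}

#' Per-individual repeat statistics from the two allelic unit counts
#'
#' Given the QTR unit counts of the two alleles, returns the statistics
#' used for association testing: their sum, absolute difference, minimum
#' and maximum, and the number of 3-repeat alleles (`n_3rep`, dosage 0/1/2,
#' defined by a central STR of 3 units: `str_a`/`str_b` when provided,
#' otherwise inferred from the built-in inventory as QTR length 35).
#'
#' @param qtr_a,qtr_b QTR unit counts (vectors).
#' @param str_a,str_b Optional central STR unit counts.
#' @return A tibble with columns `n_sum`, `n_diff`, `n_min`, `n_max`,
#'   `n_3rep`.
#' @examples
#' repeat_statistics(38, 35)
#' @export
repeat_statistics <- function(qtr_a, qtr_b, str_a = NULL, str_b = NULL) {
  is3 <- function(qtr, str) {
    if (!is.null(str)) str == 3L else qtr == 35L
  }
  tibble::tibble(
    n_sum = qtr_a + qtr_b,
    n_diff = abs(qtr_a - qtr_b),
    n_min = base::pmin(qtr_a, qtr_b),
    n_max = base::pmax(qtr_a, qtr_b),
    n_3rep = as.integer(is3(qtr_a, str_a)) + as.integer(is3(qtr_b, str_b)))
}

#' Add repeat statistics and residuals to a cohort table
#'
#' Pipe-friendly: augments a cohort tibble having `qtr_a`, `qtr_b` (and
#' optionally `str_a`, `str_b`, `cag`, `onset`) with the repeat statistics
#' and, when onset data are present and `residual` is absent, the residual
#' age at onset.
#'
#' @param cohort A tibble of cohort records.
#' @param onset_params Passed to [expected_onset()].
#' @return The augmented tibble.
#' @export
add_repeat_statistics <- function(cohort, onset_params = NULL) {
  stats <- repeat_statistics(cohort$qtr_a, cohort$qtr_b,
                             cohort$str_a, cohort$str_b)
  out <- dplyr::bind_cols(cohort, stats[setdiff(names(stats), names(cohort))])
  if (!"residual" %in% names(out) &&
      all(c("onset", "cag") %in% names(out))) {
    out$residual <- residual_onset(out$onset, out$cag, onset_params)
  }
  out
}
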