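# Synthetic data generators: 75 bp paired-end reads over repeat haplotypes
# and cohorts of residual onsets with a linear repeat effect under
# extreme-residual selection. Defaults describe the data regime the
# analysis targets: HiSeq exome read geometry, the inventory's allele
# frequencies, residual SD 7.02 y, selection threshold 17.6 y with width
# 3.30 y, and a repeat effect of -1 year per added hexamer on the summed
# QTR length.

.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103515245 + 12345 + k) %% 2147483647)
}

.with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Simulate paired-end reads over a haplotype pair
#'
#' Uniform fragment sampling over each haplotype (50:50 allele balance),
#' paired reads of `read_length` bases taken from the two fragment ends,
#' reported in reference-forward orientation, with optional uniform
#' substitution errors. Deterministic under a fixed seed.
#'
#' @param hap_a,hap_b Haplotype sequences from [build_allele_sequence()]
#'   (`hap_b` defaults to `hap_a` for a homozygote).
#' @param read_length Read length in bases (default 75).
#' @param paired Generate read pairs (default) or single reads.
#' @param insert_mean,insert_sd Fragment length distribution (bases).
#' @param coverage Total haploid coverage over the pair (i.e. each
#'   haplotype is sampled at `coverage / 2`).
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param sample Sample label used in read ids.
#' @return Tibble: `read_id`, `mate`, `seq`, plus truth columns `hap`
#'   (1 or 2), `allele`, `frag_start`, `frag_len`.
#' @export
simulate_reads <- function(hap_a, hap_b = hap_a, read_length = 75L,
                           paired = TRUE, insert_mean = 300, insert_sd = 50,
                           coverage = 30, error_rate = 0, seed = NULL,
                           sample = "sample1") {
  haps <- list(hap_a, hap_b)
  lens <- vapply(haps, nchar, integer(1))
  if (any(2L * read_length > lens)) {
    stop("fragment (2 x read_length) longer than a haplotype")
  }
  # Fragments are sampled over a padded template (the haplotype embedded
  # in neutral outer sequence) so that fragment-placement constraints do
  # not depress read-start coverage anywhere inside the window, mimicking
  # reads drawn from a genome-scale library; only reads falling entirely
  # within the haplotype window are emitted, as a locus extraction from a
  # BAM would return.
  pad <- max(0L, as.integer(insert_mean + 3 * insert_sd) - read_length)
  .with_seed(seed, {
    out <- list()
    for (h in 1:2) {
      len <- lens[h]
      tlen <- len + 2L * pad
      hs <- paste0(strrep("A", pad), as.character(haps[[h]]),
                   strrep("A", pad))
      n_frag <- max(1L, ceiling((coverage / 2) * tlen /
                                  (read_length * (if (paired) 2L else 1L))))
      fl <- round(stats::rnorm(n_frag, insert_mean, insert_sd))
      fl <- base::pmin(base::pmax(fl, 2L * read_length), tlen)
      st <- floor(stats::runif(n_frag, 1, tlen - fl + 1 + 1))
      st <- base::pmin(st, tlen - fl + 1L)
      mk_mate <- function(rst, mate_no) {
        keep <- rst > pad & rst + read_length - 1L <= pad + len
        if (!any(keep)) return(NULL)
        tibble::tibble(
          read_id = sprintf("%s_h%d_f%04d", sample, h,
                            seq_len(n_frag))[keep],
          mate = mate_no,
          seq = substr(rep(hs, sum(keep)), rst[keep],
                       rst[keep] + read_length - 1L),
          hap = h,
          allele = attr(haps[[h]], "allele") %||% NA_character_,
          frag_start = st[keep] - pad,
          frag_len = fl[keep])
      }
      rows <- if (paired) {
        dplyr::bind_rows(mk_mate(st, 1L),
                         mk_mate(st + fl - read_length, 2L))
      } else {
        mk_mate(st, 1L)
      }
      rows <- rows[order(rows$read_id, rows$mate), ]
      out[[h]] <- rows
    }
    reads <- dplyr::bind_rows(out)
    if (error_rate > 0) {
      reads$seq <- vapply(reads$seq, function(s) {
        hitn <- stats::rbinom(1L, nchar(s), error_rate)
        if (hitn == 0L) return(s)
        pos <- sample.int(nchar(s), hitn)
        for (p in pos) {
          cur <- substr(s, p, p)
          substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
        }
        s
      }, character(1), USE.NAMES = FALSE)
    }
    reads
  })
}

#' Simulate a cohort of residual onsets under extreme-phenotype selection
#'
#' Diploid repeat genotypes are drawn from the allele inventory under
#' Hardy-Weinberg equilibrium; residuals follow
#' `R = beta0 + beta1 * (N_sum - mean(N_sum)) + N(0, sigma^2)` (the effect
#' acts on the centred summed QTR length so `beta0` keeps its meaning as
#' the mean residual); individuals are kept with probability `S(R)` under
#' the selection model; a biallelic marker tags allele A2 with the given
#' per-chromosome fidelity (with probability `1 - fidelity` the marker
#' allele is drawn independently from the A2 frequency, giving a
#' marker/A2 correlation equal to `fidelity`).
#'
#' @param n Number of selected individuals to return.
#' @param locus A [repeat_locus()].
#' @param freqs Named allele frequencies (default: inventory frequencies,
#'   renormalized).
#' @param cag_range CAG lengths drawn uniformly from this range.
#' @param beta0,beta1 Intercept (years) and effect (years per hexamer).
#' @param sigma Residual SD in years.
#' @param selection A [selection_model()] applied by accept/reject, or
#'   `NULL` for no selection.
#' @param marker_fidelity Per-chromosome tagging fidelity of the marker.
#' @param keep_all Also return rejected individuals (`selected = FALSE`).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Cohort tibble: `id`, `cag`, `onset`, `residual`, alleles, QTR
#'   and STR unit counts, repeat statistics, `marker_dosage`, `selected`.
#' @export
simulate_cohort <- function(n = 610L, locus = repeat_locus(), freqs = NULL,
                            cag_range = c(40L, 50L), beta0 = 0,
                            beta1 = -1.0, sigma = 7.02,
                            selection = selection_model(sigma = sigma),
                            marker_fidelity = 0.99, keep_all = FALSE,
                            seed = NULL) {
  inv <- allele_inventory(locus)
  if (is.null(freqs)) {
    freqs <- stats::setNames(inv$freq_pct / sum(inv$freq_pct), inv$name)
  } else {
    freqs <- freqs / sum(freqs)
  }
  stopifnot(all(names(freqs) %in% inv$name))
  mu_sum <- 2 * sum(freqs * inv$qtr_units[match(names(freqs), inv$name)])
  if (!is.null(selection)) {
    acc0 <- .sel_normalizer(0, sigma, selection)
    if (acc0 < 1e-4) {
      stop("selection acceptance rate below 1e-4; relax R_thr or Delta")
    }
  }
  p_a2 <- unname(freqs["A2"])
  .with_seed(seed, {
    kept <- list(); n_kept <- 0L; total <- 0L
    while (n_kept < n) {
      b <- max(1000L, ceiling((n - n_kept) * 4))
      al_a <- sample(names(freqs), b, replace = TRUE, prob = freqs)
      al_b <- sample(names(freqs), b, replace = TRUE, prob = freqs)
      qa <- inv$qtr_units[match(al_a, inv$name)]
      qb <- inv$qtr_units[match(al_b, inv$name)]
      sa <- inv$str_units[match(al_a, inv$name)]
      sb <- inv$str_units[match(al_b, inv$name)]
      nsum <- qa + qb
      R <- beta0 + beta1 * (nsum - mu_sum) + stats::rnorm(b, 0, sigma)
      keep <- if (is.null(selection)) rep(TRUE, b) else
        stats::runif(b) < selection_function(R, selection)
      mk <- function(al) {
        true <- as.integer(al == "A2")
        use_true <- stats::runif(b) < marker_fidelity
        ifelse(use_true, true, stats::rbinom(b, 1L, p_a2))
      }
      dose <- mk(al_a) + mk(al_b)
      cag <- sample(seq(cag_range[1L], cag_range[2L]), b, replace = TRUE)
      batch <- tibble::tibble(
        allele_a = al_a, allele_b = al_b, qtr_a = qa, qtr_b = qb,
        str_a = sa, str_b = sb, cag = cag, residual = R,
        onset = expected_onset(cag) + R, marker_dosage = dose,
        selected = keep)
      total <- total + b
      kept[[length(kept) + 1L]] <- if (keep_all) batch else
        batch[batch$selected, ]
      n_kept <- n_kept + sum(keep)
      if (total > 5e6 && n_kept == 0L) {
        stop("selection acceptance rate below 1e-4; relax R_thr or Delta")
      }
    }
    out <- dplyr::bind_rows(kept)
    if (!keep_all) {
      out <- out[seq_len(n), ]
    } else {
      # trim to the batch containing the n-th selected individual
      cum <- cumsum(out$selected)
      out <- out[seq_len(which(cum == n)[1L]), ]
    }
    out$id <- sprintf("ind%04d", seq_len(nrow(out)))
    add_repeat_statistics(
      out[, c("id", "cag", "onset", "residual", "allele_a", "allele_b",
              "qtr_a", "qtr_b", "str_a", "str_b", "marker_dosage",
              "selected")])
  })
}

#' Coupled reads + cohort fixture
#'
#' Simulates a cohort, then per-individual read sets over the true
#' haplotype sequences, so the caller's genotype table can feed the
#' association machinery directly. The default size (n = 60) keeps
#' end-to-end tests fast.
#'
#' @param seed Integer seed.
#' @param n Number of individuals.
#' @param locus A [repeat_locus()].
#' @param coverage,error_rate,read_length Passed to [simulate_reads()].
#' @param ... Passed to [simulate_cohort()].
#' @return A list: `cohort` (truth table), `reads` (tibble with a `sample`
#'   column), `locus`.
#' @export
end_to_end_fixture <- function(seed = 1L, n = 60L, locus = repeat_locus(),
                               coverage = 30, error_rate = 0,
                               read_length = 75L, ...) {
  cohort <- simulate_cohort(n = n, locus = locus, seed = seed, ...)
  haps <- stats::setNames(
    lapply(allele_inventory(locus)$name, build_allele_sequence,
           locus = locus),
    allele_inventory(locus)$name)
  reads <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    rd <- simulate_reads(haps[[cohort$allele_a[i]]],
                         haps[[cohort$allele_b[i]]],
                         read_length = read_length, coverage = coverage,
                         error_rate = error_rate,
                         seed = .derive_seed(seed, i),
                         sample = cohort$id[i])
    rd$sample <- cohort$id[i]
    rd
  })
  list(cohort = cohort, reads = reads, locus = locus)
}
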