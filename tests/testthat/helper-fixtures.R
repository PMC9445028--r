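# Shared fixtures: the default locus and the eight built-in haplotypes are
# deterministic, so build them once per test run.
fx_locus <- repeat_locus()
fx_inv <- allele_inventory(fx_locus)
fx_haps <- stats::setNames(
  lapply(fx_inv$name, build_allele_sequence, locus = fx_locus),
  fx_inv$name)

# Random nucleotide string.
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Independent brute-force minimum mismatch error: enumerate every chain of
# up to three candidate pieces (maximal diagonal runs of length >= seed_len)
# and score it by walking the junctions from the definition of the error
# function, with overlaps resolved by the balanced split that minimises the
# gap penalty. Used as the oracle for the path search.
oracle_min_error <- function(read, win, seed_len = 5L, max_gaps = 2L) {
  n <- nchar(read)
  hit <- regexpr(read, win, fixed = TRUE)
  pieces <- build_match_matrix(read, win)$pieces
  pieces <- pieces[pieces$length >= seed_len, ]
  np <- nrow(pieces)
  best <- if (hit[1] != -1L) 0 else Inf
  if (np == 0L) return(best)
  chain_cost <- function(ch) {
    ps <- pieces[ch, , drop = FALSE]
    m <- ps$read_start[1L] - 1L
    pen <- 0
    gaps <- 0L
    left_len <- ps$length[1L]
    for (t in seq_len(nrow(ps))[-1L]) {
      re <- ps$read_end[t - 1L]; fe <- ps$ref_end[t - 1L]
      if (ps$read_end[t] <= re || ps$ref_end[t] <= fe) return(Inf)
      dr <- ps$read_start[t] - re - 1L
      dg <- ps$ref_start[t] - fe - 1L
      tt <- max(0L, -dr, -dg)
      a_lo <- max(0L, tt - ps$length[t] + 1L)
      a_hi <- min(tt, left_len - 1L)
      if (a_lo > a_hi) return(Inf)
      dr2 <- dr + tt; dg2 <- dg + tt
      m <- m + min(dr2, dg2)
      delta <- abs(dg2 - dr2)
      if (delta > 0L) {
        gaps <- gaps + 1L
        if (gaps > max_gaps) return(Inf)
        a_star <- (left_len - ps$length[t] + tt) / 2
        a_cand <- unique(pmin(pmax(c(floor(a_star), ceiling(a_star),
                                     0L, tt), a_lo), a_hi))
        l_cand <- pmin(left_len - a_cand, ps$length[t] - (tt - a_cand))
        l <- max(l_cand)
        a <- a_cand[which.max(l_cand)]
        pen <- pen + delta * exp(5 - l)
        left_len <- ps$length[t] - (tt - a)
      } else {
        left_len <- ps$length[t]
      }
    }
    m + (n - ps$read_end[nrow(ps)]) + pen
  }
  idx <- seq_len(np)
  for (i in idx) best <- min(best, chain_cost(i))
  if (np >= 2L) {
    for (i in idx) for (j in idx) {
      if (i == j) next
      best <- min(best, chain_cost(c(i, j)))
    }
  }
  if (np >= 3L && np <= 14L) {
    for (i in idx) for (j in idx) for (k in idx) {
      if (length(unique(c(i, j, k))) < 3L) next
      best <- min(best, chain_cost(c(i, j, k)))
    }
  }
  best
}
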