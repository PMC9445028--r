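# Match-matrix alignment of a single read against a reference window, scored
# by the mismatch-error function M = m + sum_i Delta_i * exp(5 - l_i).
# Candidate alignment pieces are maximal exact diagonal runs of the match
# matrix; a path chains pieces left to right, charging substitutions (m) for
# uncovered read bases on an unchanged diagonal and a length-discounted gap
# penalty for each diagonal jump. The exponential discount means a gap
# flanked by long exact pieces costs almost nothing, which is what lets a
# 75 bp read vote for a multi-unit repeat indel it spans.

#' Mismatch error of an alignment path
#'
#' Computes `M = m + sum_i Delta_i * exp(5 - l_i)`, where `m` is the number
#' of mismatching nucleotides on the path, `Delta_i` is the height of the
#' i-th gap (bases jumped between the diagonals of the adjoining match
#' pieces) and `l_i` is the shorter of the two adjoining pieces. No capping
#' or rescaling is applied.
#'
#' @param m Non-negative mismatch count.
#' @param gaps Gaps as a list of `c(delta, l)` pairs, or a data frame /
#'   matrix with columns `delta` and `l`. Empty for a gapless path.
#' @return The mismatch error, a non-negative number.
#' @examples
#' mismatch_error(2, list())                 # 2
#' mismatch_error(0, list(c(18, 36)))        # 6.2e-13
#' @export
mismatch_error <- function(m, gaps = list()) {
  if (length(m) != 1L || is.na(m) || m < 0) stop("m must be a single value >= 0")
  if (is.matrix(gaps) || is.data.frame(gaps)) {
    gaps <- asplit(as.matrix(gaps[, c("delta", "l"), drop = FALSE]), 1)
  }
  if (length(gaps) == 0L) return(as.numeric(m))
  delta <- vapply(gaps, function(g) as.numeric(g[[1]]), numeric(1))
  l <- vapply(gaps, function(g) as.numeric(g[[2]]), numeric(1))
  if (any(delta < 1) || any(l < 1)) stop("each gap needs delta >= 1 and l >= 1")
  as.numeric(m) + sum(delta * exp(5 - l))
}

# Integer codes for a nucleotide string (fast equality comparisons).
.seq_int <- function(s) utf8ToInt(s)

#' Build the match matrix between a read and a reference window
#'
#' Cell (i, j) is `TRUE` iff base i of the read equals base j of the
#' reference window. The matrix is summarised as its maximal exact diagonal
#' runs, the candidate match pieces of the path search.
#'
#' @param read,ref_window Nonempty nucleotide strings.
#' @param min_run Minimum run length to report as a candidate piece.
#' @return A list with `matrix` (logical, read x reference) and `pieces`
#'   (tibble: `read_start`, `read_end`, `ref_start`, `ref_end`, `length`,
#'   `offset` where `offset = ref_start - read_start` indexes the diagonal).
#' @export
build_match_matrix <- function(read, ref_window, min_run = 1L) {
  if (!nzchar(read) || !nzchar(ref_window)) stop("sequences must be nonempty")
  M <- outer(.seq_int(read), .seq_int(ref_window), "==")
  list(matrix = M, pieces = .diagonal_runs(M, min_run))
}

# Maximal diagonal runs of TRUE cells, as a tibble sorted by read_end.
.diagonal_runs <- function(M, min_run = 1L) {
  hits <- which(M, arr.ind = TRUE)
  if (nrow(hits) == 0L) {
    return(tibble::new_tibble(
      list(read_start = integer(), read_end = integer(),
           ref_start = integer(), ref_end = integer(),
           length = integer(), offset = integer()), nrow = 0L))
  }
  d <- hits[, 2L] - hits[, 1L]
  o <- order(d, hits[, 1L])
  row <- hits[o, 1L]; dd <- d[o]
  new_run <- c(TRUE, diff(dd) != 0L | diff(row) != 1L)
  run_id <- cumsum(new_run)
  rs <- row[new_run]
  len <- tabulate(run_id)
  off <- dd[new_run]
  keep <- len >= min_run
  read_start <- as.integer(rs[keep])
  length <- as.integer(len[keep])
  offset <- as.integer(off[keep])
  read_end <- read_start + length - 1L
  ref_start <- read_start + offset
  ref_end <- read_end + offset
  o2 <- order(read_end, ref_end)
  tibble::new_tibble(list(
    read_start = read_start[o2], read_end = read_end[o2],
    ref_start = ref_start[o2], ref_end = ref_end[o2],
    length = length[o2], offset = offset[o2]), nrow = sum(keep))
}

#' Classify the gap between two adjoining match pieces
#'
#' With the diagonal offset defined as `ref_start - read_start`, an offset
#' increase from the left to the right piece means reference bases were
#' skipped (a deletion in the read relative to the reference); an offset
#' decrease means extra read bases (an insertion). The gap height `delta`
#' is the absolute offset difference and `l` the shorter piece length.
#'
#' @param left_piece,right_piece Lists or one-row data frames with fields
#'   `read_start`, `ref_start` and `length`, ordered in read coordinates.
#' @return A list with `kind` ("deletion" or "insertion"), `delta` and `l`.
#' @export
classify_gap <- function(left_piece, right_piece) {
  off <- function(p) as.integer(p[["ref_start"]]) - as.integer(p[["read_start"]])
  o1 <- off(left_piece); o2 <- off(right_piece)
  if (o1 == o2) stop("pieces lie on the same diagonal: no gap")
  list(kind = if (o2 > o1) "deletion" else "insertion",
       delta = abs(o2 - o1),
       l = min(as.integer(left_piece[["length"]]),
               as.integer(right_piece[["length"]])))
}

.unalignable_path <- function(reason) {
  structure(list(unalignable = TRUE, reason = reason,
                 pieces = NULL, gaps = NULL, m = NA_integer_, M = Inf),
            class = "alignment_path")
}

.path_obj <- function(pieces, gaps, m, M) {
  structure(list(unalignable = FALSE, pieces = pieces, gaps = gaps,
                 m = as.integer(m), M = M, n_gaps = nrow(gaps)),
            class = "alignment_path")
}

#' @export
print.alignment_path <- function(x, ...) {
  if (x$unalignable) {
    cat("<alignment_path> unalignable:", x$reason, "\n")
    return(invisible(x))
  }
  cat("<alignment_path> M =", format(x$M), " m =", x$m,
      " gaps =", x$n_gaps, "\n")
  print(x$pieces)
  if (nrow(x$gaps)) print(x$gaps)
  invisible(x)
}

# Relative comparison of mismatch errors. Penalty terms span many orders of
# magnitude (exp(5 - l) is ~1e-13 for l = 36), so equality must be judged
# relative to the magnitudes involved; all terms are nonnegative, hence no
# cancellation. Exact ties (periodic placements of the same path shape)
# produce identical arithmetic and compare equal.
.m_lt <- function(a, b) a < b * (1 - 1e-14) - 1e-300
.m_eq <- function(a, b) !.m_lt(a, b) && !.m_lt(b, a)

# Transition geometry between candidate pieces P -> Q. Overlap in read or
# reference coordinates is resolved by trimming t = max(0, -dr, -dg) bases
# in total from P's end and/or Q's start; only the total matters for the
# resulting (dr, dg), so the split is chosen to maximise min(l_left,
# l_right), the quantity the gap penalty discounts. Returns NULL when no
# feasible split exists.
.transition <- function(p_len, p_read_end, p_ref_end,
                        q_len, q_read_start, q_ref_start) {
  dr <- q_read_start - p_read_end - 1L
  dg <- q_ref_start - p_ref_end - 1L
  t <- max(0L, -dr, -dg)
  if (t > p_len + q_len - 2L) return(NULL)
  dr <- dr + t; dg <- dg + t
  if (dr == dg) {
    return(list(m_add = dr, delta = 0L, l = NA_integer_, a = t, u = 0L,
                penalty = 0))
  }
  delta <- abs(dg - dr)
  m_add <- min(dr, dg)
  # balanced split: a from P's end, u = t - a from Q's start
  a_star <- (p_len - q_len + t) / 2
  a_cand <- unique(base::pmin(base::pmax(c(floor(a_star), ceiling(a_star), 0L, t), 0L), t))
  a_cand <- a_cand[p_len - a_cand >= 1L & q_len - (t - a_cand) >= 1L]
  if (length(a_cand) == 0L) return(NULL)
  l_cand <- base::pmin(p_len - a_cand, q_len - (t - a_cand))
  best <- which.max(l_cand)
  a <- a_cand[best]
  l <- l_cand[best]
  list(m_add = m_add, delta = delta, l = l, a = a, u = t - a,
       penalty = delta * exp(5 - l))
}

#' Find the minimum mismatch-error alignment path
#'
#' Aligns a read to a reference window by dynamic programming over the
#' maximal diagonal runs of the match matrix, minimising the mismatch error
#' `M = m + sum Delta_i exp(5 - l_i)`. Read bases not covered by any piece
#' (before the first, after the last, or between pieces on one diagonal)
#' are charged to `m`. Pieces overlapping in read or reference coordinates
#' are resolved at each junction by the split maximising `min(l_left,
#' l_right)`, i.e. minimising the gap penalty; the DP keeps a small Pareto
#' front of (error, gap count, remaining piece length) states per piece so
#' the search is exact for this cost model. Ties are broken by fewer gaps,
#' then by leftmost reference placement. Indel signatures in `gaps` are
#' reported at the leftmost equivalent reference position.
#'
#' @param read,ref_window Nucleotide strings.
#' @param max_gaps Maximum number of gaps in a path.
#' @param seed_length Minimum length of a candidate match piece.
#' @param min_read Reads shorter than this are flagged unalignable.
#' @param max_pieces Cap on candidate pieces (longest kept).
#' @return An `alignment_path`: tibbles `pieces` and `gaps` (columns `kind`,
#'   `delta`, `l`, `ref_start`, `ref_end`, `ins_seq`), mismatch count `m`
#'   and error `M`. If no piece seeds, a path with `unalignable = TRUE`.
#' @export
find_min_error_path <- function(read, ref_window, max_gaps = 3L,
                                seed_length = 8L, min_read = 20L,
                                max_pieces = 400L) {
  n <- nchar(read)
  if (n < min_read) return(.unalignable_path("read shorter than minimum"))
  if (max_gaps < 0L) stop("max_gaps must be >= 0")
  # exact substring: gapless perfect path at the leftmost placement
  hit <- regexpr(read, ref_window, fixed = TRUE)
  if (hit[1] != -1L) {
    p <- tibble::tibble(read_start = 1L, read_end = n,
                        ref_start = as.integer(hit[1]),
                        ref_end = as.integer(hit[1]) + n - 1L,
                        length = n, offset = as.integer(hit[1]) - 1L)
    return(.path_obj(p, .empty_gaps(), 0L, 0))
  }
  pieces <- .diagonal_runs(
    outer(.seq_int(read), .seq_int(ref_window), "=="), seed_length)
  if (nrow(pieces) == 0L) return(.unalignable_path("no seed match"))
  if (nrow(pieces) > max_pieces) {
    keep <- order(pieces$length, decreasing = TRUE)[seq_len(max_pieces)]
    pieces <- pieces[sort(keep), ]
  }
  np <- nrow(pieces)
  rs <- pieces$read_start; re <- pieces$read_end
  fs <- pieces$ref_start; fe <- pieces$ref_end; ln <- pieces$length
  max_states <- 4L
  # flat state arrays; state k lives on piece st_piece[k]
  cap <- np * max_states + np
  st_piece <- integer(cap); st_M <- numeric(cap); st_gaps <- integer(cap)
  st_len <- integer(cap); st_u <- integer(cap); st_fr <- integer(cap)
  st_prev <- integer(cap)
  ns <- 0L
  add_state <- function(piece, M, gaps, len, u, fr, prev) {
    ns <<- ns + 1L
    st_piece[ns] <<- piece; st_M[ns] <<- M; st_gaps[ns] <<- gaps
    st_len[ns] <<- len; st_u[ns] <<- u; st_fr[ns] <<- fr; st_prev[ns] <<- prev
  }
  ub <- min(rs - 1 + n - re)           # best single-piece path
  for (j in seq_len(np)) {
    j_states <- 0L
    if (j > 1L) {
      ks <- seq_len(ns)
      pc <- st_piece[ks]
      ok <- re[pc] < re[j] & fe[pc] < fe[j] & !.m_lt(ub, st_M[ks])
      ks <- ks[ok]
      if (length(ks)) {
        pc <- st_piece[ks]
        p_len <- st_len[ks]
        dr <- rs[j] - re[pc] - 1L
        dg <- fs[j] - fe[pc] - 1L
        t <- base::pmax(0L, -dr, -dg)
        a_lo <- base::pmax(0L, t - ln[j] + 1L)
        a_hi <- base::pmin(t, p_len - 1L)
        feas <- a_lo <= a_hi
        dr2 <- dr + t; dg2 <- dg + t
        delta <- abs(dg2 - dr2)
        m_add <- base::pmin(dr2, dg2)
        gp <- st_gaps[ks] + (delta > 0L)
        a_star <- (p_len - ln[j] + t) / 2
        a1 <- base::pmin(base::pmax(floor(a_star), a_lo), a_hi)
        a2 <- base::pmin(base::pmax(ceiling(a_star), a_lo), a_hi)
        l1 <- base::pmin(p_len - a1, ln[j] - (t - a1))
        l2 <- base::pmin(p_len - a2, ln[j] - (t - a2))
        use2 <- l2 > l1
        a_b <- ifelse(use2, a2, a1)
        l_b <- base::pmax(l1, l2)
        pen <- ifelse(delta > 0L, delta * exp(5 - l_b), 0)
        candM <- st_M[ks] + m_add + pen
        keep <- feas & gp <= max_gaps & !.m_lt(ub, candM)
        if (any(keep)) {
          ki <- ks[keep]
          o <- order(candM[keep], gp[keep], st_fr[ki])
          o <- o[seq_len(min(length(o), 12L))]
          cM <- candM[keep][o]; cG <- gp[keep][o]
          cU <- (t - a_b)[keep][o]; cL <- (ln[j] - (t - a_b))[keep][o]
          cF <- st_fr[ki][o]; cP <- ki[o]
          accM <- numeric(0); accG <- integer(0); accL <- integer(0)
          accF <- integer(0)
          for (z in seq_along(o)) {
            dominated <- FALSE
            if (length(accM)) {
              dominated <- any(!.m_lt(cM[z], accM) & accG <= cG[z] &
                                 accL >= cL[z] & accF <= cF[z])
            }
            if (dominated) next
            add_state(j, cM[z], cG[z], cL[z], cU[z], cF[z], cP[z])
            j_states <- j_states + 1L
            accM <- c(accM, cM[z]); accG <- c(accG, cG[z])
            accL <- c(accL, cL[z]); accF <- c(accF, cF[z])
            if (j_states >= max_states) break
          }
        }
      }
    }
    add_state(j, rs[j] - 1, 0L, ln[j], 0L, fs[j] - (rs[j] - 1L), 0L)
    lastk <- seq.int(ns - j_states, ns)
    ub <- min(ub, min(st_M[lastk]) + (n - re[j]))
  }
  ks <- seq_len(ns)
  total <- st_M[ks] + (n - re[st_piece[ks]])
  best_k <- 1L
  for (k in ks[-1L]) {
    better <- .m_lt(total[k], total[best_k]) ||
      (.m_eq(total[k], total[best_k]) &&
         (st_gaps[k] < st_gaps[best_k] ||
            (st_gaps[k] == st_gaps[best_k] && st_fr[k] < st_fr[best_k])))
    if (better) best_k <- k
  }
  chain <- list()
  k <- best_k
  while (k != 0L) {
    chain <- c(list(list(piece = st_piece[k], st_len = st_len[k],
                         u = st_u[k])), chain)
    k <- st_prev[k]
  }
  .assemble_path(read, pieces, chain, n)
}

.empty_gaps <- function() {
  tibble::tibble(kind = character(), delta = integer(), l = integer(),
                 ref_start = integer(), ref_end = integer(),
                 ins_seq = character())
}

# Walk the chosen chain, re-deriving each junction's trims from the stored
# states, and build the reported path: trimmed (non-overlapping) pieces plus
# gap records with leftmost-normalized indel signatures. M is re-derived
# from (m, gaps) so the reported error is exactly mismatch_error(m, gaps).
.assemble_path <- function(read, pieces, chain, n) {
  k <- length(chain)
  idxs <- vapply(chain, `[[`, integer(1), "piece")
  ps <- pieces$read_start[idxs]; pe <- pieces$read_end[idxs]
  gs <- pieces$ref_start[idxs]; ge <- pieces$ref_end[idxs]
  ln <- pieces$length[idxs]
  m <- ps[1L] - 1L
  gaps <- .empty_gaps()
  if (k > 1L) {
    for (idx in 2:k) {
      i <- idx - 1L
      left_len <- chain[[i]]$st_len                 # length after start trim
      tr <- .transition(left_len, pe[i], ge[i], ln[idx], ps[idx], gs[idx])
      m <- m + tr$m_add
      rp_start <- ps[idx]; rp_ref_start <- gs[idx]  # untrimmed, for signature
      pe[i] <- pe[i] - tr$a; ge[i] <- ge[i] - tr$a
      ps[idx] <- ps[idx] + tr$u; gs[idx] <- gs[idx] + tr$u
      if (tr$delta > 0L) {
        if (gs[idx] - ge[i] > ps[idx] - pe[i]) {
          kind <- "deletion"
          sig_start <- rp_ref_start - tr$delta
          sig_end <- rp_ref_start - 1L
          ins <- NA_character_
        } else {
          kind <- "insertion"
          sig_start <- rp_ref_start
          sig_end <- rp_ref_start
          ins <- substr(read, rp_start - tr$delta, rp_start - 1L)
        }
        gaps <- rbind(gaps, tibble::tibble(
          kind = kind, delta = as.integer(tr$delta), l = as.integer(tr$l),
          ref_start = as.integer(sig_start), ref_end = as.integer(sig_end),
          ins_seq = ins))
      }
    }
  }
  m <- m + (n - pe[k])
  out <- tibble::tibble(read_start = ps, read_end = pe,
                        ref_start = gs, ref_end = ge,
                        length = pe - ps + 1L, offset = gs - ps)
  M <- mismatch_error(m, gaps)
  .path_obj(out, gaps, m, M)
}

#' Dump a match matrix to TSV for inspection
#'
#' Writes the read-by-reference match matrix as tab-separated 0/1 values
#' with base labels, a debugging aid for unexpected alignment paths.
#'
#' @param read,ref_window Nucleotide strings.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
dump_match_matrix <- function(read, ref_window, path) {
  mm <- build_match_matrix(read, ref_window)$matrix
  df <- as.data.frame(mm * 1L)
  colnames(df) <- paste0(strsplit(ref_window, "")[[1]],
                         seq_len(nchar(ref_window)))
  rownames(df) <- paste0(strsplit(read, "")[[1]], seq_len(nchar(read)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
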