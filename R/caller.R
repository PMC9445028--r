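# Diploid QTR/STR genotype calling from reads localized to the repeat locus:
# (i) align single reads to the reference window, (ii) drop badly aligned
# reads, (iii) enumerate candidate haplotypes from observed indel
# signatures, (iv) realign every read to every candidate and keep the best,
# (v) resolve ambiguous reads with their mates, (vi) split reads into two
# groups over discordant columns of an asterisk-padded multiple alignment,
# (vii) optionally borrow confirmed candidates from other samples.

#' Caller configuration
#'
#' Thresholds for the genotyping pipeline. `m_max` is the step-(ii)
#' bad-alignment cutoff on the mismatch error; `min_support` the minimum
#' reads per allele group; `min_depth` the minimum informative depth for a
#' call; `min_anchor` the minimum read length the aligner will attempt.
#'
#' @param seed_length Minimum match-piece length for the path search.
#' @param max_gaps Maximum gaps per read alignment.
#' @param m_max Discard reads whose best mismatch error exceeds this.
#' @param min_anchor Minimum alignable read length.
#' @param min_support Minimum reads supporting an allele group.
#' @param min_depth Minimum tract-overlapping reads for a call.
#' @param max_candidates Cap on enumerated candidate haplotypes.
#' @return A list of class `call_config`.
#' @export
call_config <- function(seed_length = 8L, max_gaps = 3L, m_max = 5,
                        min_anchor = 20L, min_support = 3L, min_depth = 10L,
                        max_candidates = 64L) {
  structure(list(seed_length = as.integer(seed_length),
                 max_gaps = as.integer(max_gaps), m_max = m_max,
                 min_anchor = as.integer(min_anchor),
                 min_support = as.integer(min_support),
                 min_depth = as.integer(min_depth),
                 max_candidates = as.integer(max_candidates)),
            class = "call_config")
}

# Minimum gapless mismatch count of `read` over all full placements inside
# `subject`, by counting matches per diagonal of the match matrix.
.gapless_min_m <- function(read_int, subject_int) {
  nr <- length(read_int); nc <- length(subject_int)
  if (nc < nr) return(Inf)
  M <- outer(read_int, subject_int, "==")
  hits <- which(M, arr.ind = TRUE)
  d <- hits[, 2L] - hits[, 1L]            # diagonal 0 .. nc-1 valid: 0..nc-nr
  d <- d[d >= 0L & d <= nc - nr]
  if (length(d) == 0L) return(nr)
  nr - max(tabulate(d + 1L, nbins = nc - nr + 1L))
}

# Gapless scan: best full placement of the read inside the subject with
# its mismatch count (Inf if the subject is shorter than the read).
.gapless_scan <- function(read_int, subject_int) {
  nr <- length(read_int); nc <- length(subject_int)
  if (nc < nr) return(list(m = Inf, start = NA_integer_))
  hits <- which(outer(read_int, subject_int, "=="), arr.ind = TRUE)
  d <- hits[, 2L] - hits[, 1L]
  d <- d[d >= 0L & d <= nc - nr]
  if (length(d) == 0L) return(list(m = nr, start = 1L, nbest = 1L))
  tb <- tabulate(d + 1L, nbins = nc - nr + 1L)
  list(m = nr - max(tb), start = which.max(tb),
       nbest = sum(tb == max(tb)))
}

# Signature of an alignment path: canonical string and op table.
.path_signature <- function(path) {
  if (path$unalignable || nrow(path$gaps) == 0L) return(NULL)
  g <- path$gaps
  key <- paste(g$kind, g$ref_start, g$delta,
               ifelse(is.na(g$ins_seq), "", g$ins_seq),
               sep = ":", collapse = ";")
  list(key = key, ops = g)
}

# Apply a table of indel ops (columns kind, ref_start, delta, ins_seq) to a
# reference window string.
.apply_signature <- function(ref_window, ops) {
  if (is.null(ops) || nrow(ops) == 0L) return(ref_window)
  ops <- ops[order(ops$ref_start, decreasing = TRUE), ]
  s <- ref_window
  for (i in seq_len(nrow(ops))) {
    p <- ops$ref_start[i]
    if (ops$kind[i] == "deletion") {
      s <- paste0(substr(s, 1L, p - 1L), substr(s, p + ops$delta[i], nchar(s)))
    } else {
      s <- paste0(substr(s, 1L, p - 1L), ops$ins_seq[i],
                  substr(s, p, nchar(s)))
    }
  }
  s
}

# Do two signatures touch overlapping reference intervals?
.sigs_compatible <- function(ops_a, ops_b) {
  span <- function(o) cbind(o$ref_start,
                            ifelse(o$kind == "deletion",
                                   o$ref_start + o$delta - 1L, o$ref_start))
  sa <- span(ops_a); sb <- span(ops_b)
  for (i in seq_len(nrow(sa))) {
    if (any(sa[i, 1L] <= sb[, 2L] & sb[, 1L] <= sa[i, 2L])) return(FALSE)
  }
  TRUE
}

#' Enumerate candidate haplotypes from single-read alignments
#'
#' Collects the distinct indel signatures observed in per-read alignment
#' paths and builds candidate haplotype sequences: the reference window,
#' each observed signature, and unions of compatible (non-overlapping)
#' signatures. Candidates are deduplicated by sequence and canonically
#' ordered (reference first, then by total indel length, then by signature
#' string), which fixes tie-breaking downstream.
#'
#' @param paths List of `alignment_path` objects from reads at the locus
#'   (`NULL` entries stand for reads aligned without indel evidence).
#' @param ref_window Reference window string the paths were computed on.
#' @param max_candidates Cap on the number of candidates.
#' @return A tibble: `key`, `sequence`, `n_ops`, `indel_bases`, with the
#'   op tables in the `ops` list column (`NULL` for the reference).
#' @export
enumerate_candidates <- function(paths, ref_window, max_candidates = 64L) {
  sigs <- list()
  support <- integer(0)
  for (p in paths) {
    sg <- if (is.null(p)) NULL else .path_signature(p)
    if (is.null(sg)) next
    if (is.null(sigs[[sg$key]])) {
      sigs[[sg$key]] <- sg$ops
      support[sg$key] <- 0L
    }
    support[sg$key] <- support[sg$key] + 1L
    # single-gap sub-signatures of multi-gap reads are candidates too
    if (nrow(sg$ops) > 1L) {
      for (r in seq_len(nrow(sg$ops))) {
        sub <- sg$ops[r, ]
        k <- paste(sub$kind, sub$ref_start, sub$delta,
                   ifelse(is.na(sub$ins_seq), "", sub$ins_seq), sep = ":")
        if (is.null(sigs[[k]])) { sigs[[k]] <- sub; support[k] <- 0L }
      }
    }
  }
  if (length(sigs) == 0L) {
    if (length(paths) == 0L) warning("no reads: reference-only candidate set")
    return(tibble::tibble(key = "ref", sequence = ref_window, n_ops = 0L,
                          indel_bases = 0L, ops = list(NULL)))
  }
  # prefer well-supported signatures when capping
  ord <- order(-support, names(sigs))
  sigs <- sigs[ord]
  if (length(sigs) > 8L) sigs <- sigs[seq_len(8L)]
  # unions of pairwise-compatible signatures (sizes 2..3)
  combos <- sigs
  keys <- names(sigs)
  if (length(sigs) >= 2L) {
    for (i in seq_len(length(sigs) - 1L)) {
      for (j in (i + 1L):length(sigs)) {
        if (!.sigs_compatible(sigs[[i]], sigs[[j]])) next
        k2 <- paste(keys[i], keys[j], sep = ";")
        combos[[k2]] <- rbind(sigs[[i]], sigs[[j]])
        if (length(combos) >= max_candidates) break
      }
      if (length(combos) >= max_candidates) break
    }
  }
  seqs <- vapply(combos, .apply_signature, character(1),
                 ref_window = ref_window)
  out <- tibble::tibble(
    key = c("ref", names(combos)),
    sequence = c(ref_window, unname(seqs)),
    n_ops = c(0L, vapply(combos, nrow, integer(1))),
    indel_bases = c(0L, vapply(combos, function(o) sum(o$delta), integer(1))),
    ops = c(list(NULL), unname(combos)))
  out <- out[!duplicated(out$sequence), ]
  # canonical order: reference first, then parsimony (fewest ops), then
  # total indel length, then signature string
  out <- out[order(out$n_ops, out$indel_bases, out$key), ]
  out[seq_len(min(nrow(out), max_candidates)), ]
}

# Alignment summary of one read against one candidate: gapless placement
# (start, m) when one exists within m_max mismatches, otherwise the DP path.
.read_vs_candidate <- function(seq, seq_int, cand, cand_int, config) {
  hit <- regexpr(seq, cand, fixed = TRUE)
  if (hit[1] != -1L) {
    return(list(M = 0, m = 0L, start = as.integer(hit[1]), gapless = TRUE,
                path = NULL))
  }
  m <- .gapless_min_m(seq_int, cand_int)
  if (is.finite(m) && m <= 2L) {
    # locate the best gapless placement
    M <- outer(seq_int, cand_int, "==")
    hits <- which(M, arr.ind = TRUE)
    d <- hits[, 2L] - hits[, 1L]
    ok <- d >= 0L & d <= length(cand_int) - length(seq_int)
    tb <- tabulate(d[ok] + 1L, nbins = length(cand_int) - length(seq_int) + 1L)
    start <- which.max(tb)
    return(list(M = as.numeric(m), m = as.integer(m),
                start = as.integer(start), gapless = TRUE, path = NULL))
  }
  p <- find_min_error_path(seq, cand, max_gaps = config$max_gaps,
                           seed_length = config$seed_length,
                           min_read = config$min_anchor)
  if (p$unalignable) {
    return(list(M = Inf, m = NA_integer_, start = NA_integer_,
                gapless = FALSE, path = p))
  }
  list(M = p$M, m = p$m,
       start = as.integer(p$pieces$ref_start[1L] -
                            (p$pieces$read_start[1L] - 1L)),
       gapless = nrow(p$gaps) == 0L, path = p)
}

#' Realign reads to candidate haplotypes and select the best
#'
#' Each read is assigned the candidate minimising its mismatch error; exact
#' ties go to the reference, then to the candidate with the smallest indel
#' signature (the canonical candidate order), and are flagged ambiguous.
#'
#' @param reads Tibble with columns `read_id`, `mate`, `seq`.
#' @param candidates Candidate tibble from [enumerate_candidates()].
#' @param config A [call_config()].
#' @return Tibble: `read_id`, `mate`, `seq`, `cand` (row index into
#'   `candidates`), `M`, `m`, `start` (1-based placement on the candidate),
#'   `gapless`, `tied` (ambiguous), `tied_with` (list of tied candidate
#'   indices).
#' @export
realign_and_select <- function(reads, candidates, config = call_config()) {
  mats <- .realign_matrices(reads, candidates, config)
  out <- .select_from_matrices(reads, mats, seq_len(nrow(candidates)))
  attr(out, "matrices") <- mats
  out
}

# Full per-read-per-candidate alignment summaries. When a read has an exact
# substring hit on some candidate, other candidates' entries are Inf: no
# gapped path can reach M = 0, so ranking and exact ties are unaffected.
.realign_matrices <- function(reads, candidates, config) {
  cand_seqs <- candidates$sequence
  cand_ints <- lapply(cand_seqs, .seq_int)
  nc <- length(cand_seqs)
  nr <- nrow(reads)
  M <- matrix(Inf, nr, nc)
  St <- matrix(NA_integer_, nr, nc)
  mm <- matrix(NA_integer_, nr, nc)
  gp <- matrix(TRUE, nr, nc)
  pt <- matrix(FALSE, nr, nc)           # placement within candidate ambiguous
  for (i in seq_len(nr)) {
    seq <- reads$seq[i]
    subs <- vapply(cand_seqs, function(cs) regexpr(seq, cs, fixed = TRUE)[1],
                   numeric(1))
    if (any(subs != -1L)) {
      hitk <- which(subs != -1L)
      M[i, hitk] <- 0
      St[i, hitk] <- as.integer(subs[hitk])
      mm[i, hitk] <- 0L
    } else {
      si <- .seq_int(seq)
      scans <- lapply(cand_ints, function(ci) .gapless_scan(si, ci))
      gm <- vapply(scans, `[[`, numeric(1), "m")
      if (min(gm) <= 2) {
        # some candidate explains the read as a near-exact gapless match
        # (a read with a sequencing error or two); other candidates'
        # gapless mismatch counts are upper bounds that cannot disturb
        # the minimum, so the expensive path search is unnecessary
        for (k in seq_len(nc)) {
          M[i, k] <- gm[k]
          St[i, k] <- scans[[k]]$start
          mm[i, k] <- as.integer(gm[k])
          pt[i, k] <- scans[[k]]$nbest > 1L
        }
      } else {
        for (k in seq_len(nc)) {
          r <- .read_vs_candidate(seq, si, cand_seqs[k], cand_ints[[k]],
                                  config)
          M[i, k] <- r$M; St[i, k] <- r$start
          mm[i, k] <- r$m; gp[i, k] <- r$gapless
        }
      }
    }
  }
  list(M = M, start = St, m = mm, gapless = gp, place_tied = pt)
}

# Tie-broken assignment restricted to the active candidate subset.
.select_from_matrices <- function(reads, mats, active) {
  n <- nrow(reads)
  cand <- integer(n); Mv <- numeric(n); mv <- integer(n)
  st <- integer(n); gp <- logical(n); tied <- logical(n)
  ptv <- logical(n)
  tw <- vector("list", n); tws <- vector("list", n)
  for (i in seq_len(n)) {
    Ms <- mats$M[i, active]
    best <- min(Ms)
    tied_with <- active[!.m_lt(best, Ms)]     # candidate indices, canonical
    k <- tied_with[1L]
    cand[i] <- k; Mv[i] <- mats$M[i, k]; mv[i] <- mats$m[i, k]
    st[i] <- mats$start[i, k]; gp[i] <- mats$gapless[i, k]
    ptv[i] <- mats$place_tied[i, k]
    tied[i] <- length(tied_with) > 1L
    tw[[i]] <- tied_with
    tws[[i]] <- mats$start[i, tied_with]
  }
  tibble::new_tibble(list(
    read_id = reads$read_id, mate = reads$mate, seq = reads$seq,
    cand = cand, M = Mv, m = mv, start = st, gapless = gp,
    tied = tied, tied_with = tw, tied_starts = tws,
    place_tied = ptv), nrow = n)
}

#' Resolve ambiguous reads using their mates
#'
#' A read whose best candidate is tied adopts its mate's candidate when the
#' mate is unambiguous and the mate's candidate is among the read's tied
#' set. Pairs in which both mates are unambiguous but disagree are flagged
#' `conflict` and excluded from allele separation.
#'
#' @param assignments Tibble from [realign_and_select()].
#' @param candidates Candidate tibble; needed to re-place a read on its
#'   adopted candidate.
#' @return The assignments with `cand`, `start`, `tied` updated and a
#'   `conflict` column added.
#' @export
mate_pair_correct <- function(assignments, candidates = NULL) {
  a <- assignments
  a$conflict <- FALSE
  adopt <- function(i, k) {
    # re-place read i on candidate k; only adopt when the placement is
    # unambiguous (an exact or stored gapless hit)
    if (is.null(candidates)) return(FALSE)
    hit <- regexpr(a$seq[i], candidates$sequence[k], fixed = TRUE)
    if (hit[1] == -1L) return(FALSE)
    a$cand[i] <<- k
    a$start[i] <<- as.integer(hit[1])
    a$gapless[i] <<- TRUE
    a$tied[i] <<- FALSE
    TRUE
  }
  for (id in unique(a$read_id[duplicated(a$read_id)])) {
    idx <- which(a$read_id == id)
    if (length(idx) != 2L) next
    t1 <- a$tied[idx[1L]]; t2 <- a$tied[idx[2L]]
    if (t1 && !t2) {
      if (a$cand[idx[2L]] %in% a$tied_with[[idx[1L]]]) {
        adopt(idx[1L], a$cand[idx[2L]])
      }
    } else if (t2 && !t1) {
      if (a$cand[idx[1L]] %in% a$tied_with[[idx[2L]]]) {
        adopt(idx[2L], a$cand[idx[1L]])
      }
    } else if (!t1 && !t2 && a$cand[idx[1L]] != a$cand[idx[2L]]) {
      a$conflict[idx] <- TRUE
    }
  }
  a
}

#' Build the asterisk-padded multiple alignment
#'
#' Expands the reference window by inserting asterisk columns wherever any
#' candidate carries an insertion, and writes each read into this common
#' frame: deleted bases appear as `*` in the read row, insertion columns
#' absent from a read's candidate as `*`, positions the read does not cover
#' as `.`. Removing `*` and `.` from a row reproduces the read exactly, so
#' indels can be treated as substitutions from here on. Reads whose best
#' alignment to their candidate is not gapless cannot be placed and are
#' dropped (counted in `n_dropped`).
#'
#' @param assignments Tibble from [mate_pair_correct()].
#' @param candidates Candidate tibble.
#' @param ref_window Reference window string.
#' @return A list of class `padded_alignment`: `mat` (character matrix,
#'   reads x columns), `expanded_ref`, `col_ref` (reference position of
#'   each column, NA for insertion columns), `col_ins_at` (insertion
#'   anchor), `row_reads` (assignment rows used), `n_dropped`.
#' @export
build_padded_alignment <- function(assignments, candidates, ref_window) {
  W <- nchar(ref_window)
  # insertion blocks: maximum inserted length per anchor position
  ins_w <- integer(0)
  for (ops in candidates$ops) {
    if (is.null(ops)) next
    ins <- ops[ops$kind == "insertion", ]
    for (r in seq_len(nrow(ins))) {
      p <- as.character(ins$ref_start[r])
      w <- nchar(ins$ins_seq[r])
      ins_w[p] <- max(ins_w[p] %||% 0L, w, na.rm = TRUE)
    }
  }
  anchors <- sort(as.integer(names(ins_w)))
  # expanded columns: before reference position p, ins_w[p] asterisk columns
  col_ref <- integer(0); col_ins_at <- integer(0)
  for (p in seq_len(W)) {
    ap <- as.character(p)
    if (!is.na(ins_w[ap]) && p %in% anchors) {
      col_ref <- c(col_ref, rep(NA_integer_, ins_w[ap]))
      col_ins_at <- c(col_ins_at, rep(p, ins_w[ap]))
    }
    col_ref <- c(col_ref, p)
    col_ins_at <- c(col_ins_at, NA_integer_)
  }
  ncol_x <- length(col_ref)
  ref_chars <- strsplit(ref_window, "")[[1]]
  expanded_ref <- ifelse(is.na(col_ref), "*", ref_chars[col_ref])
  # per-candidate map: candidate position -> expanded column (insertions
  # right-aligned within their block so shared unit copies line up)
  cand_map <- lapply(seq_len(nrow(candidates)), function(k) {
    ops <- candidates$ops[[k]]
    map <- integer(nchar(candidates$sequence[k]))
    del <- rep(FALSE, W)
    ins_here <- integer(0)
    if (!is.null(ops)) {
      for (r in seq_len(nrow(ops))) {
        if (ops$kind[r] == "deletion") {
          del[ops$ref_start[r]:(ops$ref_start[r] + ops$delta[r] - 1L)] <- TRUE
        } else {
          ins_here[as.character(ops$ref_start[r])] <- nchar(ops$ins_seq[r])
        }
      }
    }
    base_col <- which(!is.na(col_ref))         # expanded col of ref pos p
    pos <- 0L
    for (p in seq_len(W)) {
      ap <- as.character(p)
      w <- ins_here[ap]
      if (!is.na(w) && length(w) && !is.na(ins_w[ap])) {
        block <- which(!is.na(col_ins_at) & col_ins_at == p)
        use <- block[(length(block) - w + 1L):length(block)]
        map[pos + seq_len(w)] <- use
        pos <- pos + w
      }
      if (!del[p]) {
        pos <- pos + 1L
        map[pos] <- base_col[p]
      }
    }
    map
  })
  placeable <- !is.na(assignments$start) & assignments$gapless
  rows <- assignments[placeable, ]
  rows$ambiguous <- rows$place_tied %||% FALSE
  mat <- matrix(".", nrow = nrow(rows), ncol = ncol_x)
  for (i in seq_len(nrow(rows))) {
    map <- cand_map[[rows$cand[i]]]
    s <- rows$start[i]; L <- nchar(rows$seq[i])
    cols <- map[s:(s + L - 1L)]
    span <- min(cols):max(cols)
    mat[i, span] <- "*"
    mat[i, cols] <- strsplit(rows$seq[i], "")[[1]]
    if (rows$tied[i]) {
      # a tie is harmless when every tied placement writes the read into
      # the same expanded columns (e.g. a candidate and its superset)
      tw <- rows$tied_with[[i]]; tst <- rows$tied_starts[[i]]
      for (z in seq_along(tw)) {
        if (tw[z] == rows$cand[i]) next
        sz <- tst[z]
        if (is.na(sz)) { rows$ambiguous[i] <- TRUE; break }
        cz <- cand_map[[tw[z]]][sz:(sz + L - 1L)]
        if (length(cz) != length(cols) || any(cz != cols)) {
          rows$ambiguous[i] <- TRUE
          break
        }
      }
    }
  }
  structure(list(mat = mat, expanded_ref = expanded_ref, col_ref = col_ref,
                 col_ins_at = col_ins_at, row_reads = rows,
                 n_dropped = sum(!placeable)),
            class = "padded_alignment")
}

#' Separate reads into allele groups over discordant columns
#'
#' Discordant columns are those where at least `min_support` placed reads
#' carry the same non-reference character and those reads make up at
#' least `min_var_frac` of the reads covering the column. Requiring
#' coherent support suppresses sequencing-error columns (errors scatter
#' across bases) while keeping columns whose variant reads are a modest
#' fraction of coverage, as happens for insertions where every
#' junction-spanning read "covers" the block. Reads covering at least one
#' discordant column are greedily clustered so that all reads in a group
#' agree at every discordant column they cover. Two groups with at least
#' `min_support` reads each mean a heterozygote; fewer mean a homozygote.
#' Three or more well-supported incompatible groups raise an error
#' (multiallelic signal or contamination).
#'
#' @param padded A `padded_alignment`.
#' @param min_support Minimum reads per allele group.
#' @param min_var_frac Minimum fraction of covering reads that must differ
#'   for a column to count as discordant.
#' @return A list: `n_groups`, `groups` (list of row indices), `disc_cols`,
#'   `unassigned` (row indices fitting no retained group).
#' @export
separate_alleles <- function(padded, min_support = 3L,
                             min_var_frac = 0.1) {
  mat <- padded$mat
  nr <- nrow(mat)
  covered <- mat != "."
  disc <- which(vapply(seq_len(ncol(mat)), function(j) {
    cv <- covered[, j]
    diff_chars <- mat[cv & mat[, j] != padded$expanded_ref[j], j]
    if (length(diff_chars) == 0L) return(FALSE)
    # coherent evidence: enough reads carrying the *same* variant
    # character; sequencing errors scatter across bases and placements
    mx <- max(tabulate(factor(diff_chars,
                              levels = c("A", "C", "G", "T", "*"))))
    mx >= min_support && mx >= min_var_frac * sum(cv)
  }, logical(1)))
  if (length(disc) == 0L || nr == 0L) {
    return(list(n_groups = 1L, groups = list(seq_len(nr)),
                disc_cols = integer(0), unassigned = integer(0)))
  }
  sub <- mat[, disc, drop = FALSE]
  cov <- covered[, disc, drop = FALSE]
  informative <- which(rowSums(cov) > 0L)
  ord <- informative[order(-rowSums(cov[informative, , drop = FALSE]))]
  protos <- list(); members <- list()
  for (i in ord) {
    placed <- FALSE
    for (g in seq_along(protos)) {
      p <- protos[[g]]
      ok <- TRUE
      for (j in which(cov[i, ])) {
        if (!is.na(p[j]) && p[j] != sub[i, j]) { ok <- FALSE; break }
      }
      if (ok) {
        p[which(cov[i, ] & is.na(p))] <- sub[i, which(cov[i, ] & is.na(p))]
        protos[[g]] <- p
        members[[g]] <- c(members[[g]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      p <- rep(NA_character_, length(disc))
      p[cov[i, ]] <- sub[i, cov[i, ]]
      protos[[length(protos) + 1L]] <- p
      members[[length(members) + 1L]] <- i
    }
  }
  supp <- vapply(members, length, integer(1))
  big <- which(supp >= min_support)
  if (length(big) > 2L) {
    stop("more than two well-supported allele groups at the locus: ",
         "multiallelic signal or contamination")
  }
  if (length(big) == 2L) {
    groups <- members[big]
    unassigned <- setdiff(seq_len(nr), unlist(groups))
    return(list(n_groups = 2L, groups = groups, disc_cols = disc,
                unassigned = unassigned))
  }
  # homozygote (possibly non-reference): keep the dominant group if any
  if (length(big) == 1L) {
    return(list(n_groups = 1L, groups = members[big], disc_cols = disc,
                unassigned = setdiff(seq_len(nr), members[[big]])))
  }
  list(n_groups = 1L, groups = list(seq_len(nr)), disc_cols = disc,
       unassigned = integer(0))
}

# Column-wise majority consensus for a set of padded rows; ties and
# uncovered columns fall back to the expanded reference.
.group_consensus <- function(padded, rows) {
  mat <- padded$mat[rows, , drop = FALSE]
  out <- padded$expanded_ref
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[col != "."]
    if (length(col) == 0L) next
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) > 1L && tab[1L] == tab[2L]) next   # tie -> reference
    out[j] <- names(tab)[1L]
  }
  out
}

# Extract the tract from a consensus over expanded columns.
.consensus_tract <- function(consensus, padded, tract_start, tract_end) {
  in_tract <- (!is.na(padded$col_ref) & padded$col_ref >= tract_start &
                 padded$col_ref <= tract_end) |
    (!is.na(padded$col_ins_at) & padded$col_ins_at >= tract_start &
       padded$col_ins_at <= tract_end + 1L)
  chars <- consensus[in_tract]
  paste(chars[chars != "*"], collapse = "")
}

#' Call the diploid repeat genotype from localized reads
#'
#' Runs the full pipeline: single-read alignment against the reference
#' window, bad-read filtering, candidate-haplotype enumeration,
#' realignment, mate correction, asterisk padding, allele separation and
#' per-group consensus. QTR unit counts come from consensus tract lengths,
#' STR unit counts from the longest pure-unit run.
#'
#' @param reads Tibble with columns `read_id`, `mate`, `seq`.
#' @param locus A [repeat_locus()].
#' @param config A [call_config()].
#' @param sample Sample label attached to the call.
#' @return An object of class `qtr_call`; see [genotype_table()] for the
#'   tidy summary. Alleles are ordered so allele A has the shorter QTR.
#' @export
call_genotype <- function(reads, locus = repeat_locus(),
                          config = call_config(), sample = "sample1") {
  ref_hap <- build_allele_sequence("A1", locus)
  ref_window <- as.character(ref_hap)
  ts <- attr(ref_hap, "tract_start")
  te <- ts + nchar(attr(ref_hap, "tract")) - 1L
  # step (i): discovery alignment against the reference window
  ref_int <- .seq_int(ref_window)
  paths <- vector("list", nrow(reads))
  keep <- rep(TRUE, nrow(reads))
  for (i in seq_len(nrow(reads))) {
    seq <- reads$seq[i]
    hit <- regexpr(seq, ref_window, fixed = TRUE)
    if (hit[1] != -1L) { paths[i] <- list(NULL); next }   # no indel evidence
    m0 <- .gapless_min_m(.seq_int(seq), ref_int)
    if (is.finite(m0) && m0 <= 1L) { paths[i] <- list(NULL); next }
    p <- find_min_error_path(seq, ref_window, max_gaps = config$max_gaps,
                             seed_length = config$seed_length,
                             min_read = config$min_anchor)
    if (p$unalignable || .m_lt(config$m_max, p$M)) {      # step (ii)
      keep[i] <- FALSE
      paths[i] <- list(NULL)
    } else {
      paths[[i]] <- p
    }
  }
  reads2 <- reads[keep, ]
  paths <- paths[keep]
  # steps (iii)-(vi)
  cands <- enumerate_candidates(paths, ref_window, config$max_candidates)
  .finish_call(reads2, cands, locus, config, sample, ref_window, ts, te,
               n_filtered = sum(!keep))
}

# Realignment through genotype assembly, shared by call_genotype() and
# cross_sample_correct().
.finish_call <- function(reads, cands, locus, config, sample, ref_window,
                         ts, te, n_filtered = 0L) {
  # Realign once against the full candidate set, then iteratively
  # eliminate candidates that no unambiguously placed read supports: the
  # periodic repeat structure breeds equivalent-looking spurious
  # signatures whose ties would otherwise fragment read support (this is
  # the collective "other reads" correction). Elimination is pure
  # bookkeeping on the stored alignment matrices.
  assign <- realign_and_select(reads, cands, config)
  mats <- attr(assign, "matrices")
  active <- seq_len(nrow(cands))
  repeat {
    assign <- .select_from_matrices(reads, mats, active)
    assign <- mate_pair_correct(assign, cands)
    ok <- !assign$conflict
    padded <- build_padded_alignment(assign[ok, ], cands, ref_window)
    if (length(active) == 1L) break
    rr <- padded$row_reads
    unamb <- tabulate(rr$cand[!rr$ambiguous], nbins = nrow(cands))
    alln <- tabulate(rr$cand, nbins = nrow(cands))
    zero <- setdiff(active[unamb[active] == 0L], active[1L])
    if (length(zero) == 0L) break
    # drop the weakest: fewest assigned reads, then largest indel load
    drop <- zero[order(alln[zero], -cands$indel_bases[zero])][1L]
    active <- setdiff(active, drop)
  }
  cands <- cands[active, ]
  # re-select against the reduced set so candidate row indices are dense
  assign <- .select_from_matrices(
    reads, list(M = mats$M[, active, drop = FALSE],
                start = mats$start[, active, drop = FALSE],
                m = mats$m[, active, drop = FALSE],
                gapless = mats$gapless[, active, drop = FALSE],
                place_tied = mats$place_tied[, active, drop = FALSE]),
    seq_len(length(active)))
  assign <- mate_pair_correct(assign, cands)
  ok <- !assign$conflict
  padded <- build_padded_alignment(assign[ok, ], cands, ref_window)
  # depth: placed reads overlapping the tract
  base_col <- which(!is.na(padded$col_ref))
  tract_cols <- range(base_col[padded$col_ref[base_col] %in% c(ts, te)])
  depth <- if (nrow(padded$mat) == 0L) 0L else {
    sum(apply(padded$mat != ".", 1L, function(cv) {
      w <- which(cv); length(w) > 0L && w[1L] <= tract_cols[2L] &&
        w[length(w)] >= tract_cols[1L]
    }))
  }
  empty_allele <- function() list(sequence = NA_character_,
                                  qtr_units = NA_integer_,
                                  str_units = NA_integer_,
                                  support = NA_integer_,
                                  matched = NA_character_)
  if (depth < config$min_depth) {
    return(structure(list(sample = sample, allele_a = empty_allele(),
                          allele_b = empty_allele(), zygosity = NA_character_,
                          depth = depth, qc = "uncallable_low_depth",
                          candidates = cands, assignments = assign,
                          padded = padded, locus = locus, config = config,
                          n_filtered = n_filtered,
                          tract_range = c(ts, te), ref_window = ref_window),
                     class = "qtr_call"))
  }
  # exclude genuinely ambiguous reads from separation: mask their rows
  sep_rows <- which(!padded$row_reads$ambiguous)
  masked <- padded
  if (length(sep_rows) < nrow(padded$mat)) {
    masked$mat <- padded$mat
    masked$mat[setdiff(seq_len(nrow(padded$mat)), sep_rows), ] <- "."
  }
  sep <- separate_alleles(masked, config$min_support)
  inv <- allele_inventory(locus)
  inv_tract <- vapply(inv$name, function(a)
    build_allele_sequence(a, locus, flanks = FALSE), character(1))
  mk_allele <- function(rows) {
    cons <- .group_consensus(padded, rows)
    tract <- .consensus_tract(cons, padded, ts, te)
    seq_full <- paste(cons[cons != "*"], collapse = "")
    qtr <- if (nchar(tract) %% 6L == 0L) nchar(tract) %/% 6L else NA_integer_
    list(sequence = seq_full, tract = tract,
         qtr_units = qtr,
         str_units = str_run_units(tract, locus$unit),
         support = length(rows),
         matched = if (tract %in% inv_tract) {
           inv$name[match(tract, inv_tract)]
         } else NA_character_)
  }
  if (sep$n_groups == 2L) {
    al <- mk_allele(sep$groups[[1L]])
    bl <- mk_allele(sep$groups[[2L]])
    zyg <- "het"
  } else {
    rows <- if (length(sep$groups[[1L]])) sep$groups[[1L]] else
      seq_len(nrow(padded$mat))
    al <- mk_allele(rows)
    bl <- al
    zyg <- "hom"
  }
  if (!is.na(al$qtr_units) && !is.na(bl$qtr_units) &&
      al$qtr_units > bl$qtr_units) {
    tmp <- al; al <- bl; bl <- tmp
  }
  qc <- "pass"
  if (is.na(al$qtr_units) || is.na(bl$qtr_units)) qc <- "tract_not_hexameric"
  structure(list(sample = sample, allele_a = al, allele_b = bl,
                 zygosity = zyg, depth = depth, qc = qc,
                 candidates = cands, assignments = assign, padded = padded,
                 locus = locus, config = config, n_filtered = n_filtered,
                 tract_range = c(ts, te), ref_window = ref_window),
            class = "qtr_call")
}

#' @export
print.qtr_call <- function(x, ...) {
  cat("<qtr_call> sample", x$sample, "depth", x$depth, "qc", x$qc, "\n")
  if (!is.na(x$zygosity)) {
    cat("  ", x$zygosity, ": QTR ", x$allele_a$qtr_units, "/",
        x$allele_b$qtr_units, "  STR ", x$allele_a$str_units, "/",
        x$allele_b$str_units, "  (", x$allele_a$matched %||% "?", "/",
        x$allele_b$matched %||% "?", ")\n", sep = "")
  }
  invisible(x)
}

#' Tidy summary of genotype calls
#'
#' @param calls A `qtr_call` or list of them.
#' @return A tibble with one row per sample: QTR and STR unit counts per
#'   allele, matched built-in allele names, read support, depth, zygosity
#'   and QC status.
#' @export
genotype_table <- function(calls) {
  if (inherits(calls, "qtr_call")) calls <- list(calls)
  purrr::map_dfr(calls, function(x) tibble::tibble(
    sample = x$sample,
    qtr_a = x$allele_a$qtr_units, qtr_b = x$allele_b$qtr_units,
    str_a = x$allele_a$str_units, str_b = x$allele_b$str_units,
    allele_a = x$allele_a$matched %||% NA_character_,
    allele_b = x$allele_b$matched %||% NA_character_,
    support_a = x$allele_a$support, support_b = x$allele_b$support,
    depth = x$depth, zygosity = x$zygosity %||% NA_character_, qc = x$qc))
}

#' Borrow confirmed candidate haplotypes across samples
#'
#' Candidate haplotypes supported in other samples (appearing in their
#' calls) are added to every sample's candidate set and realignment is
#' repeated once. A no-op for a single sample.
#'
#' @param calls List of `qtr_call` objects for the same locus.
#' @return List of corrected `qtr_call` objects.
#' @export
cross_sample_correct <- function(calls) {
  if (inherits(calls, "qtr_call")) calls <- list(calls)
  if (length(calls) <= 1L) return(calls)
  all_cands <- dplyr::bind_rows(lapply(calls, function(x) x$candidates))
  all_cands <- all_cands[!duplicated(all_cands$sequence), ]
  all_cands <- all_cands[order(all_cands$n_ops, all_cands$indel_bases,
                               all_cands$key), ]
  lapply(calls, function(x) {
    extra <- setdiff(all_cands$sequence, x$candidates$sequence)
    if (length(extra) == 0L) return(x)
    reads <- x$assignments[, c("read_id", "mate", "seq")]
    .finish_call(reads, all_cands, x$locus, x$config, x$sample,
                 x$ref_window %||% as.character(
                   build_allele_sequence("A1", x$locus)),
                 x$tract_range[1L], x$tract_range[2L],
                 n_filtered = x$n_filtered)
  })
}

#' Call genotypes for a multi-sample read table
#'
#' Convenience wrapper: splits a read tibble by `sample`, calls each, runs
#' one round of cross-sample correction, and returns the tidy genotype
#' table (the `qtr_call` objects are attached as attribute `"calls"`).
#'
#' @param reads Tibble with columns `sample`, `read_id`, `mate`, `seq`.
#' @param locus A [repeat_locus()].
#' @param config A [call_config()].
#' @param cross_correct Run the cross-sample round (default `TRUE`).
#' @return Tibble as from [genotype_table()].
#' @export
call_genotypes <- function(reads, locus = repeat_locus(),
                           config = call_config(), cross_correct = TRUE) {
  calls <- lapply(split(reads, reads$sample), function(rd)
    call_genotype(rd, locus, config, sample = rd$sample[1L]))
  if (cross_correct && length(calls) > 1L) {
    calls <- cross_sample_correct(calls)
  }
  out <- genotype_table(calls)
  attr(out, "calls") <- calls
  out
}
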