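test_that("mismatch-error function matches its definition", {
  expect_identical(mismatch_error(2, list()), 2)
  expect_equal(mismatch_error(0, list(c(18, 36))), 18 * exp(5 - 36))
  expect_equal(mismatch_error(0, list(c(18, 36))), 6.2e-13,
               tolerance = 0.01)
  expect_identical(mismatch_error(0, list()), 0)
  expect_identical(mismatch_error(0, list(c(18, 5))), 18)
  expect_equal(mismatch_error(1, data.frame(delta = c(2, 3), l = c(10, 4))),
               1 + 2 * exp(-5) + 3 * exp(1))
  expect_error(mismatch_error(-1, list()), "m must")
  expect_error(mismatch_error(0, list(c(0, 5))), "delta")
  expect_error(mismatch_error(0, list(c(2, 0))), "delta|l")
})

test_that("mismatch error is monotone in m, delta and l", {
  base <- mismatch_error(1, list(c(6, 20)))
  expect_gt(mismatch_error(2, list(c(6, 20))), base)
  expect_gt(mismatch_error(1, list(c(7, 20))), base)
  expect_lt(mismatch_error(1, list(c(6, 21))), base)
})

test_that("match matrix exposes maximal diagonal runs", {
  mm <- build_match_matrix("CAGGCC", "CAGGCC")
  full <- mm$pieces[mm$pieces$length == 6L, ]
  expect_true(any(full$offset == 0L))
  expect_true(mm$matrix[1, 1] && mm$matrix[6, 6])

  expect_identical(nrow(build_match_matrix("AAAA", "CCCC")$pieces), 0L)

  # a window with three units deleted: two long runs on diagonals 18 apart
  win <- as.character(fx_haps$A1)
  ts <- attr(fx_haps$A2, "tract_start")
  read <- substr(fx_haps$A2, ts + 60, ts + 60 + 74)
  runs <- build_match_matrix(read, win)$pieces
  runs <- runs[runs$length >= 30, ]
  offs <- sort(unique(runs$offset))
  expect_true(any(diff(offs) == 18L) || any(outer(offs, offs, "-") == 18L))
})

test_that("gap classification follows the diagonal offset change", {
  left <- list(read_start = 1L, ref_start = 1L, length = 36L)
  right_del <- list(read_start = 37L, ref_start = 55L, length = 39L)
  g <- classify_gap(left, right_del)
  expect_identical(g$kind, "deletion")
  expect_identical(g$delta, 18L)
  expect_identical(g$l, 36L)

  right_ins <- list(read_start = 37L, ref_start = 19L, length = 39L)
  g2 <- classify_gap(left, right_ins)
  expect_identical(g2$kind, "insertion")
  expect_identical(g2$delta, 18L)

  left2 <- list(read_start = 1L, ref_start = 1L, length = 36L)
  right2 <- list(read_start = 40L, ref_start = 46L, length = 30L)
  g3 <- classify_gap(left2, right2)
  expect_identical(g3$kind, "deletion")
  expect_identical(g3$delta, 6L)
  expect_identical(g3$l, 30L)

  expect_error(classify_gap(left, list(read_start = 40L, ref_start = 40L,
                                       length = 10L)), "same diagonal")
})

test_that("perfect reads align gapless with zero error", {
  win <- as.character(fx_haps$A1)
  read <- substr(win, 101, 175)
  p <- find_min_error_path(read, win)
  expect_false(p$unalignable)
  expect_identical(p$M, 0)
  expect_identical(nrow(p$pieces), 1L)
  expect_identical(nrow(p$gaps), 0L)
  expect_identical(p$pieces$ref_start, 101L)
})

test_that("a read spanning a 3-unit deletion prefers the gap path", {
  win <- as.character(fx_haps$A1)
  ts <- attr(fx_haps$A2, "tract_start")
  # 36 bases left of the deletion junction, 39 to the right
  read <- substr(fx_haps$A2, ts + 96 - 36, ts + 96 - 36 + 74)
  p <- find_min_error_path(read, win)
  expect_identical(nrow(p$gaps), 1L)
  expect_identical(p$gaps$kind, "deletion")
  expect_identical(p$gaps$delta, 18L)
  expect_identical(p$m, 0L)
  expect_lt(p$M, 1e-10)
  # deletion signature normalized to the leftmost placement: the start of
  # the central pure run
  expect_identical(p$gaps$ref_start, ts + 96L)
  # the reported error equals the error function applied to (m, gaps)
  expect_identical(p$M, mismatch_error(p$m, p$gaps))
})

test_that("short reads are flagged unalignable", {
  p <- find_min_error_path("CAGGCC", as.character(fx_haps$A1))
  expect_true(p$unalignable)
})

test_that("swapping read and reference mirrors deletion into insertion", {
  set.seed(41)
  for (rep in 1:5) {
    a <- rand_seq(30); b <- rand_seq(12); c <- rand_seq(30)
    win <- paste0(a, b, c)
    read <- paste0(a, c)
    p_del <- find_min_error_path(read, win, seed_length = 8L)
    p_ins <- find_min_error_path(win, read, seed_length = 8L,
                                 min_read = 20L)
    expect_identical(p_del$gaps$kind, "deletion")
    expect_identical(p_ins$gaps$kind, "insertion")
    expect_identical(p_del$gaps$delta, p_ins$gaps$delta)
    expect_identical(p_del$gaps$l, p_ins$gaps$l)
    expect_equal(p_del$M, p_ins$M)
  }
})

test_that("path search equals the brute-force enumeration minimum", {
  set.seed(7)
  n_checked <- 0L
  for (rep in 1:40) {
    win <- rand_seq(80)
    kind <- rep %% 3L
    read <- if (kind == 0L) {
      # embedded with a deletion
      s <- sample(5:30, 1)
      paste0(substr(win, s, s + 17), substr(win, s + 24, s + 24 + 17))
    } else if (kind == 1L) {
      # embedded with an insertion
      s <- sample(5:40, 1)
      paste0(substr(win, s, s + 15), rand_seq(5),
             substr(win, s + 16, s + 16 + 15))
    } else {
      rand_seq(38)
    }
    p <- find_min_error_path(read, win, max_gaps = 2L, seed_length = 5L,
                             min_read = 10L)
    o <- oracle_min_error(read, win, seed_len = 5L, max_gaps = 2L)
    if (p$unalignable) {
      expect_identical(o, Inf)
    } else {
      n_checked <- n_checked + 1L
      expect_equal(p$M, o, tolerance = 1e-12,
                   info = paste("rep", rep))
    }
  }
  expect_gt(n_checked, 20L)
})

test_that("hexamer indels through the anchored repeat have delta divisible by 6", {
  win <- as.character(fx_haps$A1)
  n_gapped <- 0L
  for (al in c("A2", "A3", "A4", "A7")) {
    hap <- fx_haps[[al]]
    ts <- attr(hap, "tract_start")
    # reads spanning the central run with an anchored left piece
    read <- substr(hap, ts + 96 - 12, ts + 96 - 12 + 74)
    p <- find_min_error_path(read, win)
    expect_false(p$unalignable, info = al)
    if (nrow(p$gaps) > 0) {
      n_gapped <- n_gapped + 1L
      expect_true(all(p$gaps$delta %% 6L == 0L), info = al)
    }
  }
  expect_gt(n_gapped, 2L)
})

test_that("the match-matrix dump writes a readable TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  dump_match_matrix("CAGGCC", "ACAGGCCA", path)
  tab <- utils::read.delim(path, row.names = 1)
  expect_identical(dim(tab), c(6L, 8L))
  expect_identical(tab[1, 2], 1L)
})
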