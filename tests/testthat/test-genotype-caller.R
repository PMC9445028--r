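cfg <- call_config()
ref_win <- as.character(fx_haps$A1)

test_that("candidate enumeration from observed indel signatures", {
  # perfectly matching reads propose only the reference
  expect_warning(cands0 <- enumerate_candidates(list(), ref_win),
                 "no reads")
  expect_identical(nrow(cands0), 1L)

  cands_ref <- enumerate_candidates(list(NULL, NULL), ref_win)
  expect_identical(cands_ref$sequence, ref_win)

  # one observed 18 bp deletion: reference plus the deleted haplotype
  ts <- attr(fx_haps$A2, "tract_start")
  read <- substr(fx_haps$A2, ts + 96 - 36, ts + 96 - 36 + 74)
  p <- find_min_error_path(read, ref_win)
  cands <- enumerate_candidates(list(p), ref_win)
  expect_identical(nrow(cands), 2L)
  expect_true(as.character(fx_haps$A2) %in% cands$sequence)

  # signatures {-18, +12} share the same run anchor, so they are
  # incompatible: reference plus the two singles, no combination
  ts4 <- attr(fx_haps$A4, "tract_start")
  read4 <- substr(fx_haps$A4, ts4 + 96 - 14, ts4 + 96 - 14 + 74)
  p4 <- find_min_error_path(read4, ref_win)
  cands2 <- enumerate_candidates(list(p, p4), ref_win)
  expect_identical(nrow(cands2), 3L)
  expect_identical(unname(cands2$n_ops), c(0L, 1L, 1L))

  # two signatures at distinct positions do combine: run deletion plus
  # the A8 variant-unit insertion upstream
  ts8 <- attr(fx_haps$A8, "tract_start")
  read8 <- substr(fx_haps$A8, ts8 + 60 - 30, ts8 + 60 - 30 + 74)
  p8 <- find_min_error_path(read8, ref_win)
  cands3 <- enumerate_candidates(list(p, p8), ref_win)
  expect_identical(nrow(cands3), 4L)
  expect_identical(max(cands3$n_ops), 2L)
})

test_that("realignment assigns reads to their true haplotype", {
  ts <- attr(fx_haps$A2, "tract_start")
  read <- substr(fx_haps$A2, ts + 96 - 36, ts + 96 - 36 + 74)
  p <- find_min_error_path(read, ref_win)
  cands <- enumerate_candidates(list(p), ref_win)
  k_a2 <- match(as.character(fx_haps$A2), cands$sequence)

  reads <- tibble::tibble(read_id = c("r1", "r2"), mate = 1L,
                          seq = c(read, substr(ref_win, 10, 84)))
  asn <- realign_and_select(reads, cands, cfg)
  expect_identical(asn$cand[1L], k_a2)
  expect_identical(asn$M[1L], 0)
  expect_false(asn$tied[1L])
  # a read carrying no variant-region anchor matches every candidate:
  # tied, resolved to the reference, uninformative for length
  expect_true(asn$tied[2L])
  expect_identical(asn$cand[2L], 1L)
})

test_that("error-free A1/A4 reads select their true haplotype when anchored", {
  rd <- simulate_reads(fx_haps$A1, fx_haps$A4, seed = 71)
  cl <- call_genotype(rd, fx_locus, cfg, sample = "s")
  asn <- cl$assignments
  k4 <- match(as.character(fx_haps$A4), cl$candidates$sequence)
  informative <- !asn$tied
  truth <- rd$hap[match(paste(asn$read_id, asn$mate),
                        paste(rd$read_id, rd$mate))]
  sel4 <- asn$cand[informative] == k4
  expect_true(all(truth[informative][sel4] == 2L))
})

test_that("mate correction resolves ties and flags conflicts", {
  cands <- tibble::tibble(
    key = c("ref", "alt"),
    sequence = c("AAAACCCCGGGGTTTTACGT", "AAAACCCCGGGTTTTTACGT"),
    n_ops = c(0L, 1L), indel_bases = c(0L, 1L), ops = list(NULL, NULL))
  asn <- tibble::tibble(
    read_id = c("p1", "p1", "p2", "p2"), mate = c(1L, 2L, 1L, 2L),
    seq = c("AAAACCCC", "GGGTTTTT", "AAAACCCC", "AAAACCCC"),
    cand = c(1L, 2L, 1L, 2L), M = 0, m = 0L,
    start = c(1L, 9L, 1L, 1L), gapless = TRUE,
    tied = c(TRUE, FALSE, FALSE, FALSE),
    tied_with = list(c(1L, 2L), 2L, 1L, 2L),
    tied_starts = list(c(1L, 1L), 9L, 1L, 1L),
    place_tied = FALSE)
  out <- mate_pair_correct(asn, cands)
  # the tied first mate adopts its informative mate's candidate
  expect_identical(out$cand[1L], 2L)
  expect_false(out$tied[1L])
  # both informative but different: conflict, pair excluded
  expect_true(all(out$conflict[3:4]))
  expect_false(any(out$conflict[1:2]))
})

test_that("padding round-trip reproduces every read byte for byte", {
  rd <- simulate_reads(fx_haps$A1, fx_haps$A2, seed = 72)
  cl <- call_genotype(rd, fx_locus, cfg, sample = "s")
  pad <- cl$padded
  for (i in seq_len(nrow(pad$mat))) {
    row <- pad$mat[i, ]
    depadded <- paste(row[!(row %in% c("*", "."))], collapse = "")
    expect_identical(depadded, pad$row_reads$seq[i])
  }
  # A2-assigned reads carry * in 18 reference columns
  k2 <- match(as.character(fx_haps$A2), cl$candidates$sequence)
  rows2 <- which(pad$row_reads$cand == k2)
  stars <- colSums(pad$mat[rows2, , drop = FALSE] == "*")
  expect_identical(sum(stars > 0), 18L)
})

test_that("insertion alleles expand the reference with asterisk columns", {
  rd <- simulate_reads(fx_haps$A1, fx_haps$A4, seed = 73)
  cl <- call_genotype(rd, fx_locus, cfg, sample = "s")
  expect_identical(sum(cl$padded$expanded_ref == "*"), 12L)
})

test_that("allele separation distinguishes het from hom", {
  # all reads identical to the reference: one group
  rd1 <- simulate_reads(fx_haps$A1, fx_haps$A1, seed = 74)
  cl1 <- call_genotype(rd1, fx_locus, cfg, sample = "s")
  sep1 <- separate_alleles(cl1$padded, cfg$min_support)
  expect_identical(sep1$n_groups, 1L)

  # balanced A1/A2: two groups whose consensus tracts differ by 18 bp
  rd2 <- simulate_reads(fx_haps$A1, fx_haps$A2, seed = 75)
  cl2 <- call_genotype(rd2, fx_locus, cfg, sample = "s")
  expect_identical(cl2$zygosity, "het")
  expect_identical(nchar(cl2$allele_b$tract) - nchar(cl2$allele_a$tract),
                   18L)
})

test_that("diploid genotype calls recover truth on clean reads", {
  cl_hom <- call_genotype(simulate_reads(fx_haps$A1, fx_haps$A1, seed = 76),
                          fx_locus, cfg, sample = "s")
  expect_identical(cl_hom$zygosity, "hom")
  expect_identical(c(cl_hom$allele_a$qtr_units, cl_hom$allele_b$qtr_units),
                   c(38L, 38L))
  expect_identical(c(cl_hom$allele_a$str_units, cl_hom$allele_b$str_units),
                   c(6L, 6L))

  cl_het <- call_genotype(simulate_reads(fx_haps$A1, fx_haps$A2, seed = 77),
                          fx_locus, cfg, sample = "s")
  expect_identical(cl_het$zygosity, "het")
  expect_identical(c(cl_het$allele_a$qtr_units, cl_het$allele_b$qtr_units),
                   c(35L, 38L))
  expect_identical(c(cl_het$allele_a$str_units, cl_het$allele_b$str_units),
                   c(3L, 6L))
})

test_that("low depth yields an uncallable genotype", {
  rd <- simulate_reads(fx_haps$A1, fx_haps$A1, coverage = 1, seed = 78)
  cl <- suppressWarnings(call_genotype(rd, fx_locus, cfg, sample = "s"))
  expect_identical(cl$qc, "uncallable_low_depth")
  expect_true(is.na(cl$allele_a$qtr_units))
})

test_that("cross-sample correction is the identity for single samples", {
  rd <- simulate_reads(fx_haps$A1, fx_haps$A1, seed = 79)
  cl <- call_genotype(rd, fx_locus, cfg, sample = "s")
  out <- cross_sample_correct(list(cl))
  expect_identical(genotype_table(out), genotype_table(list(cl)))
})

test_that("cross-sample correction shares confirmed candidates", {
  rd_a <- simulate_reads(fx_haps$A1, fx_haps$A3, seed = 80, sample = "a")
  rd_b <- simulate_reads(fx_haps$A1, fx_haps$A1, seed = 81, sample = "b")
  cl_a <- call_genotype(rd_a, fx_locus, cfg, sample = "a")
  cl_b <- call_genotype(rd_b, fx_locus, cfg, sample = "b")
  out <- cross_sample_correct(list(cl_a, cl_b))
  # sample b gains a's candidate set but keeps its hom-reference call
  expect_true(nrow(out[[2L]]$candidates) >= nrow(cl_b$candidates))
  gt <- genotype_table(out)
  expect_identical(gt$allele_a, c("A3", "A1"))
  expect_identical(gt$allele_b, c("A1", "A1"))
})

test_that("called unit counts satisfy their arithmetic identities", {
  gt <- genotype_table(call_genotype(
    simulate_reads(fx_haps$A2, fx_haps$A4, seed = 82), fx_locus, cfg,
    sample = "s"))
  st <- repeat_statistics(gt$qtr_a, gt$qtr_b)
  expect_identical(st$n_sum, st$n_min + st$n_max)
  expect_identical(st$n_diff, st$n_max - st$n_min)
  expect_identical(st$n_min, base::pmin(gt$qtr_a, gt$qtr_b))
})

test_that("genotypes at error rate 0.2% are recovered almost always", {
  # genotypes drawn from the population allele frequencies, 30x coverage
  set.seed(991)
  n_rep <- 200L
  fr <- fx_inv$freq_pct / 100
  ok <- 0L
  for (r in seq_len(n_rep)) {
    al <- sample(fx_inv$name, 2L, replace = TRUE, prob = fr)
    cl <- tryCatch(
      suppressWarnings(call_genotype(
        simulate_reads(fx_haps[[al[1L]]], fx_haps[[al[2L]]],
                       error_rate = 0.002, seed = 5000L + r),
        fx_locus, cfg, sample = "s")),
      error = function(e) NULL)
    truth_q <- sort(fx_inv$qtr_units[match(al, fx_inv$name)])
    truth_s <- sort(fx_inv$str_units[match(al, fx_inv$name)])
    good <- !is.null(cl) && !is.na(cl$allele_a$qtr_units) &&
      identical(sort(c(cl$allele_a$qtr_units, cl$allele_b$qtr_units)),
                truth_q) &&
      identical(sort(c(cl$allele_a$str_units, cl$allele_b$str_units)),
                truth_s)
    if (good) ok <- ok + 1L
  }
  expect_gte(ok / n_rep, 0.95)
})
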