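# Repeat-locus model: the declared hexanucleotide quasi-tandem repeat (QTR),
# its built-in allele inventory, and sequence constructors shared by the
# caller (as reference/truth) and the read simulator.

# Synthetic, non-repetitive 150 bp flanks used to anchor reads. The true
# genomic flanks are not part of the locus definition; any flank sequence can
# be supplied to repeat_locus(). These constants contain no hexamer-unit
# motifs and no duplicated 20-mers, so every flank-overlapping read has a
# unique anchor.
.DEFAULT_LEFT_FLANK <- paste0(
  "AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTGCA",
  "CGCCCTAAAGTACAATTAGGATATTCATCCCTACACTGTATATGCCGAACGTTCTAATAAACGACTTAGC",
  "AACAAGTCGC")
.DEFAULT_RIGHT_FLANK <- paste0(
  "TTCCTGTTAGTTTTGGTTAGGCACGGAACGCTATCGAGCGCGTAAGCGCCAACCCGCATTTACGAAGTAC",
  "CCATCGTATGTAATAAGACCTCGAGTACGTCGGGACGTTGGCTGTGATGTTTTGATGAGCGAAGTTCGAC",
  "GTTGCCGATG")

# Reference tract layout: 38 hexamer units, the central 6 (units 17-22) a
# perfect (CAGGCC)_6 short tandem repeat, the rest imperfect quasi-repeat
# units (QA-coding variants plus occasional valine-coding GTGGCC units).
# Outside the central run no pure-unit run exceeds 2 units, so the longest
# pure run identifies the STR even for the 3-unit allele. The variant units
# are arranged aperiodically: a periodic arrangement would let multi-unit
# indels near the run mimic each other beyond what a 75 bp read can
# resolve, a degeneracy the real imperfect tract does not show.
.ref_units <- function(unit = "CAGGCC") {
  stopifnot(identical(unit, "CAGGCC"))
  c("CAGGCT", "CAGGCC", "CAGGCA", "CAGGCC", "CAGGCT", "CAAGCC",
    "CAGGCC", "CAGGCC", "GTGGCC", "CAGGCA", "CAGGCC", "CAAGCC",
    "CAGGCA", "CAGGCC", "CAGGCC", "CAGGCA",
    rep("CAGGCC", 6),
    "CAGGCA", "CAGGCC", "GTGGCC", "CAGGCT", "CAGGCC", "CAGGCC",
    "CAGGCA", "CAAGCC", "CAGGCC", "GTGGCC", "CAGGCA", "CAGGCT",
    "CAGGCC", "CAAGCC", "CAGGCC", "CAGGCA")
}
.STR_RUN_START_UNIT <- 17L

#' Count repeat units in a declared locus span
#'
#' The span of a tandem-repeat locus given in 1-based inclusive reference
#' coordinates must be an exact multiple of the repeat unit length; the
#' quotient is the number of units in the reference tract.
#'
#' @param locus_start,locus_end 1-based inclusive reference coordinates.
#' @param unit_length Repeat unit length in bases (6 for a hexamer).
#' @return Integer unit count.
#' @examples
#' reference_unit_count(145838546, 145838773, 6) # 38
#' @export
reference_unit_count <- function(locus_start, locus_end, unit_length = 6L) {
  if (locus_end < locus_start) {
    stop("malformed locus: end (", locus_end, ") < start (", locus_start, ")")
  }
  span <- locus_end - locus_start + 1
  if (span %% unit_length != 0) {
    stop("malformed locus: span ", span,
         " is not divisible by unit length ", unit_length)
  }
  as.integer(span %/% unit_length)
}

#' Declare a hexanucleotide repeat locus
#'
#' Models a quasi-tandem repeat (QTR): an imperfect tandem tract of
#' `qtr_units` hexamer units containing a central perfect short tandem
#' repeat (STR) of `str_units` units. Defaults describe the 38-unit QTR in
#' *TCERG1* exon 4 (chr5:145,838,546-145,838,773, hg19) with its central
#' (CAGGCC)_6 STR. Coordinates are 1-based inclusive, as printed for hg19;
#' the same convention is used internally.
#'
#' @param chromosome Chromosome label.
#' @param start,end 1-based inclusive reference coordinates of the tract.
#' @param unit Hexamer unit (A/C/G/T only, length 6).
#' @param str_units Units in the central perfect run of the reference allele.
#' @param left_flank,right_flank Anchoring sequence either side of the tract.
#'   Defaults are synthetic non-repetitive 150 bp flanks.
#' @param build Genome build label attached to the coordinates.
#' @return An object of class `repeat_locus`.
#' @export
repeat_locus <- function(chromosome = "chr5",
                         start = 145838546, end = 145838773,
                         unit = "CAGGCC", str_units = 6L,
                         left_flank = .DEFAULT_LEFT_FLANK,
                         right_flank = .DEFAULT_RIGHT_FLANK,
                         build = "hg19") {
  if (nchar(unit) != 6L || grepl("[^ACGT]", unit)) {
    stop("unit must be a 6-base A/C/G/T string")
  }
  qtr_units <- reference_unit_count(start, end, nchar(unit))
  if (str_units > qtr_units) stop("str_units must not exceed qtr_units")
  if (grepl("[^ACGT]", left_flank) || grepl("[^ACGT]", right_flank)) {
    stop("flanks must be A/C/G/T strings")
  }
  units <- .ref_units(unit)
  stopifnot(length(units) == qtr_units)
  locus <- structure(
    list(chromosome = chromosome, start = start, end = end, unit = unit,
         qtr_units = qtr_units, str_units = as.integer(str_units),
         left_flank = left_flank, right_flank = right_flank,
         build = build, units = units,
         str_run_start_unit = .STR_RUN_START_UNIT),
    class = "repeat_locus")
  locus
}

#' @export
print.repeat_locus <- function(x, ...) {
  cat("<repeat_locus> ", x$chromosome, ":", x$start, "-", x$end,
      " (", x$build, ")\n", sep = "")
  cat("  unit ", x$unit, ", QTR ", x$qtr_units, " units, central STR ",
      x$str_units, " units\n", sep = "")
  cat("  flanks ", nchar(x$left_flank), " / ", nchar(x$right_flank),
      " bp\n", sep = "")
  invisible(x)
}

#' Built-in allele inventory at the repeat locus
#'
#' The eight alleles observed at the *TCERG1* hexamer repeat, as a tibble
#' with QTR/STR unit lengths, length deltas versus the reference allele A1,
#' and the observed population frequencies (percent). Allele A6 has the same
#' length as A1 and differs by a synonymous SNV; A5 and A8 change length in
#' the imperfect (non-STR) part of the tract.
#'
#' @param locus A [repeat_locus()].
#' @return A tibble with one row per allele.
#' @export
allele_inventory <- function(locus = repeat_locus()) {
  tibble::tibble(
    name = paste0("A", 1:8),
    qtr_units = c(38L, 35L, 36L, 40L, 34L, 38L, 39L, 39L),
    str_units = c(6L, 3L, 4L, 8L, 4L, 6L, 7L, 6L),
    delta_qtr = c(0L, -3L, -2L, 2L, -4L, 0L, 1L, 1L),
    delta_str = c(0L, -3L, -2L, 2L, -2L, 0L, 1L, 0L),
    freq_pct = c(91.31, 4.10, 2.30, 1.97, 0.08, 0.08, 0.08, 0.08)
  )
}

# Recipe for each built-in allele: indel units in the central STR run plus
# auxiliary edits outside it. Positions of the non-STR edits (A5's extra
# deletions, A6's SNV, A8's inserted variant unit) are configurable design
# defaults: the true positions are not available as machine-readable sequence.
.allele_recipe <- function(name) {
  switch(name,
    A1 = list(str_delta = 0L),
    A2 = list(str_delta = -3L),
    A3 = list(str_delta = -2L),
    A4 = list(str_delta = 2L),
    A5 = list(str_delta = -2L, del_units = c(14L, 15L)),
    A6 = list(str_delta = 0L, subs = list(list(offset = 30L, base = "G"))),
    A7 = list(str_delta = 1L),
    A8 = list(str_delta = 0L,
              ins_units = list(list(after_unit = 10L, seq = "CAGGCA"))),
    stop("unknown allele name: ", name)
  )
}

#' Specify a repeat allele
#'
#' An allele is described relative to the reference tract by the number of
#' hexamer units inserted into (positive) or deleted from (negative) the
#' central pure run, plus optional edits outside the run: whole-unit
#' deletions (`del_units`, reference unit indices), unit insertions
#' (`ins_units`, list of `list(after_unit=, seq=)`), and base substitutions
#' (`subs`, list of `list(offset=, base=)`, 1-based offsets within the
#' edited tract). Unit indels in the pure run are normalized to the leftmost
#' equivalent placement.
#'
#' @param name Allele label. For `"A1"`..`"A8"` the built-in recipe is used
#'   and the remaining arguments must be omitted.
#' @param str_delta Signed unit count added to the central pure run.
#' @param del_units,ins_units,subs Optional non-STR edits, see above.
#' @return An object of class `allele_spec`.
#' @export
allele_spec <- function(name, str_delta = NULL, del_units = NULL,
                        ins_units = NULL, subs = NULL) {
  if (name %in% paste0("A", 1:8)) {
    if (!is.null(str_delta) || !is.null(del_units) ||
        !is.null(ins_units) || !is.null(subs)) {
      stop("built-in allele ", name, " cannot be modified; use a new name")
    }
    rec <- .allele_recipe(name)
  } else {
    rec <- list(str_delta = as.integer(str_delta %||% 0L),
                del_units = del_units, ins_units = ins_units, subs = subs)
  }
  structure(c(list(name = name), rec), class = "allele_spec")
}

#' Build the full sequence of a repeat allele
#'
#' Returns the haplotype sequence `left_flank + tract + right_flank` for an
#' allele at the locus. Length-changing alleles add or remove copies of the
#' unit at the leftmost position of the central pure run; substitutions are
#' applied at their stated offsets within the edited tract.
#'
#' @param spec An [allele_spec()] or the name of a built-in allele.
#' @param locus A [repeat_locus()].
#' @param flanks If `FALSE`, return the tract only.
#' @return A nucleotide string; the tract is available as attribute
#'   `"tract"` and its 1-based position within the haplotype as
#'   `"tract_start"`.
#' @export
build_allele_sequence <- function(spec, locus = repeat_locus(),
                                  flanks = TRUE) {
  if (is.character(spec)) spec <- allele_spec(spec)
  stopifnot(inherits(spec, "allele_spec"))
  units <- locus$units
  keep <- rep(TRUE, length(units))
  s0 <- locus$str_run_start_unit
  d <- spec$str_delta %||% 0L
  if (d < 0) {
    if (-d > locus$str_units) stop("cannot delete more units than the STR run")
    keep[s0:(s0 - d - 1L)] <- FALSE
  }
  if (!is.null(spec$del_units)) {
    if (any(spec$del_units < 1L | spec$del_units > length(units))) {
      stop("del_units outside the reference tract")
    }
    keep[spec$del_units] <- FALSE
  }
  # assemble with insertions keyed by reference unit index (0 = before unit 1)
  ins <- stats::setNames(vector("list", length(units) + 1L),
                         as.character(0:length(units)))
  if (d > 0) ins[[as.character(s0 - 1L)]] <- rep(locus$unit, d)
  for (iu in spec$ins_units %||% list()) {
    if (iu$after_unit < 0L || iu$after_unit > length(units)) {
      stop("ins_units after_unit outside the reference tract")
    }
    if (nchar(iu$seq) %% nchar(locus$unit) != 0 || grepl("[^ACGT]", iu$seq)) {
      stop("inserted sequence must be whole A/C/G/T hexamer units")
    }
    k <- as.character(iu$after_unit)
    ins[[k]] <- c(ins[[k]], iu$seq)
  }
  out <- character(0)
  if (!is.null(ins[["0"]])) out <- c(out, ins[["0"]])
  for (i in seq_along(units)) {
    if (keep[i]) out <- c(out, units[i])
    if (!is.null(ins[[as.character(i)]])) out <- c(out, ins[[as.character(i)]])
  }
  tract <- paste(out, collapse = "")
  for (sb in spec$subs %||% list()) {
    if (sb$offset < 1L || sb$offset > nchar(tract)) {
      stop("substitution offset ", sb$offset, " outside the tract (length ",
           nchar(tract), ")")
    }
    substr(tract, sb$offset, sb$offset) <- sb$base
  }
  if (!flanks) return(tract)
  hap <- paste0(locus$left_flank, tract, locus$right_flank)
  attr(hap, "tract") <- tract
  attr(hap, "tract_start") <- nchar(locus$left_flank) + 1L
  attr(hap, "allele") <- spec$name
  hap
}

#' Longest pure-unit run in a tract, in units
#'
#' The STR length of an allele is defined as the longest run of perfect
#' repeat units within its tract.
#'
#' @param tract Nucleotide string.
#' @param unit Repeat unit.
#' @return Integer unit count (0 if the unit never occurs).
#' @export
str_run_units <- function(tract, unit = "CAGGCC") {
  m <- gregexpr(paste0("(?:", unit, ")+"), tract)[[1]]
  if (m[1] == -1) return(0L)
  as.integer(max(attr(m, "match.length")) %/% nchar(unit))
}

#' Translate a repeat tract
#'
#' Standard-genetic-code translation of the in-frame tract. The hexamer unit
#' CAGGCC encodes the dipeptide glutamine-alanine (QA); the full reference
#' tract translates to an imperfect 38-unit QA repeat with occasional
#' valines. Internal stop codons are flagged with a warning rather than
#' dropped.
#'
#' @param tract Nucleotide string, length >= 3 after the frame offset.
#' @param frame_offset Bases to skip before the first codon (0, 1 or 2).
#' @return Amino-acid string with attribute `"dipeptide_units"` (the number
#'   of complete 6-base units translated) and `"has_stop"`.
#' @export
translate_tract <- function(tract, frame_offset = 0L) {
  stopifnot(frame_offset %in% 0:2)
  s <- substr(tract, frame_offset + 1L, nchar(tract))
  if (nchar(s) < 3L) stop("tract shorter than one codon after frame offset")
  s <- substr(s, 1L, nchar(s) - nchar(s) %% 3L)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
  has_stop <- grepl("\\*", aa)
  if (has_stop) warning("stop codon inside translated tract")
  structure(aa, dipeptide_units = nchar(s) %/% 6L, has_stop = has_stop)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
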