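# File formats: SAM/BAM alignments in, FASTA/FASTQ sequences out, TSV
# cohort and genotype tables with a provenance header.

#' Read locus-overlapping alignments from SAM/BAM
#'
#' Extracts reads overlapping the declared locus window (tract plus
#' `margin` on both sides) from one or more SAM or BAM files, returning
#' the tidy read tibble the caller consumes. SAM files are converted to
#' BAM internally via Rsamtools. Multiple files for one sample are merged.
#'
#' @param path Character vector of SAM/BAM paths.
#' @param locus A [repeat_locus()].
#' @param margin Window margin in bases around the tract.
#' @param sample Sample label; defaults to the first file's base name.
#' @return Tibble: `sample`, `read_id`, `mate`, `seq`, `pos`, `mapq`.
#' @export
read_alignments <- function(path, locus = repeat_locus(), margin = 200L,
                            sample = NULL) {
  if (is.null(sample)) sample <- sub("\\.(sam|bam)$", "", basename(path[1L]))
  out <- lapply(path, function(p) {
    if (!file.exists(p)) stop("alignment file not found: ", p)
    bam <- p
    if (grepl("\\.sam$", p, ignore.case = TRUE)) {
      bam <- Rsamtools::asBam(p, tempfile(), overwrite = TRUE,
                              indexDestination = TRUE)
    }
    which <- GenomicRanges::GRanges(
      locus$chromosome,
      IRanges::IRanges(max(1L, locus$start - nchar(locus$left_flank) -
                             margin),
                       locus$end + nchar(locus$right_flank) + margin))
    param <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "pos", "mapq", "seq"), which = which)
    res <- Rsamtools::scanBam(bam, param = param)[[1L]]
    if (length(res$qname) == 0L) {
      return(tibble::tibble(sample = character(), read_id = character(),
                            mate = integer(), seq = character(),
                            pos = integer(), mapq = integer()))
    }
    tibble::tibble(
      sample = sample,
      read_id = res$qname,
      mate = ifelse(bitwAnd(res$flag, 128L) > 0L, 2L, 1L),
      seq = as.character(res$seq),
      pos = res$pos,
      mapq = res$mapq)
  })
  dplyr::distinct(dplyr::bind_rows(out),
                  .data$read_id, .data$mate, .keep_all = TRUE)
}

#' Write simulated reads as SAM
#'
#' Writes a read tibble (from [simulate_reads()]) as a minimal SAM file
#' with the reads positioned by their true fragment coordinates mapped
#' onto the locus coordinate system. The CIGAR is reported as full-length
#' match; the caller realigns from scratch, so approximate placements
#' suffice.
#'
#' @param reads Read tibble with `read_id`, `mate`, `seq`, `frag_start`,
#'   `frag_len`.
#' @param path Output path (".sam").
#' @param locus A [repeat_locus()].
#' @return The path, invisibly.
#' @export
write_sam <- function(reads, path, locus = repeat_locus()) {
  window_start <- locus$start - nchar(locus$left_flank)
  rl <- nchar(reads$seq)
  pos <- ifelse(reads$mate == 1L, reads$frag_start,
                reads$frag_start + reads$frag_len - rl)
  chrom_len <- locus$end + nchar(locus$right_flank) + 10000L
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", locus$chromosome, "\tLN:", chrom_len))
  flag <- ifelse(reads$mate == 1L, 99L, 147L)
  rec <- paste(reads$read_id, flag, locus$chromosome,
               window_start + pos - 1L, 60L, paste0(rl, "M"), "=",
               window_start + ifelse(reads$mate == 1L,
                                     reads$frag_start + reads$frag_len - rl,
                                     reads$frag_start) - 1L,
               ifelse(reads$mate == 1L, reads$frag_len, -reads$frag_len),
               reads$seq, strrep("I", rl), sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(vapply(seqs, as.character, character(1)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write reads as FASTQ
#'
#' @param reads Read tibble with `read_id`, `mate`, `seq`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ids <- paste0(reads$read_id, "/", reads$mate)
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- ids
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(reads$seq))))
  invisible(path)
}

# Deterministic provenance line: version and seed only, so identical runs
# produce byte-identical outputs.
.provenance <- function(seed = NULL) {
  paste0("# qtronset ",
         as.character(utils::packageVersion("qtronset")),
         " | seed=", seed %||% "NA")
}

#' Write / read a cohort table as TSV
#'
#' Tab-separated, UTF-8, '.' decimal, with a `#` provenance header line.
#' Round-trips value-identically.
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @param seed Seed recorded in the provenance header.
#' @return `write_cohort` returns the path invisibly; `read_cohort` the
#'   tibble.
#' @export
write_cohort <- function(cohort, path, seed = NULL) {
  writeLines(.provenance(seed), path)
  suppressMessages(readr::write_tsv(cohort, path, append = TRUE,
                                    col_names = TRUE))
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Write a genotype table as TSV
#'
#' @param genotypes Tibble from [genotype_table()] or [call_genotypes()].
#' @param path File path.
#' @param seed Seed recorded in the provenance header.
#' @return The path, invisibly.
#' @export
write_genotypes <- function(genotypes, path, seed = NULL) {
  writeLines(.provenance(seed), path)
  suppressMessages(readr::write_tsv(genotypes, path, append = TRUE,
                                    col_names = TRUE))
  invisible(path)
}
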