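# Genome sequences and sequence extraction.
#
# Genomes are held as Biostrings::DNAStringSet objects (uppercase, alphabet
# {A,C,G,T,N}); peak coordinates index into them 0-based half-open.

#' Read a genome FASTA
#'
#' Sequences are uppercased on input; `N` is permitted. Duplicate chromosome
#' names are an error.
#'
#' @param path FASTA file (optionally gzip-compressed).
#' @return A [Biostrings::DNAStringSet] keyed by chromosome name.
#' @export
read_fasta <- function(path) {
  gs <- Biostrings::readDNAStringSet(path)
  names(gs) <- sub("\\s.*$", "", names(gs))
  if (anyDuplicated(names(gs))) {
    abort(paste0(path, ": duplicate chromosome names"))
  }
  Biostrings::DNAStringSet(toupper(gs))
}

#' Write a genome FASTA
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Chromosome lengths of a genome
#' @param genome A [Biostrings::DNAStringSet].
#' @return Named integer vector.
#' @export
genome_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

check_chroms <- function(chroms, genome, what = "input") {
  missing <- setdiff(unique(chroms), names(genome))
  if (length(missing)) {
    abort(paste0(what, " references chromosome(s) absent from the genome: ",
                 paste(missing, collapse = ", ")))
  }
}

#' Extract the sequences underlying a peak set
#'
#' One uppercase forward-strand sequence per peak, of exactly the peak's
#' length; `N` bases are retained.
#'
#' @param peaks A [peak_set()].
#' @param genome A [Biostrings::DNAStringSet].
#' @return A [Biostrings::DNAStringSet] named by peak name.
#' @export
extract_peak_sequences <- function(peaks, genome) {
  check_chroms(peaks$chrom, genome, "peak set")
  lens <- genome_lengths(genome)
  bad <- which(peaks$start < 0 | peaks$end > lens[peaks$chrom])
  if (length(bad)) {
    abort(paste0("peak ", peaks$name[bad[1]], " (", peaks$chrom[bad[1]], ":",
                 peaks$start[bad[1]], "-", peaks$end[bad[1]],
                 ") exceeds chromosome bounds"))
  }
  res <- Biostrings::DNAStringSet(rep("", nrow(peaks)))
  for (cm in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == cm)
    res[idx] <- Biostrings::extractAt(
      genome[[cm]],
      IRanges::IRanges(peaks$start[idx] + 1L, peaks$end[idx])
    )
  }
  names(res) <- peaks$name
  res
}

#' Build a TSS-upstream background sequence set
#'
#' For a `+` strand TSS at t the background window is `[t - span, t)`; for a
#' `-` strand TSS it is the reverse complement of `[t, t + span)`. Windows
#' truncated by a chromosome edge are dropped with a warning. This emulates
#' the promoter-proximal background used for both k-mer fingerprints and
#' motif enrichment.
#'
#' @param tss Tibble with columns `chrom`, `pos`, `strand` (see [read_tss()]).
#' @param genome A [Biostrings::DNAStringSet].
#' @param span Window length in bp (default 2000).
#' @return A [Biostrings::DNAStringSet] with a `provenance` attribute.
#' @export
build_tss_background <- function(tss, genome, span = 2000L) {
  span <- as.integer(span)
  check_chroms(tss$chrom, genome, "TSS set")
  lens <- genome_lengths(genome)
  start <- ifelse(tss$strand == "+", tss$pos - span, tss$pos)
  end <- start + span
  ok <- start >= 0 & end <= lens[tss$chrom]
  if (any(!ok)) {
    warn(sprintf("%d TSS window(s) truncated at chromosome edges were dropped",
                 sum(!ok)))
  }
  if (!any(ok)) abort("no TSS window fits inside the genome")
  keep <- tss[ok, ]
  start <- start[ok]; end <- end[ok]
  seqs <- Biostrings::DNAStringSet(rep("", nrow(keep)))
  for (cm in unique(keep$chrom)) {
    idx <- which(keep$chrom == cm)
    seqs[idx] <- Biostrings::extractAt(
      genome[[cm]], IRanges::IRanges(start[idx] + 1L, end[idx]))
  }
  minus <- keep$strand == "-"
  if (any(minus)) seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  names(seqs) <- paste0("tss_up", span, "_", seq_len(length(seqs)))
  attr(seqs, "provenance") <- sprintf("upstream %d bp of %d TSS", span,
                                      length(seqs))
  seqs
}
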