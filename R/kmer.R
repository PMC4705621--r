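# k-mer fingerprint enrichment: frequency per kb of a fixed panel of k-mers
# in peak sequences, reported as log2(foreground frequency / background
# frequency). The panels bundled with the package are the core Hox-monomer
# 5-mers and Exd-Hox dimer 8-mers used for SELEX-Seq-style binding
# fingerprints.

#' Construct a k-mer panel
#'
#' @param kmers Character vector of same-length DNA words over ACGT.
#' @param labels Optional display labels (e.g. fingerprint colour names).
#' @return Tibble of class `kmer_panel` with columns `kmer`, `label`.
#' @export
kmer_panel <- function(kmers, labels = kmers) {
  kmers <- toupper(kmers)
  if (!length(kmers)) abort("empty k-mer panel")
  if (length(unique(nchar(kmers))) != 1) {
    abort("all panel k-mers must have the same length")
  }
  if (any(grepl("[^ACGT]", kmers))) {
    abort("panel k-mers must be over {A,C,G,T} only")
  }
  structure(tibble(kmer = kmers, label = labels),
            class = c("kmer_panel", class(tibble())),
            k = nchar(kmers[1]))
}

#' Read a k-mer panel file
#'
#' One k-mer per line, optionally followed by whitespace and a label.
#'
#' @param path Panel file.
#' @return A [kmer_panel()].
#' @export
read_kmer_panel <- function(path) {
  fields <- read_tab_fields(path)
  kmers <- vapply(fields, `[`, character(1), 1)
  labels <- vapply(fields, function(f) if (length(f) > 1) f[2] else f[1],
                   character(1))
  kmer_panel(kmers, labels)
}

#' Bundled fingerprint k-mer panels
#'
#' `hox_monomer_panel()` holds the named core Hox-monomer binding 5-mers;
#' `exd_hox_dimer_panel()` the named Exd-Hox dimer 8-mers (each beginning
#' with the Exd core TGAT). Both ship as editable text files under
#' `inst/extdata/` and can be replaced by user panels via
#' [read_kmer_panel()].
#'
#' @return A [kmer_panel()].
#' @export
hox_monomer_panel <- function() {
  read_kmer_panel(system.file("extdata", "panel_hox_5mers.txt",
                              package = "hoxspec", mustWork = TRUE))
}

#' @rdname hox_monomer_panel
#' @export
exd_hox_dimer_panel <- function() {
  read_kmer_panel(system.file("extdata", "panel_exdhox_8mers.txt",
                              package = "hoxspec", mustWork = TRUE))
}

#' Count occurrences of a k-mer in a sequence set
#'
#' Overlapping occurrences are counted; positions containing `N` never
#' match. In `"both"` mode occurrences of the reverse complement are added,
#' except for palindromic words, which are counted once per position.
#'
#' @param seqs A [Biostrings::DNAStringSet] or character vector.
#' @param kmer A DNA word over ACGT.
#' @param strands `"forward"` (default, the counting convention used for
#'   fingerprints) or `"both"`.
#' @return Integer total count over all sequences.
#' @export
count_kmer <- function(seqs, kmer, strands = c("forward", "both")) {
  strands <- match.arg(strands)
  kmer <- toupper(kmer)
  if (grepl("[^ACGT]", kmer)) abort("k-mer must be over {A,C,G,T} only")
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  n <- sum(Biostrings::vcountPattern(kmer, seqs, fixed = TRUE))
  if (strands == "both") {
    rc <- revcomp_chr(kmer)
    if (rc != kmer) {
      n <- n + sum(Biostrings::vcountPattern(rc, seqs, fixed = TRUE))
    }
  }
  as.integer(n)
}

#' k-mer fingerprint enrichment of peak sequences against a background
#'
#' For each panel k-mer, counts occurrences in the foreground (peak)
#' sequences and in the background set, converts both to frequencies per kb
#' of total sequence, and reports `enrichment = log2(fg_per_kb /
#' bg_per_kb)`. Background frequency is pooled over all background sequences
#' (total count / total kb). A k-mer absent from either side has undefined
#' enrichment (`NA`, flagged in `defined`), never +/-Inf.
#'
#' @param fg_seqs Foreground sequences ([Biostrings::DNAStringSet], e.g.
#'   [extract_peak_sequences()] output).
#' @param bg Background sequences (e.g. [build_tss_background()] output).
#' @param panel A [kmer_panel()].
#' @param strands `"forward"` (default) or `"both"`.
#' @return Tibble of class `kmer_fingerprint` with per-k-mer counts,
#'   frequencies per kb, `enrichment` and `defined`, ordered as the panel.
#' @export
fingerprint <- function(fg_seqs, bg, panel, strands = c("forward", "both")) {
  strands <- match.arg(strands)
  if (!length(fg_seqs) || !length(bg)) {
    abort("foreground and background must be non-empty")
  }
  fg_kb <- sum(as.numeric(Biostrings::width(fg_seqs))) / 1000
  bg_kb <- sum(as.numeric(Biostrings::width(bg))) / 1000
  out <- dplyr::mutate(as_tibble(panel),
    fg_count = vapply(.data$kmer, function(k)
      count_kmer(fg_seqs, k, strands), integer(1), USE.NAMES = FALSE),
    bg_count = vapply(.data$kmer, function(k)
      count_kmer(bg, k, strands), integer(1), USE.NAMES = FALSE),
    fg_kb = fg_kb, bg_kb = bg_kb,
    fg_per_kb = .data$fg_count / fg_kb,
    bg_per_kb = .data$bg_count / bg_kb,
    defined = .data$fg_count > 0 & .data$bg_count > 0,
    enrichment = ifelse(.data$defined,
                        log2((.data$fg_count / fg_kb) /
                             (.data$bg_count / bg_kb)),
                        NA_real_)
  )
  structure(out, class = c("kmer_fingerprint", class(tibble())),
            strands = strands)
}
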