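# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Chromosomes used for downstream analysis
#'
#' The default chromosome whitelist: the euchromatic arms of the
#' D. melanogaster genome plus the mitochondrial contig. Peaks on any other
#' contig are dropped on input.
#'
#' @return Character vector of chromosome names.
#' @export
default_whitelist <- function() {
  c("chr2L", "chr2R", "chr3L", "chr3R", "chr4", "chrX", "chrM")
}

#' Analysis parameter bundle
#'
#' Collects the tunable parameters shared by the pipeline stages, with the
#' defaults used throughout: a 5 % reciprocal-overlap rule for calling two
#' peaks "the same" site, 1 kb windows for binding-score correlation, 2 kb
#' summit-centred spans smoothed with a 100 bp window sliding in 10 bp steps,
#' and a 0.001 match p-value for PWM scanning.
#'
#' @param reciprocal_overlap_fraction Minimum fraction of BOTH peaks that the
#'   overlap must cover for the pair to qualify.
#' @param window_size_bp Window size for binned binding scores.
#' @param profile_span_bp Total span of summit-centred profiles.
#' @param smooth_window_bp Sliding-window width used to smooth profiles.
#' @param smooth_step_bp Step between successive smoothing windows.
#' @param pwm_match_pvalue Per-window p-value threshold for PWM matches.
#' @param pseudocount Pseudocount added to mean signals in differential
#'   ranking.
#' @param chrom_whitelist Chromosomes retained on input.
#' @param random_seed Seed used by any stage that draws random numbers.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(reciprocal_overlap_fraction = 0.05,
                            window_size_bp = 1000L,
                            profile_span_bp = 2000L,
                            smooth_window_bp = 100L,
                            smooth_step_bp = 10L,
                            pwm_match_pvalue = 0.001,
                            pseudocount = 0.1,
                            chrom_whitelist = default_whitelist(),
                            random_seed = 1L) {
  if (!(reciprocal_overlap_fraction > 0 && reciprocal_overlap_fraction <= 1)) {
    abort("`reciprocal_overlap_fraction` must be in (0, 1].")
  }
  if (smooth_window_bp > profile_span_bp) {
    abort("`smooth_window_bp` must not exceed `profile_span_bp`.")
  }
  if (smooth_step_bp < 1) abort("`smooth_step_bp` must be >= 1.")
  structure(
    list(
      reciprocal_overlap_fraction = reciprocal_overlap_fraction,
      window_size_bp = as.integer(window_size_bp),
      profile_span_bp = as.integer(profile_span_bp),
      smooth_window_bp = as.integer(smooth_window_bp),
      smooth_step_bp = as.integer(smooth_step_bp),
      pwm_match_pvalue = pwm_match_pvalue,
      pseudocount = pseudocount,
      chrom_whitelist = chrom_whitelist,
      random_seed = as.integer(random_seed)
    ),
    class = "analysis_config"
  )
}

# Median of the multiset where value[i] appears weight[i] times (integer
# weights), without expanding. Matches stats::median() on the expanded vector.
weighted_median <- function(values, weights) {
  stopifnot(length(values) == length(weights), all(weights >= 0))
  keep <- weights > 0
  values <- values[keep]
  weights <- weights[keep]
  total <- sum(weights)
  if (total == 0) return(NA_real_)
  ord <- order(values)
  values <- values[ord]
  cw <- cumsum(weights[ord])
  if (total %% 2 == 1) {
    values[which(cw >= (total + 1) / 2)[1]]
  } else {
    lo <- values[which(cw >= total / 2)[1]]
    hi <- values[which(cw >= total / 2 + 1)[1]]
    (lo + hi) / 2
  }
}

# Reverse complement of a plain character k-mer.
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Open a path as a (possibly gzip-compressed) text connection.
open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

# Derive a reproducible 32-bit sub-seed from a base seed and a stage offset,
# so adding a stage never perturbs earlier draws.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9973) %% 2147483647)
}
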