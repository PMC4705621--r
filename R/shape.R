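# Summit-centred DNA minor-groove-width (MGW) and GC-content profiles.
#
# MGW is predicted per base from the local pentamer via a lookup table
# (strand-symmetric: value(pentamer) == value(revcomp)); GC is 1 for G/C, 0
# for A/T, missing for N. Per-position averages across peaks are computed
# first, then the profile is smoothed with a sliding window (average first,
# then smooth).

#' Load a pentamer minor-groove-width table
#'
#' Tab-separated `pentamer<TAB>value` rows, values in Angstrom at the central
#' base of the pentamer. The table must be strand-symmetric; asymmetric
#' entries are symmetrized by averaging with a warning, and a table given
#' only one strand of each pentamer pair is completed by reverse-complement
#' closure. A table covering fewer than all 1024 pentamers is accepted and
#' flagged (`attr(, "complete")`); missing pentamers predict `NA`.
#'
#' @param path TSV file.
#' @return Named numeric vector of class `shape_table`.
#' @export
load_shape_table <- function(path) {
  fields <- read_tab_fields(path)
  keys <- toupper(vapply(fields, `[`, character(1), 1))
  vals <- parse_num(vapply(fields, `[`, character(1), 2), path,
                    attr(fields, "line_no"), "width")
  if (any(nchar(keys) != 5) || any(grepl("[^ACGT]", keys))) {
    abort(paste0(path, ": keys must be DNA pentamers over {A,C,G,T}"))
  }
  if (anyDuplicated(keys)) abort(paste0(path, ": duplicate pentamer keys"))
  tab <- setNames(vals, keys)
  shape_table(tab)
}

#' @rdname load_shape_table
#' @param values Named numeric vector keyed by pentamer.
#' @export
shape_table <- function(values) {
  keys <- names(values)
  rc <- revcomp_chr(keys)
  # reverse-complement closure, then symmetrize
  missing_rc <- setdiff(rc, keys)
  if (length(missing_rc)) {
    add <- setNames(values[match(missing_rc, rc)], missing_rc)
    values <- c(values, add)
    keys <- names(values)
    rc <- revcomp_chr(keys)
  }
  asym <- abs(values - values[rc]) > 1e-9
  if (any(asym)) {
    warn(sprintf("%d pentamer pair(s) violated strand symmetry; symmetrized by averaging",
                 sum(asym) / 2))
    values <- (values + values[rc]) / 2
  }
  complete <- length(values) == 1024
  structure(values, class = "shape_table", complete = complete)
}

#' Write a shape table as TSV
#' @param table A `shape_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shape_table <- function(table, path) {
  writeLines(sprintf("%s\t%s", names(table),
                     format(as.numeric(table), trim = TRUE, digits = 10)),
             path)
  invisible(path)
}

#' Synthetic pentamer minor-groove-width table
#'
#' A toy, fully synthetic lookup in which the width grows with the A/T
#' content of the pentamer reversed in sign: `value = base - at_step *
#' (#A + #T)`, so AT-rich cores are narrow, as real minor grooves tend to
#' be. Strand-symmetric and complete by construction. Intended for tests and
#' examples; real analyses should load a published pentamer query table.
#'
#' @param base Width (Angstrom) of a pentamer with no A/T (default 6.2).
#' @param at_step Width decrement per A/T base (default 0.35).
#' @return A `shape_table` over all 1024 pentamers.
#' @export
synthetic_mgw_table <- function(base = 6.2, at_step = 0.35) {
  pent <- do.call(paste0, expand.grid(rep(list(DNA_BASES), 5),
                                      stringsAsFactors = FALSE)[, 5:1])
  at <- vapply(strsplit(pent, ""), function(s) sum(s %in% c("A", "T")),
               numeric(1))
  shape_table(setNames(base - at_step * at, pent))
}

#' Predict per-base minor groove width from a pentamer table
#'
#' Position i (0-based: 2..L-3) receives the table value of the pentamer
#' centred on it; the two outermost positions on each side, pentamers
#' containing `N`, and pentamers missing from a partial table yield `NA`.
#'
#' @param seq A DNA string (character or [Biostrings::DNAString]).
#' @param table A `shape_table`.
#' @return Numeric vector of length `nchar(seq)`.
#' @export
mgw_predict <- function(seq, table) {
  s <- toupper(as.character(seq))
  L <- nchar(s)
  out <- rep(NA_real_, L)
  if (L < 5) return(out)
  pent <- substring(s, seq_len(L - 4), seq_len(L - 4) + 4L)
  out[3:(L - 2)] <- unname(table[pent])
  out
}

# Per-base GC indicator: 1 for G/C, 0 for A/T, NA otherwise.
gc_per_base <- function(seq) {
  b <- strsplit(toupper(as.character(seq)), "")[[1]]
  out <- rep(NA_real_, length(b))
  out[b %in% c("G", "C")] <- 1
  out[b %in% c("A", "T")] <- 0
  out
}

#' Summit-centred average profile of a per-base sequence feature
#'
#' Takes the `span`-bp window centred on each peak's summit (peaks without a
#' summit fall back to the interval midpoint, with a message; windows
#' crossing a chromosome edge are dropped with a warning), computes the
#' chosen per-base value (minor groove width from a pentamer table, or GC
#' indicator), averages across peaks at each relative position ignoring
#' missing values, then smooths the averaged profile with a `window`-bp
#' sliding mean advanced in `step`-bp increments (average first, then
#' smooth). Smoothed values are reported at window midpoints.
#'
#' @param peaks A [peak_set()].
#' @param genome A [Biostrings::DNAStringSet].
#' @param mode `"mgw"` or `"gc"`.
#' @param table A `shape_table` (required for `mode = "mgw"`).
#' @param span Window span centred on the summit (even; default 2000).
#' @param window Smoothing window in bp (default 100).
#' @param step Smoothing step in bp (default 10).
#' @return Tibble of class `summit_profile` with columns `rel_pos` (window
#'   midpoint relative to the summit), `value` (smoothed mean), `n_min`
#'   (smallest per-position peak coverage inside the window). The unsmoothed
#'   per-position profile is available via [tidy()].
#' @export
summit_profile <- function(peaks, genome, mode = c("mgw", "gc"),
                           table = NULL, span = 2000L, window = 100L,
                           step = 10L) {
  mode <- match.arg(mode)
  span <- as.integer(span); window <- as.integer(window)
  step <- as.integer(step)
  if (span %% 2 != 0) abort("`span` must be even")
  if (window > span) abort("`window` must not exceed `span`")
  if (mode == "mgw" && is.null(table)) {
    abort("`table` is required for mode = 'mgw'")
  }
  check_chroms(peaks$chrom, genome, "peak set")
  if (anyNA(peaks$summit)) {
    inform(sprintf("%d peak(s) without summit use the interval midpoint",
                   sum(is.na(peaks$summit))))
  }
  ctr <- peak_centers(peaks)
  half <- span %/% 2L
  lens <- genome_lengths(genome)
  lo <- ctr - half
  hi <- ctr + half
  ok <- lo >= 0 & hi <= lens[peaks$chrom]
  if (any(!ok)) {
    warn(sprintf("%d peak window(s) exceeding chromosome bounds were dropped",
                 sum(!ok)))
  }
  if (!any(ok)) abort("all peak windows fall outside the genome")
  keep <- which(ok)

  sums <- numeric(span)
  n <- numeric(span)
  per_base <- switch(mode,
                     mgw = function(s) mgw_predict(s, table),
                     gc = gc_per_base)
  for (i in keep) {
    s <- as.character(Biostrings::subseq(genome[[peaks$chrom[i]]],
                                         lo[i] + 1L, hi[i]))
    v <- per_base(s)
    has <- !is.na(v)
    sums[has] <- sums[has] + v[has]
    n <- n + has
  }
  raw <- tibble(rel_pos = seq_len(span) - half - 1L,
                mean = ifelse(n > 0, sums / n, NA_real_),
                n = as.integer(n))

  starts <- seq(1L, span - window + 1L, by = step)
  smoothed <- zoo::rollapply(raw$mean, width = window, by = step,
                             FUN = function(v) mean(v, na.rm = TRUE),
                             align = "left")
  n_min <- zoo::rollapply(raw$n, width = window, by = step, FUN = min,
                          align = "left")
  out <- tibble(
    rel_pos = raw$rel_pos[starts] + (window - 1) / 2,
    value = as.numeric(smoothed),
    n_min = as.integer(n_min)
  )
  structure(out, class = c("summit_profile", class(tibble())),
            raw = raw, mode = mode, span = span, window = window,
            step = step, n_peaks = length(keep),
            set_name = set_name(peaks))
}

#' @rdname summit_profile
#' @param x A `summit_profile`.
#' @param ... Unused.
#' @method tidy summit_profile
#' @export
tidy.summit_profile <- function(x, ...) {
  attr(x, "raw")
}
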