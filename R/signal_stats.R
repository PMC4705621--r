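# Track-level statistics: binned binding scores, their correlation between
# factors, per-peak median signal, and differential ranking of peaks by the
# ratio of two tracks (e.g. Hox binding versus DNase1 accessibility).

#' Bin a signal track into fixed windows
#'
#' Divides each chromosome into non-overlapping windows of `w` bp and reports
#' the mean per-base pileup in each (implicit zeros included); the last,
#' possibly partial, window is averaged over its actual length. The window
#' mean is the "binding score" used for between-factor correlations.
#'
#' @param track A [signal_track()].
#' @param genome A [Biostrings::DNAStringSet] or named vector of chromosome
#'   lengths; every track chromosome must be present.
#' @param w Window size in bp (default 1000).
#' @return Tibble of class `binned_profile` with columns `chrom`, `window`
#'   (0-based index), `start`, `end`, `value`.
#' @export
bin_track <- function(track, genome, w = 1000L) {
  w <- as.integer(w)
  if (w < 1) abort("`w` must be >= 1")
  lens <- if (is.numeric(genome)) genome else genome_lengths(genome)
  missing <- setdiff(unique(track$chrom), names(lens))
  if (length(missing)) {
    abort(paste0("track references chromosome(s) absent from the genome: ",
                 paste(missing, collapse = ", ")))
  }
  out <- purrr::map(names(lens), function(cm) {
    len <- as.integer(lens[[cm]])
    n_win <- ceiling(len / w)
    win <- tibble(chrom = cm, window = seq_len(n_win) - 1L)
    win$start <- win$window * w
    win$end <- pmin(win$start + w, len)
    sums <- numeric(n_win)
    s <- track[track$chrom == cm, ]
    if (nrow(s)) {
      if (any(s$end > len)) {
        abort(paste0("track extends beyond chromosome ", cm))
      }
      # split each step across the windows it touches
      first <- s$start %/% w
      last <- (s$end - 1L) %/% w
      for (i in seq_len(nrow(s))) {
        ws <- first[i]:last[i]
        lo <- pmax(s$start[i], ws * w)
        hi <- pmin(s$end[i], (ws + 1L) * w)
        sums[ws + 1L] <- sums[ws + 1L] + s$value[i] * (hi - lo)
      }
    }
    win$value <- sums / (win$end - win$start)
    win
  })
  structure(dplyr::bind_rows(out),
            class = c("binned_profile", class(tibble())),
            window_size = w,
            track_name = attr(track, "track_name") %||% "track")
}

#' Pearson correlation of two binned binding profiles
#'
#' @param p1,p2 [bin_track()] outputs on identical window grids.
#' @return One-row tibble with `r`, `n_windows` and the two track names; `r`
#'   is `NA` (with a warning) when either profile has zero variance.
#' @export
profile_correlation <- function(p1, p2) {
  if (!identical(attr(p1, "window_size"), attr(p2, "window_size")) ||
      !identical(p1$chrom, p2$chrom) || !identical(p1$window, p2$window)) {
    abort("profiles must share an identical window grid")
  }
  r <- if (stats::sd(p1$value) == 0 || stats::sd(p2$value) == 0) {
    warn("zero variance in a profile; correlation undefined")
    NA_real_
  } else {
    cor(p1$value, p2$value, method = "pearson")
  }
  tibble(track_a = attr(p1, "track_name"), track_b = attr(p2, "track_name"),
         r = r, n_windows = nrow(p1),
         window_size = attr(p1, "window_size"))
}

#' Per-peak median track signal
#'
#' Median of the base-resolved track value over every base of each peak;
#' bases not covered by any bedGraph step contribute 0. This is the per-peak
#' accessibility summary whose distribution separates open- from
#' closed-chromatin peak classes.
#'
#' @param peaks A non-empty [peak_set()].
#' @param track A [signal_track()].
#' @return Tibble of class `peak_signal_summary`: peak columns plus
#'   `median_signal`. [glance()] returns the quartiles of the distribution.
#' @export
peak_median_signal <- function(peaks, track) {
  if (nrow(peaks) == 0) abort("`peaks` must be non-empty")
  queries <- dplyr::mutate(as_tibble(peaks)[, c("chrom", "start", "end")],
                           qid = dplyr::row_number())
  pieces <- track_pieces(track, queries)
  lens <- peaks$end - peaks$start
  med <- vapply(seq_len(nrow(peaks)), function(i) {
    p <- pieces[pieces$qid == i, ]
    zero_w <- lens[i] - sum(p$width)
    weighted_median(c(p$value, 0), c(p$width, zero_w))
  }, numeric(1))
  out <- dplyr::mutate(as_tibble(peaks), median_signal = med)
  structure(out, class = c("peak_signal_summary", class(tibble())),
            set_name = set_name(peaks),
            track_name = attr(track, "track_name") %||% "track")
}

#' @rdname peak_median_signal
#' @param x A `peak_signal_summary`.
#' @param ... Unused.
#' @method glance peak_signal_summary
#' @export
glance.peak_signal_summary <- function(x, ...) {
  q <- quantile(x$median_signal, c(0.25, 0.5, 0.75))
  tibble(set = attr(x, "set_name"), track = attr(x, "track_name"),
         n_peaks = nrow(x), q25 = q[[1]], median = q[[2]], q75 = q[[3]])
}

# Mean per-base pileup over each query interval (implicit zeros included).
peak_mean_signal <- function(peaks, track) {
  queries <- dplyr::mutate(as_tibble(peaks)[, c("chrom", "start", "end")],
                           qid = dplyr::row_number())
  pieces <- track_pieces(track, queries)
  sums <- numeric(nrow(peaks))
  if (nrow(pieces)) {
    agg <- tapply(pieces$value * pieces$width, pieces$qid, sum)
    sums[as.integer(names(agg))] <- agg
  }
  sums / (peaks$end - peaks$start)
}

#' Rank peaks by differential signal between two tracks
#'
#' Scores each peak by `D = log2((mean_a + c) / (mean_b + c))`, the log-ratio
#' of its mean pileup in track `a` versus track `b` with pseudocount `c`, and
#' ranks peaks by decreasing D (ties broken by chromosome, then start). Used
#' to select e.g. the peaks with the highest factor-binding versus
#' accessibility differential. With `mode = "summit"` the mean is taken over
#' a +/-100 bp window around the summit instead of the whole peak.
#'
#' @param peaks A [peak_set()].
#' @param a,b [signal_track()]s, both normalized the same way.
#' @param c Pseudocount (> 0; default 0.1).
#' @param n_top Size of the selected top subset (default all peaks).
#' @param mode `"mean"` (whole peak) or `"summit"` (+/-100 bp of summit).
#' @return Tibble of class `differential_ranking`: peak columns plus
#'   `a_signal`, `b_signal`, `diff_score`, `rank`, sorted by rank. The
#'   top-`n_top` subset is available via [top_peaks()].
#' @export
differential_rank <- function(peaks, a, b, c = 0.1, n_top = nrow(peaks),
                              mode = c("mean", "summit")) {
  mode <- match.arg(mode)
  if (!(c > 0)) abort("pseudocount `c` must be > 0")
  if (n_top > nrow(peaks)) {
    abort(sprintf("`n_top` (%d) exceeds the number of peaks (%d)",
                  n_top, nrow(peaks)))
  }
  q <- as_tibble(peaks)
  if (mode == "summit") {
    ctr <- peak_centers(peaks)
    if (anyNA(peaks$summit)) {
      inform("peaks without summit use the interval midpoint")
    }
    q$start <- pmax(0L, ctr - 100L)
    q$end <- ctr + 100L
  }
  qa <- peak_mean_signal(q, a)
  qb <- peak_mean_signal(q, b)
  out <- dplyr::mutate(as_tibble(peaks),
                       a_signal = qa, b_signal = qb,
                       diff_score = log2((qa + c) / (qb + c)))
  ord <- order(-out$diff_score, out$chrom, out$start)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("differential_ranking", class(tibble())),
            set_name = set_name(peaks), n_top = as.integer(n_top),
            pseudocount = c, mode = mode,
            track_a = attr(a, "track_name"), track_b = attr(b, "track_name"),
            stringency = attr(peaks, "stringency"),
            whitelist = attr(peaks, "whitelist"))
}

#' Top-ranked subset of a differential ranking
#'
#' @param ranking A [differential_rank()] result.
#' @param n Number of peaks to keep (defaults to the `n_top` used).
#' @return A [peak_set()] of the `n` highest-ranked peaks.
#' @export
top_peaks <- function(ranking, n = attr(ranking, "n_top")) {
  peak_set(
    as_tibble(ranking)[seq_len(n), c("chrom", "start", "end", "name",
                                     "score", "summit")],
    set_name = paste0(attr(ranking, "set_name"), "_top", n),
    stringency = attr(ranking, "stringency"),
    whitelist = attr(ranking, "whitelist")
  )
}
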