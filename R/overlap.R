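# Peak-set algebra built on the reciprocal-overlap rule.
#
# Two peaks a, b "qualify" as the same binding site iff their overlap covers
# at least a fraction f of BOTH intervals: ov >= max(1, ceiling(f*len_a)) and
# ov >= max(1, ceiling(f*len_b)). ceiling makes the stated minimum fraction a
# true minimum, and the 1 bp floor reproduces bedtools' minimum overlap. A
# peak counts once no matter how many partners qualify (bedtools -u); the
# "specific" complement reproduces -v.

# Indices of peaks in `a` with >= 1 qualifying partner in `b`.
qualifying_idx <- function(a, b, f) {
  hit <- logical(nrow(a))
  for (cm in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- which(a$chrom == cm)
    bi <- which(b$chrom == cm)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(a$start[ai] + 1L, a$end[ai]),
      IRanges::IRanges(b$start[bi] + 1L, b$end[bi])
    )
    if (!length(hits)) next
    qa <- ai[S4Vectors::queryHits(hits)]
    qb <- bi[S4Vectors::subjectHits(hits)]
    ov <- pmin(a$end[qa], b$end[qb]) - pmax(a$start[qa], b$start[qb])
    la <- a$end[qa] - a$start[qa]
    lb <- b$end[qb] - b$start[qb]
    ok <- ov >= pmax(1, ceiling(f * la)) & ov >= pmax(1, ceiling(f * lb))
    hit[unique(qa[ok])] <- TRUE
  }
  which(hit)
}

#' Reciprocal-overlap analysis of two peak sets
#'
#' Counts, in each direction, the peaks with at least one reciprocal-overlap
#' partner in the other set (the Venn-style percentages of a pairwise
#' comparison), and returns the common/specific partitions of both sets.
#'
#' @param a,b [peak_set()] tibbles.
#' @param f Minimum reciprocal overlap fraction (default 0.05).
#' @return An object of class `overlap_result`: a list with counts,
#'   percentages (`NA` for an empty set, not 0) and the four partition
#'   `peak_set`s (`common_a`, `specific_a`, `common_b`, `specific_b`).
#'   [tidy()] gives one row per direction; [glance()] a one-row summary.
#' @export
reciprocal_overlap <- function(a, b, f = 0.05) {
  if (!(f > 0 && f <= 1)) abort("`f` must be in (0, 1]")
  ia <- qualifying_idx(a, b, f)
  ib <- qualifying_idx(b, a, f)
  n_a <- nrow(a); n_b <- nrow(b)
  res <- list(
    set_a_name = set_name(a), set_b_name = set_name(b), f = f,
    n_a = n_a, n_b = n_b,
    n_a_overlapping = length(ia), n_b_overlapping = length(ib),
    pct_a = if (n_a > 0) 100 * length(ia) / n_a else NA_real_,
    pct_b = if (n_b > 0) 100 * length(ib) / n_b else NA_real_,
    common_a = as_peak_set(a[ia, ], a,
                           set_name = paste0(set_name(a), "_common")),
    specific_a = as_peak_set(a[setdiff(seq_len(n_a), ia), ], a,
                             set_name = paste0(set_name(a), "_specific")),
    common_b = as_peak_set(b[ib, ], b,
                           set_name = paste0(set_name(b), "_common")),
    specific_b = as_peak_set(b[setdiff(seq_len(n_b), ib), ], b,
                             set_name = paste0(set_name(b), "_specific"))
  )
  structure(res, class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "# overlap_result (f = %g)\n#  %s: %d/%d peaks overlap %s (%.1f%%)\n#  %s: %d/%d peaks overlap %s (%.1f%%)\n",
    x$f, x$set_a_name, x$n_a_overlapping, x$n_a, x$set_b_name, x$pct_a,
    x$set_b_name, x$n_b_overlapping, x$n_b, x$set_a_name, x$pct_b))
  invisible(x)
}

#' @rdname reciprocal_overlap
#' @param x An `overlap_result`.
#' @param ... Unused.
#' @method tidy overlap_result
#' @export
tidy.overlap_result <- function(x, ...) {
  tibble(
    set = c(x$set_a_name, x$set_b_name),
    other = c(x$set_b_name, x$set_a_name),
    n = c(x$n_a, x$n_b),
    n_overlapping = c(x$n_a_overlapping, x$n_b_overlapping),
    pct = c(x$pct_a, x$pct_b),
    f = x$f
  )
}

#' @rdname reciprocal_overlap
#' @method glance overlap_result
#' @export
glance.overlap_result <- function(x, ...) {
  tibble(set_a = x$set_a_name, set_b = x$set_b_name, f = x$f,
         n_a = x$n_a, n_b = x$n_b, pct_a = x$pct_a, pct_b = x$pct_b)
}

#' Partition a peak set by overlap with a reference set
#'
#' Splits `a` into the peaks with a qualifying reciprocal-overlap partner in
#' `ref` (`common`) and the rest (`specific`). The two parts are disjoint,
#' preserve coordinate order, and together restore `a`.
#'
#' @param a,ref [peak_set()] tibbles.
#' @param f Minimum reciprocal overlap fraction.
#' @return List with `peak_set` elements `common` and `specific`.
#' @export
partition_by_reference <- function(a, ref, f = 0.05) {
  ia <- qualifying_idx(a, ref, f)
  list(
    common = as_peak_set(a[ia, ], a,
                         set_name = paste0(set_name(a), "_common")),
    specific = as_peak_set(a[setdiff(seq_len(nrow(a)), ia), ], a,
                           set_name = paste0(set_name(a), "_specific"))
  )
}

#' Per-focal-set Venn counts for two or three peak sets
#'
#' For each focal set, classifies every peak by which OTHER sets it has a
#' qualifying reciprocal-overlap partner in. Because reciprocal overlap is
#' not transitive, counts are reported per focal set (matching pairwise Venn
#' percentages) rather than as a single 7-region partition.
#'
#' @param sets Named list of 2 or 3 [peak_set()]s.
#' @param f Minimum reciprocal overlap fraction.
#' @return Tibble with columns `focal_set`, `pattern` (comma-separated names
#'   of the other sets hit, `"none"` for exclusive peaks), `n_peaks`, `pct`.
#' @export
venn_counts <- function(sets, f = 0.05) {
  if (length(sets) < 2 || length(sets) > 3) {
    abort("`venn_counts()` supports 2 or 3 peak sets")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- vapply(sets, set_name, character(1))
  }
  out <- purrr::imap(sets, function(a, nm) {
    others <- sets[setdiff(names(sets), nm)]
    hits <- purrr::map(others, function(b) {
      v <- logical(nrow(a)); v[qualifying_idx(a, b, f)] <- TRUE; v
    })
    hm <- do.call(cbind, hits)
    pattern <- apply(hm, 1, function(r) {
      if (!any(r)) "none" else paste(colnames(hm)[r], collapse = ",")
    })
    tibble(focal_set = nm, pattern = pattern) |>
      dplyr::count(.data$focal_set, .data$pattern, name = "n_peaks") |>
      dplyr::mutate(pct = 100 * .data$n_peaks / nrow(a))
  })
  dplyr::bind_rows(out)
}

#' Overlap of a stringent peak set with a relaxed one
#'
#' The stringent-versus-relaxed check: what percentage of high-stringency
#' peaks of one factor fall within the low-stringency peaks of another.
#'
#' @param a_stringent Stringent [peak_set()] (e.g. q <= 1e-10).
#' @param b_relaxed Relaxed [peak_set()] (e.g. q <= 1e-2).
#' @param f Minimum reciprocal overlap fraction.
#' @return One-row tibble with `pct` (of stringent peaks in relaxed set) and
#'   the underlying counts.
#' @export
stringent_vs_relaxed <- function(a_stringent, b_relaxed, f = 0.05) {
  ov <- reciprocal_overlap(a_stringent, b_relaxed, f)
  tibble(stringent_set = ov$set_a_name, relaxed_set = ov$set_b_name,
         n_stringent = ov$n_a, n_overlapping = ov$n_a_overlapping,
         pct = ov$pct_a, f = f)
}
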