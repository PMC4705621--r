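# Signal tracks: bedGraph-semantics step functions of normalized pileup.
#
# A signal track is a tibble with columns chrom, start, end, value where
# intervals are non-overlapping and sorted within each chromosome and every
# uncovered base has implicit value 0. Values are assumed already normalized
# per million reads and are never rescaled.

#' Construct a signal track
#'
#' @param x Data frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open intervals).
#' @param track_name Label for the track.
#' @param normalization Tag recording the scaling of the values (default
#'   `"per_million"`, the MACS2 `-B --SPMR` convention).
#' @return A tibble of class `signal_track`.
#' @export
signal_track <- function(x, track_name = "track",
                         normalization = "per_million") {
  x <- as_tibble(x)
  miss <- setdiff(c("chrom", "start", "end", "value"), names(x))
  if (length(miss)) abort(paste0("missing track columns: ",
                                 paste(miss, collapse = ", ")))
  x <- dplyr::transmute(x,
    chrom = as.character(.data$chrom),
    start = as.integer(.data$start),
    end = as.integer(.data$end),
    value = as.numeric(.data$value)
  )
  if (any(x$value < 0)) abort("track values must be >= 0")
  if (any(x$start >= x$end)) abort("track intervals must have start < end")

  sorted <- !is.unsorted(order(x$chrom, x$start))
  resorted <- dplyr::arrange(x, .data$chrom, .data$start)
  if (!identical(resorted$start, x$start) ||
      !identical(resorted$chrom, x$chrom)) {
    warn(paste0("track '", track_name, "' was unsorted; sorting"))
  }
  x <- resorted
  by_chrom <- split(seq_len(nrow(x)), x$chrom)
  for (idx in by_chrom) {
    if (length(idx) > 1 &&
        any(x$start[idx][-1] < head(x$end[idx], -1))) {
      abort(paste0("track '", track_name,
                   "' has overlapping intervals; bedGraph steps must be disjoint"))
    }
  }
  structure(x, class = c("signal_track", class(tibble())),
            track_name = track_name, normalization = normalization)
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("# signal_track '%s' (%s): %d steps on %d chromosome(s)\n",
              attr(x, "track_name") %||% "track",
              attr(x, "normalization") %||% "?", nrow(x),
              dplyr::n_distinct(x$chrom)))
  NextMethod()
}

#' Read a bedGraph signal track
#'
#' @param path bedGraph file (optionally gzip-compressed), numeric column 4.
#' @param track_name Label; defaults to the file name.
#' @param normalization Scaling tag recorded on the track.
#' @return A `signal_track` tibble.
#' @export
read_bedgraph <- function(path,
                          track_name = sub("\\.(bdg|bedgraph|bedGraph)(\\.gz)?$",
                                           "", basename(path)),
                          normalization = "per_million") {
  fields <- read_tab_fields(path)
  if (!length(fields)) abort(paste0(path, ": no records"))
  ncols <- lengths(fields)
  bad <- which(ncols < 4)
  if (length(bad)) {
    abort(sprintf("%s: line %d has %d field(s); bedGraph requires 4",
                  path, attr(fields, "line_no")[bad[1]], ncols[bad[1]]))
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:4))
  ln <- attr(fields, "line_no")
  df <- tibble(
    chrom = m[, 1],
    start = as.integer(parse_num(m[, 2], path, ln, "start")),
    end = as.integer(parse_num(m[, 3], path, ln, "end")),
    value = parse_num(m[, 4], path, ln, "value")
  )
  if (any(df$value < 0)) {
    abort(paste0(path, ": negative bedGraph values are not allowed"))
  }
  signal_track(df, track_name = track_name, normalization = normalization)
}

#' Write a signal track as bedGraph
#'
#' @param track A `signal_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end,
                     format(track$value, trim = TRUE, scientific = FALSE,
                            digits = 15)),
             path)
  invisible(path)
}

#' Query a track at single bases
#'
#' @param track A `signal_track`.
#' @param chrom Chromosome name (recycled).
#' @param pos 0-based base positions.
#' @return Numeric vector of values (0 where uncovered).
#' @export
track_value_at <- function(track, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  out <- numeric(n)
  for (cm in unique(chrom)) {
    steps <- track[track$chrom == cm, ]
    sel <- which(chrom == cm)
    if (!nrow(steps)) next
    i <- findInterval(pos[sel], steps$start)
    hit <- i >= 1 & pos[sel] < steps$end[pmax(i, 1)]
    out[sel][hit] <- steps$value[i[hit]]
  }
  out
}

# Decompose arbitrary query intervals against the track's step function.
# Returns one row per (query, step-piece) with the covered width; uncovered
# bases are NOT returned (they have implicit value 0). queries: tibble with
# chrom/start/end and a query index `qid`.
track_pieces <- function(track, queries) {
  out <- vector("list", length(unique(queries$chrom)))
  k <- 0L
  for (cm in unique(queries$chrom)) {
    q <- queries[queries$chrom == cm, ]
    s <- track[track$chrom == cm, ]
    if (!nrow(s) || !nrow(q)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(q$start + 1L, q$end),
      IRanges::IRanges(s$start + 1L, s$end)
    )
    if (!length(hits)) next
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    w <- pmin(q$end[qi], s$end[si]) - pmax(q$start[qi], s$start[si])
    k <- k + 1L
    out[[k]] <- tibble(qid = q$qid[qi], value = s$value[si], width = w)
  }
  if (k == 0L) return(tibble(qid = integer(), value = numeric(),
                             width = integer()))
  dplyr::bind_rows(out[seq_len(k)])
}
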