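# Peak sets: tibble-first container for ChIP-Seq peak calls.
#
# A peak set is a tibble with columns chrom, start, end, name, score, summit
# (0-based half-open coordinates; summit is an absolute coordinate or NA),
# carrying the set label, MACS2 q-value stringency tag and chromosome
# whitelist as attributes. All set algebra operates on this container.

#' Construct a peak set
#'
#' Builds a validated peak-set tibble from per-peak coordinates. Coordinates
#' are 0-based half-open (BED native); a peak of length L covers exactly L
#' bases in every base-resolved computation downstream. Peaks on
#' non-whitelisted chromosomes are dropped (and counted in the
#' `n_dropped` attribute); within each chromosome peaks are sorted by start.
#'
#' @param x A data frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `summit` (absolute coordinate).
#' @param set_name Label for the set (e.g. `"Ubx_exp1"`).
#' @param stringency Peak-calling stringency tag (e.g. `"1e-10"`).
#' @param whitelist Chromosomes to retain; `NULL` keeps everything.
#' @return A tibble of class `peak_set`.
#' @examples
#' peak_set(data.frame(chrom = "chr2L", start = 100, end = 300),
#'          set_name = "toy")
#' @export
peak_set <- function(x, set_name = "peaks", stringency = NA_character_,
                     whitelist = default_whitelist()) {
  x <- as_tibble(x)
  req <- c("chrom", "start", "end")
  miss <- setdiff(req, names(x))
  if (length(miss)) abort(paste0("missing peak columns: ",
                                 paste(miss, collapse = ", ")))
  if (!"name" %in% names(x)) x$name <- paste0("peak_", seq_len(nrow(x)))
  if (!"score" %in% names(x)) x$score <- NA_real_
  if (!"summit" %in% names(x)) x$summit <- NA_integer_
  x <- dplyr::mutate(x,
    chrom = as.character(.data$chrom),
    start = as.integer(.data$start),
    end = as.integer(.data$end),
    name = as.character(.data$name),
    score = as.numeric(.data$score),
    summit = as.integer(.data$summit)
  )
  x <- dplyr::select(x, "chrom", "start", "end", "name", "score", "summit")

  bad <- which(!(x$start < x$end))
  if (length(bad)) {
    abort(paste0("peak ", x$name[bad[1]], ": start must be < end"))
  }
  s <- x$summit
  bad <- which(!is.na(s) & !(x$start <= s & s < x$end))
  if (length(bad)) {
    abort(paste0("peak ", x$name[bad[1]],
                 ": summit must satisfy start <= summit < end"))
  }

  n_dropped <- 0L
  if (!is.null(whitelist)) {
    keep <- x$chrom %in% whitelist
    n_dropped <- sum(!keep)
    x <- x[keep, , drop = FALSE]
  }
  x <- dplyr::arrange(x, .data$chrom, .data$start, .data$end)

  ov <- dplyr::group_by(x, .data$chrom)
  ov <- dplyr::summarise(ov,
    any_ov = any(.data$start[-1] < head(.data$end, -1)), .groups = "drop")
  if (nrow(x) > 1 && any(ov$any_ov, na.rm = TRUE)) {
    warn(paste0("peak set '", set_name,
                "' contains overlapping peaks; they are kept, not merged"))
  }

  structure(x,
            class = c("peak_set", class(tibble())),
            set_name = set_name, stringency = stringency,
            whitelist = whitelist, n_dropped = n_dropped)
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("# peak_set '%s' (stringency %s): %d peaks on %d chromosome(s)\n",
              set_name(x), attr(x, "stringency") %||% NA, nrow(x),
              dplyr::n_distinct(x$chrom)))
  NextMethod()
}

#' Set label of a peak set
#' @param x A `peak_set`.
#' @return The set label.
#' @export
set_name <- function(x) attr(x, "set_name") %||% "peaks"

# Rebuild attributes after dplyr operations strip the subclass.
as_peak_set <- function(x, template, set_name = NULL) {
  peak_set(as_tibble(x),
           set_name = set_name %||% attr(template, "set_name"),
           stringency = attr(template, "stringency"),
           whitelist = attr(template, "whitelist"))
}

#' Read peak calls from BED or narrowPeak
#'
#' Reads a (possibly gzip-compressed) BED3/BED6 or 10-column ENCODE
#' narrowPeak file into a [peak_set()]. For narrowPeak, column 10 holds the
#' summit offset from the peak start; an offset of -1 (summit not reported)
#' leaves the summit absent. Column 7 (signalValue) populates `score` for
#' narrowPeak; BED6 uses column 5.
#'
#' @param path File path.
#' @param format `"auto"` (by extension/column count), `"bed"` or
#'   `"narrowPeak"`.
#' @param set_name,stringency,whitelist Passed to [peak_set()].
#' @return A `peak_set` tibble.
#' @export
read_peaks <- function(path, format = c("auto", "narrowPeak", "bed"),
                       set_name = sub("\\.(narrowPeak|bed)(\\.gz)?$", "",
                                      basename(path)),
                       stringency = NA_character_,
                       whitelist = default_whitelist()) {
  format <- match.arg(format)
  fields <- read_tab_fields(path)
  if (!length(fields)) abort(paste0(path, ": no records"))
  ncols <- lengths(fields)
  if (format == "auto") {
    format <- if (grepl("\\.narrowPeak(\\.gz)?$", path) || all(ncols == 10))
      "narrowPeak" else "bed"
  }
  need <- if (format == "narrowPeak") 10L else 3L
  bad <- which(ncols < need)
  if (length(bad)) {
    abort(sprintf("%s: line %d has %d field(s); %s requires >= %d",
                  path, attr(fields, "line_no")[bad[1]], ncols[bad[1]],
                  format, need))
  }

  get_col <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[i] else NA_character_, character(1))
  chrom <- get_col(1)
  start <- parse_num(get_col(2), path, attr(fields, "line_no"), "start")
  end <- parse_num(get_col(3), path, attr(fields, "line_no"), "end")
  name <- if (all(ncols >= 4)) get_col(4) else NA_character_
  score <- NA_real_
  summit <- NA_integer_
  if (format == "narrowPeak") {
    score <- parse_num(get_col(7), path, attr(fields, "line_no"),
                       "signalValue")
    offset <- parse_num(get_col(10), path, attr(fields, "line_no"), "summit")
    summit <- ifelse(offset >= 0, as.integer(start + offset), NA_integer_)
  } else if (all(ncols >= 5)) {
    score <- suppressWarnings(as.numeric(get_col(5)))
  }
  df <- tibble(chrom = chrom, start = start, end = end,
               name = if (all(is.na(name))) paste0("peak_", seq_along(chrom))
                      else name,
               score = score, summit = summit)
  peak_set(df, set_name = set_name, stringency = stringency,
           whitelist = whitelist)
}

# Split a text table into fields, skipping headers/comments, keeping the
# original line numbers for error messages.
read_tab_fields <- function(path) {
  if (!file.exists(path)) abort(paste0(path, ": no such file"))
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  line_no <- seq_along(lines)
  keep <- !grepl("^(#|track |browser )", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- line_no[keep]
  fields <- strsplit(lines, "[ \t]+")
  attr(fields, "line_no") <- line_no
  fields
}

parse_num <- function(x, path, line_no, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    abort(sprintf("%s: line %d: cannot parse %s '%s'",
                  path, line_no[bad[1]], what, x[bad[1]]))
  }
  out
}

#' Write a peak set as BED6 or narrowPeak
#'
#' @param peaks A `peak_set`.
#' @param path Output path. A `.narrowPeak` extension (or
#'   `format = "narrowPeak"`) writes 10 columns with the summit offset in
#'   column 10 (-1 when absent); otherwise BED6.
#' @param format `"auto"`, `"bed"` or `"narrowPeak"`.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path, format = c("auto", "bed", "narrowPeak")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.narrowPeak$", path)) "narrowPeak" else "bed"
  }
  score <- ifelse(is.na(peaks$score), 0, peaks$score)
  if (format == "narrowPeak") {
    offset <- ifelse(is.na(peaks$summit), -1L,
                     as.integer(peaks$summit - peaks$start))
    out <- sprintf("%s\t%d\t%d\t%s\t0\t.\t%s\t-1\t-1\t%d",
                   peaks$chrom, peaks$start, peaks$end, peaks$name,
                   format(score, trim = TRUE, scientific = FALSE), offset)
  } else {
    out <- sprintf("%s\t%d\t%d\t%s\t%s\t.",
                   peaks$chrom, peaks$start, peaks$end, peaks$name,
                   format(score, trim = TRUE, scientific = FALSE))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read transcription start sites from BED6
#'
#' Each record contributes one TSS: the interval start for `+` strand
#' entries, the interval end minus one for `-` strand entries (the 0-based
#' first transcribed base in both cases).
#'
#' @param path BED6 file with strand in column 6.
#' @param whitelist Chromosomes retained; `NULL` keeps everything.
#' @return Tibble with columns `chrom`, `pos`, `strand`, `name`.
#' @export
read_tss <- function(path, whitelist = default_whitelist()) {
  fields <- read_tab_fields(path)
  ncols <- lengths(fields)
  bad <- which(ncols < 6)
  if (length(bad)) {
    abort(sprintf("%s: line %d has %d field(s); TSS input requires BED6",
                  path, attr(fields, "line_no")[bad[1]], ncols[bad[1]]))
  }
  m <- do.call(rbind, fields)
  start <- parse_num(m[, 2], path, attr(fields, "line_no"), "start")
  end <- parse_num(m[, 3], path, attr(fields, "line_no"), "end")
  strand <- m[, 6]
  if (!all(strand %in% c("+", "-"))) {
    abort(paste0(path, ": strand column must be '+' or '-'"))
  }
  out <- tibble(chrom = m[, 1],
                pos = as.integer(ifelse(strand == "+", start, end - 1)),
                strand = strand, name = m[, 4])
  if (!is.null(whitelist)) out <- out[out$chrom %in% whitelist, ]
  out
}

# Summit if present, otherwise interval midpoint floor((start+end)/2);
# callers log the substitution.
peak_centers <- function(peaks) {
  ifelse(is.na(peaks$summit),
         as.integer(floor((peaks$start + peaks$end) / 2)),
         peaks$summit)
}
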