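# Chromatin colour states: five-state partition of the genome
# (RED, YELLOW = active; BLUE = Polycomb; BLACK = repressive; GREEN = HP1)
# plus implicit UNKNOWN for unannotated bases.

STATE_LABELS <- c("RED", "YELLOW", "BLUE", "BLACK", "GREEN")
STATE_LEVELS <- c(STATE_LABELS, "UNKNOWN")

#' Construct a chromatin-state annotation
#'
#' @param x Data frame with columns `chrom`, `start`, `end`, `state`
#'   (0-based half-open; state one of RED, YELLOW, BLUE, BLACK, GREEN).
#' @return Tibble of class `state_annotation`, sorted, with no overlaps.
#' @export
state_annotation <- function(x) {
  x <- as_tibble(x)
  miss <- setdiff(c("chrom", "start", "end", "state"), names(x))
  if (length(miss)) abort(paste0("missing state columns: ",
                                 paste(miss, collapse = ", ")))
  x <- dplyr::transmute(x,
    chrom = as.character(.data$chrom),
    start = as.integer(.data$start),
    end = as.integer(.data$end),
    state = toupper(as.character(.data$state))
  )
  bad <- setdiff(unique(x$state), STATE_LABELS)
  if (length(bad)) {
    abort(paste0("unknown chromatin state label(s): ",
                 paste(bad, collapse = ", ")))
  }
  x <- dplyr::arrange(x, .data$chrom, .data$start)
  for (cm in unique(x$chrom)) {
    idx <- which(x$chrom == cm)
    if (length(idx) > 1 && any(x$start[idx][-1] < head(x$end[idx], -1))) {
      abort("state intervals must not overlap")
    }
  }
  structure(x, class = c("state_annotation", class(tibble())))
}

#' Read a chromatin-state annotation from BED4
#'
#' @param path BED file with the state label in column 4.
#' @param whitelist Chromosomes retained; `NULL` keeps everything.
#' @return A [state_annotation()] tibble.
#' @export
read_states <- function(path, whitelist = default_whitelist()) {
  fields <- read_tab_fields(path)
  ncols <- lengths(fields)
  bad <- which(ncols < 4)
  if (length(bad)) {
    abort(sprintf("%s: line %d has %d field(s); state BED requires 4",
                  path, attr(fields, "line_no")[bad[1]], ncols[bad[1]]))
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:4))
  ln <- attr(fields, "line_no")
  df <- tibble(chrom = m[, 1],
               start = as.integer(parse_num(m[, 2], path, ln, "start")),
               end = as.integer(parse_num(m[, 3], path, ln, "end")),
               state = m[, 4])
  if (!is.null(whitelist)) df <- df[df$chrom %in% whitelist, ]
  state_annotation(df)
}

#' Write a chromatin-state annotation as BED4
#' @param states A [state_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_states <- function(states, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", states$chrom, states$start,
                     states$end, states$state), path)
  invisible(path)
}

#' Chromatin-state prevalence of a peak set
#'
#' Fraction of the total peak length falling in each of the five colour
#' states; bases of a peak in no annotated interval count as UNKNOWN. The
#' six fractions sum to 1. Peak bases are counted per peak (overlapping
#' peaks contribute their bases as many times as they occur).
#'
#' @param peaks A [peak_set()] with at least one peak.
#' @param states A [state_annotation()].
#' @return Tibble of class `state_prevalence` with columns `state`, `bases`,
#'   `fraction`, ordered RED, YELLOW, BLUE, BLACK, GREEN, UNKNOWN.
#' @export
state_prevalence <- function(peaks, states) {
  total <- sum(as.numeric(peaks$end - peaks$start))
  if (nrow(peaks) == 0 || total == 0) {
    abort("state_prevalence() requires non-zero total peak length")
  }
  queries <- dplyr::mutate(as_tibble(peaks)[, c("chrom", "start", "end")],
                           qid = dplyr::row_number())
  st <- as_tibble(states)
  bases <- setNames(numeric(length(STATE_LEVELS)), STATE_LEVELS)
  covered <- 0
  for (cm in intersect(unique(queries$chrom), unique(st$chrom))) {
    q <- queries[queries$chrom == cm, ]
    s <- st[st$chrom == cm, ]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(q$start + 1L, q$end),
      IRanges::IRanges(s$start + 1L, s$end)
    )
    if (!length(hits)) next
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    w <- pmin(q$end[qi], s$end[si]) - pmax(q$start[qi], s$start[si])
    agg <- tapply(w, s$state[si], sum)
    bases[names(agg)] <- bases[names(agg)] + agg
    covered <- covered + sum(w)
  }
  bases["UNKNOWN"] <- total - covered
  out <- tibble(state = factor(STATE_LEVELS, levels = STATE_LEVELS),
                bases = as.numeric(bases),
                fraction = as.numeric(bases) / total)
  structure(out, class = c("state_prevalence", class(tibble())),
            set_name = set_name(peaks), total_bases = total)
}

#' Genome-wide chromatin-state composition
#'
#' The state prevalence of the whole genome treated as one peak per
#' chromosome — the genome-wide baseline against which peak-set prevalences
#' are compared.
#'
#' @param states A [state_annotation()].
#' @param chrom_lengths Named integer vector of chromosome lengths (e.g.
#'   [genome_lengths()]).
#' @return A `state_prevalence` tibble.
#' @export
genome_state_composition <- function(states, chrom_lengths) {
  peaks <- peak_set(
    tibble(chrom = names(chrom_lengths), start = 0L,
           end = as.integer(chrom_lengths)),
    set_name = "genome", whitelist = NULL
  )
  state_prevalence(peaks, states)
}
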