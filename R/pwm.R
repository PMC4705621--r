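# Position weight matrices: JASPAR-style count input, log-odds scoring on a
# discretized lattice, exact score-threshold p-values by per-position
# convolution, scanning, per-peak match density, and a Poisson motif-set
# enrichment statistic.
#
# Log-odds scores are expressed in bits and rounded to a fixed lattice
# (PWM_LATTICE_RES = 0.01 bits). Both the threshold dynamic programme and the
# scanner use the same lattice matrix, so the p-value attached to a cutoff is
# exact for the scores actually scanned, not an approximation.

PWM_LATTICE_RES <- 0.01

#' Build a PWM from a count matrix
#'
#' Probabilities are `(count + pseudocount * bg) / (colsum + pseudocount)`
#' per position; log-odds are `log2(p / bg)` in bits, rounded to a 0.01-bit
#' lattice shared by the threshold computation and the scanner.
#'
#' @param counts 4 x w non-negative matrix with rows A, C, G, T.
#' @param name Motif name.
#' @param pseudocount Total pseudocount per column, allocated in proportion
#'   to the background (default 0.01). Must be > 0 if any count is zero.
#' @param background Named background nucleotide probabilities (0-order).
#' @return Object of class `pwm`.
#' @export
pwm_from_counts <- function(counts, name = "pwm", pseudocount = 0.01,
                            background = c(A = 0.25, C = 0.25,
                                           G = 0.25, T = 0.25)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) abort("count matrix must have 4 rows (A, C, G, T)")
  rownames(counts) <- DNA_BASES
  if (any(counts < 0)) abort("counts must be non-negative")
  if (any(colSums(counts) <= 0)) {
    abort("every column needs at least one positive count")
  }
  if (ncol(counts) < 4) abort("PWM width must be >= 4")
  background <- background[DNA_BASES] / sum(background[DNA_BASES])
  if (any(background <= 0)) abort("background probabilities must be > 0")
  prob <- sweep(counts + pseudocount * background, 2,
                colSums(counts) + pseudocount, "/")
  if (any(prob == 0)) {
    abort("zero probability in PWM; use a pseudocount > 0")
  }
  log_odds <- round(log2(prob / background) / PWM_LATTICE_RES) *
    PWM_LATTICE_RES
  structure(
    list(name = name, prob = prob, log_odds = log_odds,
         background = background, width = ncol(counts),
         pseudocount = pseudocount),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("# pwm '%s': width %d, max score %.2f bits\n", x$name,
              x$width, sum(apply(x$log_odds, 2, max))))
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param pwm A [pwm_from_counts()] object.
#' @return Character string of the per-position most probable bases.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$prob, 2, which.max)], collapse = "")
}

#' Nucleotide frequencies of a sequence set
#'
#' 0-order background model estimated from a sequence collection (e.g. the
#' TSS-upstream background); `N` bases are ignored.
#'
#' @param seqs A [Biostrings::DNAStringSet].
#' @return Named probability vector over A, C, G, T.
#' @export
background_frequencies <- function(seqs) {
  f <- colSums(Biostrings::alphabetFrequency(seqs)[, DNA_BASES, drop = FALSE])
  f / sum(f)
}

#' Read PWMs from JASPAR-style count files
#'
#' Accepts the JASPAR PFM text layout (`>ID name` header followed by four
#' count rows, with or without `A [ ... ]` brackets) and plain 4-row
#' matrices; multiple records per file are supported.
#'
#' @param path Matrix file.
#' @param pseudocount,background Passed to [pwm_from_counts()].
#' @return `read_pwms()`: named list of `pwm`; `load_pwm()`: the first (or
#'   only) motif in the file.
#' @export
read_pwms <- function(path, pseudocount = 0.01,
                      background = c(A = 0.25, C = 0.25,
                                     G = 0.25, T = 0.25)) {
  if (!file.exists(path)) abort(paste0(path, ": no such file"))
  con <- open_text(path)
  on.exit(close(con))
  lines <- trimws(readLines(con, warn = FALSE))
  lines <- lines[nzchar(lines)]
  headers <- grep("^>", lines)
  blocks <- if (length(headers)) {
    bounds <- c(headers, length(lines) + 1L)
    purrr::map(seq_along(headers), function(i) {
      list(name = sub("^>\\s*", "", lines[headers[i]]),
           rows = lines[(headers[i] + 1L):(bounds[i + 1L] - 1L)])
    })
  } else {
    list(list(name = sub("\\.[^.]*$", "", basename(path)), rows = lines))
  }
  out <- purrr::map(blocks, function(b) {
    if (length(b$rows) != 4) {
      abort(paste0(path, ": motif '", b$name, "' must have 4 count rows"))
    }
    rows <- purrr::map(b$rows, function(r) {
      r <- sub("^[ACGTacgt]\\s*\\[?", "", r)
      r <- sub("\\]\\s*$", "", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1) {
      abort(paste0(path, ": motif '", b$name, "' has ragged count rows"))
    }
    pwm_from_counts(do.call(rbind, rows), name = b$name,
                    pseudocount = pseudocount, background = background)
  })
  setNames(out, vapply(out, `[[`, character(1), "name"))
}

#' @rdname read_pwms
#' @export
load_pwm <- function(path, pseudocount = 0.01,
                     background = c(A = 0.25, C = 0.25,
                                    G = 0.25, T = 0.25)) {
  pwms <- read_pwms(path, pseudocount, background)
  if (length(pwms) > 1) inform("file holds several motifs; returning the first")
  pwms[[1]]
}

# Exact distribution of the lattice log-odds score of a random width-w word
# drawn from the PWM's background model, by per-position convolution over the
# integer lattice. Returns tibble(score, prob) over attainable scores.
score_distribution <- function(pwm) {
  L <- round(pwm$log_odds / PWM_LATTICE_RES)
  storage.mode(L) <- "integer"
  lo_cur <- 0L; hi_cur <- 0L
  cur_vec <- c(1)
  for (j in seq_len(pwm$width)) {
    new_lo <- lo_cur + min(L[, j])
    new_hi <- hi_cur + max(L[, j])
    nv <- numeric(new_hi - new_lo + 1L)
    for (b in seq_along(DNA_BASES)) {
      sh <- lo_cur + L[b, j] - new_lo
      idx <- seq_along(cur_vec) + sh
      nv[idx] <- nv[idx] + cur_vec * pwm$background[b]
    }
    cur_vec <- nv
    lo_cur <- new_lo; hi_cur <- new_hi
  }
  scores <- (lo_cur:hi_cur) * PWM_LATTICE_RES
  keep <- cur_vec > 0
  tibble(score = scores[keep], prob = cur_vec[keep])
}

#' Score cutoff for a PWM match p-value
#'
#' The smallest lattice score `s` such that a random width-w word drawn from
#' the PWM's background model scores `>= s` with probability at most `p`.
#' The null distribution is computed exactly by per-position convolution on
#' the 0.01-bit score lattice. When `p` is below the probability of even the
#' maximal score, the maximal score is returned with a warning.
#'
#' @param pwm A `pwm`.
#' @param p Match p-value threshold in (0, 1].
#' @return Numeric cutoff (bits) with attributes `attained_pvalue` (the
#'   exact tail probability at the cutoff) and `p_requested`.
#' @export
score_threshold <- function(pwm, p = 0.001) {
  if (!(p > 0 && p <= 1)) abort("`p` must be in (0, 1]")
  d <- score_distribution(pwm)
  tail_p <- rev(cumsum(rev(d$prob)))
  ok <- which(tail_p <= p + 1e-12)
  if (!length(ok)) {
    warn(sprintf(
      "p = %g is below the attainable resolution (min tail %.3g); using the maximal score",
      p, tail_p[length(tail_p)]))
    ok <- length(tail_p)
  }
  cutoff <- d$score[ok[1]]
  structure(cutoff, attained_pvalue = tail_p[ok[1]], p_requested = p)
}

# Integer codes 1..4 for A,C,G,T; NA for anything else (N).
seq_codes <- function(seq) {
  match(strsplit(as.character(seq), "")[[1]], DNA_BASES)
}

# Reverse-complement lattice matrix: scanning the forward sequence with it
# scores the minus-strand word at each window.
revcomp_matrix <- function(M) {
  M[rev(seq_len(4)), rev(seq_len(ncol(M))), drop = FALSE]
}

score_windows <- function(codes, M) {
  w <- ncol(M)
  n <- length(codes) - w + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(w)) {
    s <- s + unname(M[codes[j:(j + n - 1L)], j])
  }
  s
}

#' Scan sequences for PWM matches above a cutoff
#'
#' Every window (both strands by default) whose lattice log-odds score
#' reaches the cutoff is a match; overlapping matches are all retained;
#' windows containing `N` are skipped on both strands and excluded from the
#' count of windows scanned.
#'
#' @param seqs A [Biostrings::DNAStringSet] (e.g. peak sequences).
#' @param pwm A `pwm`.
#' @param cutoff Score cutoff in bits (see [score_threshold()]).
#' @param strands `"both"` (default) or `"forward"`.
#' @return Tibble of class `match_set` with columns `seq_name`, `position`
#'   (0-based window start on the forward strand), `strand`, `score`;
#'   attributes `cutoff` and `n_windows_scanned` (valid window-strand
#'   combinations, the denominator for match rates).
#' @export
scan_pwm <- function(seqs, pwm, cutoff, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  M <- pwm$log_odds
  Mrc <- revcomp_matrix(M)
  eps <- PWM_LATTICE_RES / 100
  res <- vector("list", length(seqs))
  n_windows <- 0
  nms <- names(seqs) %||% paste0("seq_", seq_along(seqs))
  for (i in seq_along(seqs)) {
    codes <- seq_codes(seqs[[i]])
    fwd <- score_windows(codes, M)
    valid <- !is.na(fwd)
    n_windows <- n_windows + sum(valid) * (if (strands == "both") 2L else 1L)
    hits_f <- which(valid & fwd >= cutoff - eps)
    pieces <- list(tibble(seq_name = nms[i], position = hits_f - 1L,
                          strand = "+", score = fwd[hits_f]))
    if (strands == "both") {
      rev_s <- score_windows(codes, Mrc)
      hits_r <- which(!is.na(rev_s) & rev_s >= cutoff - eps)
      pieces[[2]] <- tibble(seq_name = nms[i], position = hits_r - 1L,
                            strand = "-", score = rev_s[hits_r])
    }
    res[[i]] <- dplyr::bind_rows(pieces)
  }
  out <- dplyr::bind_rows(res)
  structure(out, class = c("match_set", class(tibble())),
            cutoff = as.numeric(cutoff), motif = pwm$name,
            strands = strands, n_windows_scanned = n_windows)
}

#' Per-peak PWM match density
#'
#' Density per peak is `(number of matches in the peak / peak length) x
#' 1000`, i.e. matches per kb.
#'
#' @param peaks The [peak_set()] the matches were scanned from (match
#'   `seq_name` must equal peak `name`).
#' @param matches A [scan_pwm()] result on [extract_peak_sequences()] output.
#' @return Tibble of class `density_result`: peak columns plus `n_matches`,
#'   `density`. [glance()] gives the set median.
#' @export
match_density <- function(peaks, matches) {
  counts <- table(matches$seq_name)
  n <- as.integer(counts[peaks$name])
  n[is.na(n)] <- 0L
  out <- dplyr::mutate(as_tibble(peaks), n_matches = n,
                       density = 1000 * n / (.data$end - .data$start))
  structure(out, class = c("density_result", class(tibble())),
            set_name = set_name(peaks), motif = attr(matches, "motif"))
}

#' @rdname match_density
#' @param x A `density_result`.
#' @param ... Unused.
#' @method glance density_result
#' @export
glance.density_result <- function(x, ...) {
  tibble(set = attr(x, "set_name"), motif = attr(x, "motif"),
         n_peaks = nrow(x), median_density = median(x$density))
}

#' Compare match densities between two peak sets
#'
#' Wilcoxon rank-sum test on the per-peak densities of two sets, with the
#' medians and their ratio.
#'
#' @param x,y [match_density()] results.
#' @return One-row tibble with medians, `median_ratio` and rank-sum
#'   `p_value`.
#' @export
compare_densities <- function(x, y) {
  w <- suppressWarnings(wilcox.test(x$density, y$density))
  tibble(set_x = attr(x, "set_name"), set_y = attr(y, "set_name"),
         median_x = median(x$density), median_y = median(y$density),
         median_ratio = median(x$density) / median(y$density),
         p_value = w$p.value)
}

#' Motif-set enrichment of peak sequences against a background
#'
#' For each motif, estimates the background match rate per scanned
#' window-strand at the cutoff implied by `p_match`, then tests the
#' foreground match count `m` over `L` scanned window-strands against
#' `Poisson(lambda * L)`: `p = P(X >= m)`, `score = log10(1/p)` capped at
#' `cap`. Motifs are ranked by score (ties by name). The Poisson count
#' model is a deliberately transparent group statistic: absolute scores are
#' not comparable to affinity-based methods, rankings are.
#'
#' @param fg_seqs Foreground sequences.
#' @param bg Background sequences.
#' @param pwms A `pwm` or list of `pwm`s.
#' @param p_match Per-window match p-value defining the cutoff
#'   (default 0.001).
#' @param cap Maximum reported score (default 50).
#' @return Tibble of class `motif_enrichment` with per-motif counts, rates,
#'   `p_value`, `score`, `rank`.
#' @export
motif_set_enrichment <- function(fg_seqs, bg, pwms, p_match = 0.001,
                                 cap = 50) {
  if (!length(fg_seqs) || !length(bg)) {
    abort("foreground and background must be non-empty")
  }
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (is.null(names(pwms))) {
    names(pwms) <- vapply(pwms, `[[`, character(1), "name")
  }
  rows <- purrr::imap(pwms, function(pwm, nm) {
    cutoff <- score_threshold(pwm, p_match)
    bg_scan <- scan_pwm(bg, pwm, cutoff)
    fg_scan <- scan_pwm(fg_seqs, pwm, cutoff)
    m_bg <- nrow(bg_scan); w_bg <- attr(bg_scan, "n_windows_scanned")
    m_fg <- nrow(fg_scan); w_fg <- attr(fg_scan, "n_windows_scanned")
    lambda <- if (w_bg > 0) m_bg / w_bg else 0
    if (lambda == 0 && m_fg > 0) {
      warn(sprintf("motif %s: no background matches but %d foreground; score capped",
                   nm, m_fg))
      p <- 10^(-cap)
    } else if (m_fg == 0) {
      p <- 1
    } else {
      p <- ppois(m_fg - 1, lambda * w_fg, lower.tail = FALSE)
    }
    tibble(motif = nm, cutoff = as.numeric(cutoff),
           n_fg = m_fg, windows_fg = w_fg,
           n_bg = m_bg, windows_bg = w_bg,
           lambda_bg = lambda, p_value = p,
           score = pmin(cap, log10(1 / pmax(p, 10^(-cap)))))
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(-out$score, out$motif), ]
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("motif_enrichment", class(tibble())),
            p_match = p_match, cap = cap)
}
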