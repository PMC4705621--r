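# Brute-force oracles and small randomized-instance generators. Every oracle
# is a direct transcription of the definition (all-pairs loops, per-base
# counting, exhaustive enumeration) and shares no code with the package
# internals it checks.

# -- generators --------------------------------------------------------------

random_peak_df <- function(n, chrom_lens, min_len = 20, max_len = 200) {
  cm <- sample(names(chrom_lens), n, replace = TRUE)
  len <- sample(min_len:max_len, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i) {
    sample.int(chrom_lens[[cm[i]]] - len[i], 1) - 1L
  }, integer(1))
  data.frame(chrom = cm, start = start, end = start + len,
             name = sprintf("p%04d", seq_len(n)))
}

random_track_df <- function(chrom_lens, n_steps = 30, max_val = 10) {
  do.call(rbind, lapply(names(chrom_lens), function(cm) {
    cuts <- sort(sample(0:chrom_lens[[cm]], n_steps * 2, replace = FALSE))
    starts <- cuts[seq(1, length(cuts), by = 2)]
    ends <- cuts[seq(2, length(cuts), by = 2)]
    keep <- ends > starts
    data.frame(chrom = cm, start = starts[keep], end = ends[keep],
               value = round(runif(sum(keep), 0, max_val), 3))
  }))
}

random_states_df <- function(chrom_lens, mean_seg = 500) {
  labels <- c("RED", "YELLOW", "BLUE", "BLACK", "GREEN")
  do.call(rbind, lapply(names(chrom_lens), function(cm) {
    rows <- list(); pos <- 0
    while (pos < chrom_lens[[cm]]) {
      seg <- min(chrom_lens[[cm]] - pos, 50 + rpois(1, mean_seg))
      if (runif(1) < 0.8) {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = cm, start = pos, end = pos + seg,
          state = sample(labels, 1))
      }
      pos <- pos + seg
    }
    do.call(rbind, rows)
  }))
}

random_genome <- function(chrom_lens, gc = 0.42, n_frac = 0) {
  p <- c(A = (1 - gc) / 2 * (1 - n_frac), C = gc / 2 * (1 - n_frac),
         G = gc / 2 * (1 - n_frac), T = (1 - gc) / 2 * (1 - n_frac),
         N = n_frac)
  seqs <- vapply(chrom_lens, function(len) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(seqs)
}

random_counts_matrix <- function(w) {
  matrix(sample(0:50, 4 * w, replace = TRUE), nrow = 4,
         dimnames = list(c("A", "C", "G", "T"), NULL))
}

# -- oracles -----------------------------------------------------------------

# All-pairs reciprocal-overlap qualification; returns logical matrix [i, j].
oracle_qualify_matrix <- function(a, b, f) {
  m <- matrix(FALSE, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- max(0, min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]))
      la <- a$end[i] - a$start[i]
      lb <- b$end[j] - b$start[j]
      m[i, j] <- ov >= max(1, ceiling(f * la)) && ov >= max(1, ceiling(f * lb))
    }
  }
  m
}

oracle_overlap_count <- function(a, b, f) {
  sum(apply(oracle_qualify_matrix(a, b, f), 1, any))
}

# Base-by-base state composition of a peak set.
oracle_state_prevalence <- function(peaks, states, chrom_lens) {
  labels <- c("RED", "YELLOW", "BLUE", "BLACK", "GREEN", "UNKNOWN")
  base_state <- lapply(chrom_lens, function(len) rep("UNKNOWN", len))
  for (i in seq_len(nrow(states))) {
    idx <- (states$start[i] + 1):states$end[i]
    base_state[[states$chrom[i]]][idx] <- states$state[i]
  }
  counts <- setNames(numeric(6), labels)
  for (i in seq_len(nrow(peaks))) {
    s <- base_state[[peaks$chrom[i]]][(peaks$start[i] + 1):peaks$end[i]]
    t <- table(s)
    counts[names(t)] <- counts[names(t)] + t
  }
  counts / sum(peaks$end - peaks$start)
}

# Per-base expansion of a step track.
oracle_base_values <- function(track, chrom_lens) {
  out <- lapply(chrom_lens, function(len) numeric(len))
  for (i in seq_len(nrow(track))) {
    out[[track$chrom[i]]][(track$start[i] + 1):track$end[i]] <- track$value[i]
  }
  out
}

oracle_window_means <- function(track, chrom_lens, w) {
  bases <- oracle_base_values(track, chrom_lens)
  unlist(lapply(names(chrom_lens), function(cm) {
    v <- bases[[cm]]
    n_win <- ceiling(length(v) / w)
    vapply(seq_len(n_win), function(k) {
      mean(v[((k - 1) * w + 1):min(k * w, length(v))])
    }, numeric(1))
  }), use.names = FALSE)
}

# Position-by-position sliding k-mer count (forward strand).
oracle_kmer_count <- function(seqs, kmer) {
  k <- nchar(kmer)
  sum(vapply(as.character(seqs), function(s) {
    if (nchar(s) < k) return(0L)
    sum(vapply(seq_len(nchar(s) - k + 1), function(i) {
      substr(s, i, i + k - 1) == kmer
    }, logical(1)))
  }, integer(1)))
}

# Per-window brute-force PWM scoring (forward strand) of one sequence.
oracle_scan_scores <- function(seq, M) {
  s <- strsplit(as.character(seq), "")[[1]]
  w <- ncol(M)
  if (length(s) < w) return(numeric(0))
  vapply(seq_len(length(s) - w + 1), function(i) {
    rows <- match(s[i:(i + w - 1)], rownames(M))
    if (anyNA(rows)) return(NA_real_)
    sum(M[cbind(rows, seq_len(w))])
  }, numeric(1))
}

# Exhaustive tail probability over all 4^w words under the background model.
oracle_tail_probability <- function(pwm, cutoff) {
  w <- pwm$width
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- numeric(nrow(grid))
  probs <- rep(1, nrow(grid))
  for (j in seq_len(w)) {
    scores <- scores + pwm$log_odds[cbind(grid[, j], j)]
    probs <- probs * pwm$background[grid[, j]]
  }
  sum(probs[scores >= cutoff - 1e-9])
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
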