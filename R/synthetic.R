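# Ground-truthed synthetic data: genome, TSS set, chromatin states,
# binding/accessibility tracks and peak sets with controlled overlap
# structure, planted motifs and controlled between-track correlation. Every
# planted quantity is recorded so each pipeline stage can be checked against
# its own ground truth.
#
# All randomness flows from a single seed; each generation stage draws from
# a sub-seed at a fixed offset, so adding a stage never perturbs the draws
# of earlier stages.

#' Define a synthetic-data scenario
#'
#' A scenario describes the genome, the chromatin-state annotation, the TSS
#' set, and one entry per factor ("factor" in the transcription-factor
#' sense) in `factors`. Each factor entry is a list with elements:
#'
#' * `n_peaks` — number of peaks.
#' * `derive` — optional list of `list(from =, fraction =, subset =)`
#'   entries: `round(fraction * n_peaks)` peaks are jittered copies of
#'   distinct peaks of the earlier factor `from` (guaranteeing reciprocal
#'   overlap at f = 0.05); `subset` restricts the source pool to
#'   `"derived"`, `"novel"` or `"all"` (default) peaks of `from`.
#' * `state_bias` — optional named probabilities: a novel peak is centred
#'   inside an interval of colour state `s` with probability
#'   `state_bias[s]`, otherwise placed uniformly.
#' * `avoid` — factor names the novel peaks must not touch (defaults to the
#'   `derive` sources).
#' * `motifs` — optional list of `list(word =, rate_per_kb =, subset =,
#'   placement =)` entries; occurrences of `word` are planted by
#'   substitution at Poisson(`rate_per_kb` x peak kb) copies per peak
#'   (`placement = "uniform"`) or as a single copy centred on the summit
#'   (`placement = "summit"`); `subset` is `"all"`, `"derived"` or
#'   `"novel"`.
#' * `amplitude` — mean kernel height of the factor's signal track.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param gc_content Genomic GC fraction (default 0.42, fly-like).
#' @param factors Named list of factor entries (see above); factors are
#'   generated in order, so `derive$from` must name an earlier factor.
#' @param peak_length `list(min, mode, max)` of a triangular length
#'   distribution in bp.
#' @param states `list(mean_segment_bp, coverage, weights)` for the
#'   renewal-process colour-state annotation (`coverage` = annotated
#'   fraction; `weights` = named probabilities over the five states).
#' @param n_tss Number of transcription start sites.
#' @param track_correlation Optional `list(rho, window, sdlog)`: also emit a
#'   pair of window-constant tracks (`corr_a`, `corr_b`) with lognormal
#'   margins whose population Pearson correlation equals `rho` exactly.
#' @param noise_floor Baseline track value outside peaks (default 0.01).
#' @param margin Peaks are kept `margin` bp away from chromosome ends so
#'   summit-centred windows always fit (default 2000).
#' @param seed Integer seed governing all randomness.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(chrom_lengths = c(chr2L = 6e5, chr2R = 6e5,
                                            chr3L = 6e5, chr3R = 6e5,
                                            chr4 = 2e5, chrX = 4e5),
                          gc_content = 0.42,
                          factors = list(),
                          peak_length = list(min = 200, mode = 400,
                                             max = 1000),
                          states = list(mean_segment_bp = 5000,
                                        coverage = 0.9,
                                        weights = c(RED = 0.15,
                                                    YELLOW = 0.25,
                                                    BLUE = 0.15,
                                                    BLACK = 0.35,
                                                    GREEN = 0.10)),
                          n_tss = 300,
                          track_correlation = NULL,
                          noise_floor = 0.01,
                          margin = 2000L,
                          seed = 1L) {
  if (is.null(names(chrom_lengths))) abort("chromosome lengths must be named")
  if (!(gc_content > 0 && gc_content < 1)) {
    abort("`gc_content` must be in (0, 1)")
  }
  total_req <- sum(vapply(factors, function(f) {
    f$n_peaks * peak_length$mode
  }, numeric(1)))
  if (total_req >= sum(chrom_lengths) / 2) {
    abort("requested peak bases exceed half the genome; enlarge the genome")
  }
  for (nm in names(factors)) {
    f <- factors[[nm]]
    if (!is.null(f$derive)) {
      fr <- vapply(f$derive, `[[`, numeric(1), "fraction")
      if (any(fr < 0 | fr > 1)) abort("derive fractions must be in [0, 1]")
      if (sum(fr) > 1 + 1e-9) {
        abort(sprintf("factor %s: derive fractions sum to more than 1", nm))
      }
      for (d in f$derive) {
        if (!d$from %in% head(names(factors), match(nm, names(factors)) - 1)) {
          abort(sprintf(
            "factor %s derives from '%s', which is not an earlier factor",
            nm, d$from))
        }
      }
    }
    if (!is.null(f$state_bias) && sum(f$state_bias) > 1 + 1e-9) {
      abort(sprintf("factor %s: state_bias probabilities sum to more than 1",
                    nm))
    }
  }
  structure(
    list(chrom_lengths = chrom_lengths, gc_content = gc_content,
         factors = factors, peak_length = peak_length, states = states,
         n_tss = as.integer(n_tss), track_correlation = track_correlation,
         noise_floor = noise_floor, margin = as.integer(margin),
         seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

# Triangular(min, mode, max) sampler by inverse CDF.
rtriangular <- function(n, min, mode, max) {
  u <- runif(n)
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

#' Expected k-mer frequency in random sequence
#'
#' Frequency per kb of a word in an i.i.d. nucleotide background with the
#' given GC content — the planting baseline used to express planted rates as
#' multiples of the background rate.
#'
#' @param word DNA word.
#' @param gc_content GC fraction of the background.
#' @return Expected occurrences per kb (forward strand).
#' @export
expected_kmer_rate <- function(word, gc_content = 0.42) {
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  1000 * prod(p[strsplit(toupper(word), "")[[1]]])
}

# --- generation stages -----------------------------------------------------

gen_genome <- function(spec) {
  set.seed(sub_seed(spec$seed, 1L))
  p <- c((1 - spec$gc_content) / 2, spec$gc_content / 2,
         spec$gc_content / 2, (1 - spec$gc_content) / 2)
  chars <- lapply(spec$chrom_lengths, function(len) {
    paste(sample(DNA_BASES, len, replace = TRUE, prob = p), collapse = "")
  })
  setNames(chars, names(spec$chrom_lengths))
}

gen_states <- function(spec) {
  set.seed(sub_seed(spec$seed, 2L))
  st <- spec$states
  rows <- list()
  for (cm in names(spec$chrom_lengths)) {
    len <- spec$chrom_lengths[[cm]]
    pos <- 0L
    while (pos < len) {
      seg <- min(len - pos, 200L + round(rexp(1, 1 / st$mean_segment_bp)))
      if (runif(1) < st$coverage) {
        lab <- sample(names(st$weights), 1, prob = st$weights)
        rows[[length(rows) + 1L]] <- tibble(chrom = cm, start = pos,
                                            end = pos + seg, state = lab)
      }
      pos <- pos + seg
    }
  }
  state_annotation(dplyr::bind_rows(rows))
}

gen_tss <- function(spec) {
  set.seed(sub_seed(spec$seed, 3L))
  lens <- spec$chrom_lengths
  cm <- sample(names(lens), spec$n_tss, replace = TRUE,
               prob = lens / sum(lens))
  pos <- vapply(cm, function(c) {
    as.integer(floor(runif(1, spec$margin, lens[[c]] - spec$margin)))
  }, integer(1))
  tibble(chrom = cm, pos = pos,
         strand = sample(c("+", "-"), spec$n_tss, replace = TRUE),
         name = sprintf("tss_%04d", seq_len(spec$n_tss)))
}

# Any 1 bp overlap between [s, e) and the intervals of `df` on `chrom`?
touches_any <- function(chrom, s, e, df) {
  idx <- df$chrom == chrom
  any(df$start[idx] < e & df$end[idx] > s)
}

place_factor <- function(fname, f, placed, spec, states) {
  lens <- spec$chrom_lengths
  margin <- spec$margin
  pl <- spec$peak_length
  rows <- list()
  derive <- f$derive %||% list()
  n_derived <- 0L
  for (d in derive) {
    src <- placed[[d$from]]
    pool <- src$peaks
    sub <- d$subset %||% "all"
    if (sub != "all") pool <- pool[src$origin == sub, , drop = FALSE]
    count <- round(d$fraction * f$n_peaks)
    if (count > nrow(pool)) {
      abort(sprintf(
        "factor %s: cannot derive %d peaks from %d available in '%s' (%s)",
        fname, count, nrow(pool), d$from, sub))
    }
    take <- pool[sample(nrow(pool), count), , drop = FALSE]
    len <- take$end - take$start
    shift <- round(runif(count, -0.25, 0.25) * len)
    start <- pmin(pmax(take$start + shift, margin),
                  lens[take$chrom] - margin - len)
    rows[[length(rows) + 1L]] <- tibble(
      chrom = take$chrom, start = as.integer(start),
      end = as.integer(start + len),
      origin = "derived", source = take$name
    )
    n_derived <- n_derived + count
  }
  n_novel <- f$n_peaks - n_derived
  avoid_names <- f$avoid %||%
    unique(vapply(derive, `[[`, character(1), "from"))
  avoid <- if (length(avoid_names)) {
    dplyr::bind_rows(lapply(placed[avoid_names], function(p)
      p$peaks[, c("chrom", "start", "end")]))
  } else {
    tibble(chrom = character(), start = integer(), end = integer())
  }
  bias <- f$state_bias
  state_pools <- if (!is.null(bias)) {
    lapply(names(bias), function(s) {
      iv <- states[states$state == s, ]
      iv[iv$end - iv$start > 2L, , drop = FALSE]
    }) |> setNames(names(bias))
  }
  novel <- tibble(chrom = character(), start = integer(), end = integer(),
                  origin = character(), source = character())
  if (n_novel > 0) {
    self <- dplyr::bind_rows(rows)
    out <- vector("list", n_novel)
    for (i in seq_len(n_novel)) {
      len <- as.integer(round(rtriangular(1, pl$min, pl$mode, pl$max)))
      for (try in 1:300) {
        target_state <- NULL
        if (!is.null(bias)) {
          u <- runif(1)
          cum <- cumsum(bias)
          k <- which(u < cum)
          if (length(k)) target_state <- names(bias)[k[1]]
        }
        if (!is.null(target_state) && nrow(state_pools[[target_state]])) {
          iv <- state_pools[[target_state]]
          j <- sample(nrow(iv), 1, prob = iv$end - iv$start)
          cm <- iv$chrom[j]
          ctr <- as.integer(floor(runif(1, iv$start[j], iv$end[j])))
        } else {
          cm <- sample(names(lens), 1, prob = lens / sum(lens))
          ctr <- as.integer(floor(runif(1, margin + len, lens[[cm]] -
                                          margin - len)))
        }
        s <- max(margin, ctr - len %/% 2L)
        e <- s + len
        if (e > lens[[cm]] - margin) next
        if (touches_any(cm, s, e, avoid)) next
        if (nrow(self) && touches_any(cm, s, e, self)) next
        out[[i]] <- tibble(chrom = cm, start = s, end = e,
                           origin = "novel", source = NA_character_)
        self <- dplyr::bind_rows(self, out[[i]])
        break
      }
      if (is.null(out[[i]])) {
        abort(sprintf(
          "factor %s: could not place peak %d without forbidden overlap; the genome is too crowded",
          fname, i))
      }
    }
    novel <- dplyr::bind_rows(out)
  }
  df <- dplyr::bind_rows(c(rows, list(novel)))
  df <- df[order(df$chrom, df$start), ]
  df$name <- sprintf("%s_%04d", fname, seq_len(nrow(df)))
  df$summit <- as.integer(floor((df$start + df$end) / 2))
  df$score <- NA_real_
  list(
    peaks = df[, c("chrom", "start", "end", "name", "score", "summit")],
    origin = df$origin, source = df$source
  )
}

plant_motifs <- function(genome_chars, placed, spec) {
  set.seed(sub_seed(spec$seed, 10L))
  plantings <- list()
  for (fname in names(spec$factors)) {
    f <- spec$factors[[fname]]
    for (m in f$motifs %||% list()) {
      word <- toupper(m$word)
      w <- nchar(word)
      sub <- m$subset %||% "all"
      pk <- placed[[fname]]$peaks
      if (sub != "all") pk <- pk[placed[[fname]]$origin == sub, ]
      placement <- m$placement %||% "uniform"
      for (i in seq_len(nrow(pk))) {
        len <- pk$end[i] - pk$start[i]
        pos <- if (placement == "summit") {
          pk$summit[i] - w %/% 2L
        } else {
          n_cop <- stats::rpois(1, m$rate_per_kb * len / 1000)
          if (n_cop == 0) next
          cand <- sort(sample(seq(pk$start[i], pk$end[i] - w),
                              min(n_cop, 50)))
          # keep copies at least w apart so they cannot overwrite each other
          keep <- !logical(length(cand))
          last <- -Inf
          for (k in seq_along(cand)) {
            if (cand[k] - last < w) keep[k] <- FALSE else last <- cand[k]
          }
          cand[keep]
        }
        cm <- pk$chrom[i]
        for (p in pos) {
          substring(genome_chars[[cm]], p + 1L, p + w) <- word
        }
        plantings[[length(plantings) + 1L]] <- tibble(
          set = fname, peak = pk$name[i], word = word,
          chrom = cm, position = as.integer(pos)
        )
      }
    }
  }
  pl <- if (length(plantings)) dplyr::bind_rows(plantings) else
    tibble(set = character(), peak = character(), word = character(),
           chrom = character(), position = integer())
  # peaks of different sets can share genome; a later plant may overwrite an
  # earlier one, so record whether each plant survives in the final sequence
  pl$intact <- vapply(seq_len(nrow(pl)), function(i) {
    substring(genome_chars[[pl$chrom[i]]], pl$position[i] + 1L,
              pl$position[i] + nchar(pl$word[i])) == pl$word[i]
  }, logical(1))
  list(genome = genome_chars, plantings = pl)
}

# Triangular-kernel pileup track at 10 bp resolution: height `amplitude`
# at the summit falling to 0 at the peak edges, over a constant noise floor.
gen_kernel_track <- function(peaks, amplitudes, spec, track_name) {
  res <- 10L
  rows <- list()
  for (cm in names(spec$chrom_lengths)) {
    len <- spec$chrom_lengths[[cm]]
    n_bin <- ceiling(len / res)
    v <- rep(spec$noise_floor, n_bin)
    idx <- which(peaks$chrom == cm)
    for (i in idx) {
      ctr <- peaks$summit[i]
      half <- (peaks$end[i] - peaks$start[i]) / 2
      b0 <- max(0L, peaks$start[i] %/% res)
      b1 <- min(n_bin - 1L, (peaks$end[i] - 1L) %/% res)
      mids <- (b0:b1) * res + res / 2
      v[(b0:b1) + 1L] <- v[(b0:b1) + 1L] +
        amplitudes[i] * pmax(0, 1 - abs(mids - ctr) / half)
    }
    v <- round(v, 6)
    r <- rle(v)
    ends <- pmin(cumsum(r$lengths) * res, len)
    starts <- c(0L, head(ends, -1L))
    rows[[length(rows) + 1L]] <- tibble(chrom = cm, start = as.integer(starts),
                                        end = as.integer(ends),
                                        value = r$values)
  }
  signal_track(dplyr::bind_rows(rows), track_name = track_name)
}

# Pair of window-constant tracks with lognormal margins whose population
# Pearson correlation equals rho exactly: for lognormal X = exp(s Z),
# cor(X1, X2) = (exp(rho_z s^2) - 1) / (exp(s^2) - 1), inverted for rho_z.
gen_correlated_tracks <- function(spec) {
  tc <- spec$track_correlation
  w <- as.integer(tc$window %||% 1000L)
  sdlog <- tc$sdlog %||% 0.5
  rho_z <- log(1 + tc$rho * (exp(sdlog^2) - 1)) / sdlog^2
  rows_a <- list(); rows_b <- list()
  for (cm in names(spec$chrom_lengths)) {
    len <- spec$chrom_lengths[[cm]]
    n_win <- ceiling(len / w)
    z1 <- rnorm(n_win)
    z2 <- rho_z * z1 + sqrt(1 - rho_z^2) * rnorm(n_win)
    starts <- (seq_len(n_win) - 1L) * w
    ends <- pmin(starts + w, len)
    rows_a[[length(rows_a) + 1L]] <- tibble(chrom = cm, start = starts,
                                            end = ends,
                                            value = exp(sdlog * z1))
    rows_b[[length(rows_b) + 1L]] <- tibble(chrom = cm, start = starts,
                                            end = ends,
                                            value = exp(sdlog * z2))
  }
  list(corr_a = signal_track(dplyr::bind_rows(rows_a), "corr_a"),
       corr_b = signal_track(dplyr::bind_rows(rows_b), "corr_b"))
}

#' Generate a fully ground-truthed scenario
#'
#' Deterministic given the scenario seed. Factor peak sets realize the
#' requested overlap structure by copying-and-jittering peaks of earlier
#' factors (jitter never exceeds a quarter of the peak length, so every
#' derived pair qualifies at the default 5 % reciprocal-overlap rule);
#' motifs are planted by substitution so all coordinates stay valid; signal
#' tracks sum a triangular kernel per peak over a low noise floor; colour
#' states are drawn as a renewal process; everything planted is recorded in
#' `$truth`.
#'
#' @param spec A [scenario_spec()].
#' @return List of class `scenario_bundle` with elements `genome`
#'   ([Biostrings::DNAStringSet]), `peaks` (named list of [peak_set()]),
#'   `tracks` (named list of [signal_track()]), `states`
#'   ([state_annotation()]), `tss` (tibble), `truth` (list: `provenance`,
#'   `plantings`, `overlap_targets`, `track_correlation`), and `spec`.
#' @export
generate_scenario <- function(spec) {
  if (!inherits(spec, "scenario_spec")) abort("`spec` must be a scenario_spec")
  genome_chars <- gen_genome(spec)
  states <- gen_states(spec)
  tss <- gen_tss(spec)

  placed <- list()
  off <- 4L
  for (fname in names(spec$factors)) {
    set.seed(sub_seed(spec$seed, off))
    placed[[fname]] <- place_factor(fname, spec$factors[[fname]], placed,
                                    spec, states)
    off <- off + 1L
  }

  pm <- plant_motifs(genome_chars, placed, spec)
  genome <- Biostrings::DNAStringSet(unlist(pm$genome))

  tracks <- list()
  set.seed(sub_seed(spec$seed, 20L))
  for (fname in names(spec$factors)) {
    f <- spec$factors[[fname]]
    pk <- placed[[fname]]$peaks
    amp <- (f$amplitude %||% 20) * runif(nrow(pk), 0.5, 1.5)
    tracks[[fname]] <- gen_kernel_track(pk, amp, spec, fname)
  }
  if (!is.null(spec$track_correlation)) {
    set.seed(sub_seed(spec$seed, 21L))
    tracks <- c(tracks, gen_correlated_tracks(spec))
  }

  peak_sets <- purrr::imap(placed, function(p, nm) {
    peak_set(p$peaks, set_name = nm, stringency = "synthetic",
             whitelist = names(spec$chrom_lengths))
  })

  provenance <- dplyr::bind_rows(purrr::imap(placed, function(p, nm) {
    tibble(set = nm, name = p$peaks$name, origin = p$origin,
           source = p$source)
  }))
  overlap_targets <- dplyr::bind_rows(purrr::imap(
    spec$factors, function(f, nm) {
      dplyr::bind_rows(lapply(f$derive %||% list(), function(d) {
        tibble(set = nm, from = d$from, subset = d$subset %||% "all",
               fraction = d$fraction)
      }))
    }))

  structure(
    list(genome = genome, peaks = peak_sets, tracks = tracks,
         states = states, tss = tss,
         truth = list(provenance = provenance,
                      plantings = pm$plantings,
                      overlap_targets = overlap_targets,
                      track_correlation = spec$track_correlation),
         spec = spec),
    class = "scenario_bundle"
  )
}

#' Scenario emulating the observed Hox ChIP-Seq design
#'
#' One call builds the full fixture bundle used by the end-to-end pipeline:
#' a "Ubx"-like and an "AbdA"-like peak set at 90 % mutual overlap; an
#' "AbdB"-like set sharing roughly half its peaks with AbdA while its
#' specific peaks sit preferentially in the repressive BLUE/BLACK colour
#' states, carry Hox-core TTTAT words and motif-consensus matches at
#' elevated density, and have AT-rich (narrow-minor-groove) summit cores; a
#' "DNase"-like accessibility set covering most shared peaks but few
#' AbdB-specific ones; per-factor pileup tracks; and a track pair with
#' planted Pearson correlation 0.6.
#'
#' @param seed Integer seed.
#' @return A `scenario_bundle` (see [generate_scenario()]).
#' @export
emulate_study_design <- function(seed = 1L) {
  motif_word <- pwm_consensus(hox_like_pwm())
  tttat_bg <- expected_kmer_rate("TTTAT", 0.42)
  spec <- scenario_spec(
    chrom_lengths = c(chr2L = 7e5, chr2R = 7e5, chr3L = 7e5, chr3R = 7e5,
                      chr4 = 2e5, chrX = 5e5),
    factors = list(
      Ubx = list(n_peaks = 700, amplitude = 25,
                 state_bias = c(RED = 0.35, YELLOW = 0.45)),
      AbdA = list(n_peaks = 700, amplitude = 25,
                  derive = list(list(from = "Ubx", fraction = 0.90)),
                  state_bias = c(RED = 0.35, YELLOW = 0.45)),
      AbdB = list(n_peaks = 800, amplitude = 25,
                  derive = list(list(from = "AbdA", fraction = 0.53)),
                  state_bias = c(BLUE = 0.40, BLACK = 0.40),
                  motifs = list(
                    list(word = "TTTAT", rate_per_kb = 3 * tttat_bg,
                         subset = "all"),
                    list(word = motif_word, rate_per_kb = 6,
                         subset = "novel"),
                    list(word = motif_word, rate_per_kb = 2,
                         subset = "derived"),
                    list(word = strrep("TA", 15), subset = "novel",
                         placement = "summit")
                  )),
      DNase = list(n_peaks = 1100, amplitude = 15,
                   derive = list(list(from = "Ubx", fraction = 0.55),
                                 list(from = "AbdB", fraction = 0.12,
                                      subset = "novel")),
                   avoid = character(0))
    ),
    track_correlation = list(rho = 0.6, window = 1000L, sdlog = 0.5),
    seed = seed
  )
  generate_scenario(spec)
}

#' Synthetic Hox-like PWM
#'
#' An 8-position count matrix with the AT-rich consensus TTTATGGC typical of
#' posterior Hox homeodomain preferences. Entirely synthetic — bundled so
#' examples and tests run without motif-database downloads; real analyses
#' should load JASPAR matrices via [read_pwms()].
#'
#' @param pseudocount,background Passed to [pwm_from_counts()].
#' @return A `pwm`.
#' @export
hox_like_pwm <- function(pseudocount = 0.01,
                         background = c(A = 0.25, C = 0.25,
                                        G = 0.25, T = 0.25)) {
  load_pwm(system.file("extdata", "synthetic_hox_like.pfm",
                       package = "hoxspec", mustWork = TRUE),
           pseudocount = pseudocount, background = background)
}

#' Write a scenario bundle to standard-format files
#'
#' Emits `genome.fa`, one narrowPeak per peak set, one bedGraph per track,
#' `states.bed`, `tss.bed` and `truth.json`, so synthetic fixtures are
#' indistinguishable from real inputs. Re-running with the same bundle
#' produces byte-identical files.
#'
#' @param bundle A `scenario_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$genome, file.path(dir, "genome.fa"))
  for (nm in names(bundle$peaks)) {
    write_bed(bundle$peaks[[nm]], file.path(dir, paste0(nm, ".narrowPeak")))
  }
  for (nm in names(bundle$tracks)) {
    write_bedgraph(bundle$tracks[[nm]], file.path(dir, paste0(nm, ".bdg")))
  }
  write_states(bundle$states, file.path(dir, "states.bed"))
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", bundle$tss$chrom,
                     bundle$tss$pos, bundle$tss$pos + 1L, bundle$tss$name,
                     bundle$tss$strand),
             file.path(dir, "tss.bed"))
  jsonlite::write_json(
    list(provenance = bundle$truth$provenance,
         plantings = bundle$truth$plantings,
         overlap_targets = bundle$truth$overlap_targets),
    file.path(dir, "truth.json"),
    dataframe = "columns", digits = NA, pretty = TRUE
  )
  invisible(dir)
}
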