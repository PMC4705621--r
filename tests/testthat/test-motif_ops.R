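# PWM construction, exact score thresholds, scanning, match density and
# motif-set enrichment.

uniform_pwm <- function(w = 6) {
  pwm_from_counts(matrix(10, 4, w), name = "uniform")
}

test_that("PWM probabilities and log-odds follow the pseudocount rule", {
  p <- uniform_pwm()
  expect_true(all(abs(p$log_odds) < 1e-9))
  expect_equal(colSums(p$prob), rep(1, 6), tolerance = 1e-9)

  set.seed(79)
  for (rep in 1:5) {
    counts <- random_counts_matrix(sample(4:10, 1))
    p <- pwm_from_counts(counts, pseudocount = 0.5)
    expect_equal(unname(colSums(p$prob)), rep(1, ncol(counts)),
                 tolerance = 1e-9)
  }

  # a zero count with no pseudocount would give log(0)
  counts <- matrix(c(10, 0, 0, 0), 4, 4)
  expect_error(pwm_from_counts(counts, pseudocount = 0), "pseudocount")
  expect_error(pwm_from_counts(matrix(1, 3, 4)), "4 rows")
  expect_error(pwm_from_counts(matrix(1, 4, 3)), "width")
})

test_that("JASPAR-style matrix files parse in bracket and plain layouts", {
  f <- tempfile(fileext = ".pfm")
  writeLines(c(">M1 toy",
               "A [ 10  0  0 5 ]",
               "C [  0 10 0 5 ]",
               "G [  0  0 10 0 ]",
               "T [  0  0 0 0 ]"), f)
  p <- load_pwm(f)
  expect_equal(p$width, 4L)
  expect_equal(pwm_consensus(p), "ACGA")

  writeLines(c("10 0 0 5", "0 10 0 5", "0 0 10 0", "0 0 0 0"), f)
  expect_equal(pwm_consensus(load_pwm(f)), "ACGA")

  writeLines(c(">M1", "1 2", "1 2", "1 2 3", "1 2"), f)
  expect_error(read_pwms(f), "ragged")

  bundled <- hox_like_pwm()
  expect_equal(pwm_consensus(bundled), "TTTATGGC")
})

test_that("p = 1 yields the minimum attainable score as cutoff", {
  set.seed(83)
  p <- pwm_from_counts(random_counts_matrix(5), pseudocount = 1)
  cutoff <- score_threshold(p, 1)
  expect_equal(as.numeric(cutoff), sum(apply(p$log_odds, 2, min)),
               tolerance = 1e-9)
  expect_equal(attr(cutoff, "attained_pvalue"), 1, tolerance = 1e-12)
})

test_that("threshold tail probabilities equal exhaustive enumeration", {
  set.seed(89)
  for (w in c(4, 6, 8)) {
    counts <- random_counts_matrix(w)
    bgs <- list(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                c(A = 0.29, C = 0.21, G = 0.21, T = 0.29))
    for (bg in bgs) {
      p <- pwm_from_counts(counts, pseudocount = 1, background = bg)
      max_score <- sum(apply(p$log_odds, 2, max))
      for (pv in c(0.25, 0.01, 0.001)) {
        warned <- FALSE
        cutoff <- withCallingHandlers(
          score_threshold(p, pv),
          warning = function(w) {
            warned <<- TRUE
            invokeRestart("muffleWarning")
          })
        exact <- oracle_tail_probability(p, as.numeric(cutoff))
        expect_equal(attr(cutoff, "attained_pvalue"), exact,
                     tolerance = 1e-9)
        if (warned) {
          # pv below the attainable resolution: the maximal score is used
          expect_equal(as.numeric(cutoff), max_score, tolerance = 1e-9)
          expect_gt(exact, pv)
        } else {
          expect_lte(exact, pv + 1e-12)
          # one lattice step lower would exceed the requested p
          lower <- oracle_tail_probability(p, as.numeric(cutoff) - 0.011)
          if (abs(lower - exact) > 1e-12) expect_gt(lower, pv)
        }
      }
    }
  }
})

test_that("a p-value below the attainable resolution warns and caps", {
  p <- pwm_from_counts(matrix(c(97, 1, 1, 1), 4, 6), pseudocount = 1)
  expect_warning(cutoff <- score_threshold(p, 1e-12), "resolution")
  expect_equal(as.numeric(cutoff), sum(apply(p$log_odds, 2, max)),
               tolerance = 1e-9)
})

test_that("scanning finds the consensus and skips N windows", {
  p <- hox_like_pwm()
  cutoff <- score_threshold(p, 0.001)
  hits <- scan_pwm(Biostrings::DNAStringSet(c(s = "TTTATGGC")), p, cutoff)
  expect_equal(hits$position, 0L)
  expect_equal(hits$strand, "+")

  # the reverse complement matches on the minus strand at the same window
  hits <- scan_pwm(Biostrings::DNAStringSet(c(s = "GCCATAAA")), p, cutoff)
  expect_equal(hits$strand, "-")
  expect_equal(hits$position, 0L)

  hits <- scan_pwm(Biostrings::DNAStringSet(c(s = strrep("N", 50))), p,
                   cutoff)
  expect_equal(nrow(hits), 0L)
  expect_equal(attr(hits, "n_windows_scanned"), 0)
})

test_that("scan results equal brute-force window scoring", {
  set.seed(97)
  p <- pwm_from_counts(random_counts_matrix(6), pseudocount = 1)
  cutoff <- score_threshold(p, 0.01)
  seqs <- random_genome(c(s1 = 10000L), n_frac = 0.01)
  hits <- scan_pwm(seqs, p, cutoff, strands = "forward")
  oracle <- oracle_scan_scores(seqs[[1]], p$log_odds)
  expect_equal(hits$position, which(!is.na(oracle) &
                                      oracle >= cutoff - 1e-9) - 1L)
  expect_equal(hits$score, oracle[hits$position + 1L], tolerance = 1e-9)
  expect_equal(attr(hits, "n_windows_scanned"), sum(!is.na(oracle)))
})

test_that("scanning a reverse-complemented sequence swaps strands", {
  set.seed(101)
  p <- pwm_from_counts(random_counts_matrix(5), pseudocount = 1)
  cutoff <- score_threshold(p, 0.05)
  s <- random_genome(c(x = 2000L))
  fwd <- scan_pwm(s, p, cutoff)
  rc <- scan_pwm(Biostrings::reverseComplement(s), p, cutoff)
  L <- 2000L; w <- 5L
  mirrored <- sort(L - w - rc$position[rc$strand == "-"])
  expect_equal(sort(fwd$position[fwd$strand == "+"]), mirrored)
  expect_equal(nrow(fwd), nrow(rc))
})

test_that("match density applies the per-kb formula and split invariance", {
  peaks <- peak_set(data.frame(chrom = "c", start = 0, end = 1000,
                               name = "p1"), whitelist = NULL)
  matches <- structure(
    tibble::tibble(seq_name = rep("p1", 5), position = c(1, 5, 9, 40, 700),
                   strand = "+", score = 1),
    class = c("match_set", class(tibble::tibble())), motif = "m")
  d <- match_density(peaks, matches)
  expect_equal(d$density, 5)
  expect_equal(glance(d)$median_density, 5)

  d0 <- match_density(peaks, matches[0, ])
  expect_equal(d0$density, 0)
  expect_equal(glance(d0)$median_density, 0)

  # splitting a peak into adjacent halves keeps the aggregate count
  halves <- peak_set(data.frame(chrom = "c", start = c(0, 500),
                                end = c(500, 1000),
                                name = c("p1a", "p1b")), whitelist = NULL)
  m2 <- matches
  m2$seq_name <- ifelse(matches$position < 500, "p1a", "p1b")
  d2 <- match_density(halves, m2)
  expect_equal(sum(d2$n_matches), sum(d$n_matches))
})

test_that("a planted two-fold density difference is detected", {
  p <- hox_like_pwm()
  word <- pwm_consensus(p)
  spec <- scenario_spec(
    chrom_lengths = c(chrA = 1.5e6L, chrB = 1.5e6L),
    factors = list(
      dense = list(n_peaks = 200,
                   motifs = list(list(word = word, rate_per_kb = 12))),
      sparse = list(n_peaks = 200,
                    motifs = list(list(word = word, rate_per_kb = 6)))
    ),
    peak_length = list(min = 300, mode = 500, max = 800),
    n_tss = 50, seed = 103
  )
  bundle <- generate_scenario(spec)
  cutoff <- score_threshold(p, 1e-4)
  dens <- lapply(bundle$peaks, function(pk) {
    match_density(pk, scan_pwm(extract_peak_sequences(pk, bundle$genome),
                               p, cutoff))
  })
  cmp <- compare_densities(dens$dense, dens$sparse)
  expect_equal(cmp$median_ratio, 2, tolerance = 0.3)
  expect_lt(cmp$p_value, 0.01)
})

test_that("motif-set enrichment ranks a planted motif first", {
  set.seed(107)
  pwms <- c(list(planted = hox_like_pwm()),
            lapply(setNames(1:19, paste0("decoy", 1:19)), function(i) {
              pwm_from_counts(random_counts_matrix(8), pseudocount = 1,
                              name = paste0("decoy", i))
            }))
  spec <- scenario_spec(
    chrom_lengths = c(chrA = 8e5L),
    factors = list(fg = list(n_peaks = 150,
                             motifs = list(list(word = "TTTATGGC",
                                                rate_per_kb = 5)))),
    n_tss = 100, seed = 109
  )
  bundle <- generate_scenario(spec)
  fg <- extract_peak_sequences(bundle$peaks$fg, bundle$genome)
  bg <- build_tss_background(bundle$tss, bundle$genome)
  enr <- motif_set_enrichment(fg, bg, pwms, p_match = 0.001)
  expect_equal(enr$motif[enr$rank == 1], "planted")
})

test_that("enrichment score is zero when the motif is absent everywhere", {
  p <- hox_like_pwm()
  fg <- Biostrings::DNAStringSet(strrep("CG", 500))
  bg <- Biostrings::DNAStringSet(strrep("CG", 2000))
  enr <- motif_set_enrichment(fg, bg, list(hox = p), p_match = 0.001)
  expect_equal(enr$n_fg, 0L)
  expect_equal(enr$p_value, 1)
  expect_equal(enr$score, 0)
})

test_that("adding planted matches never lowers an enrichment score", {
  set.seed(113)
  p <- hox_like_pwm()
  bg <- random_genome(c(bg = 50000L))
  fg <- random_genome(c(a = 2000L, b = 2000L, c = 2000L))
  s0 <- motif_set_enrichment(fg, bg, list(hox = p))$score
  fg_plus <- Biostrings::DNAStringSet(c(
    as.character(fg),
    extra = paste(rep(paste0("TTTATGGC", strrep("C", 42)), 20),
                  collapse = "")
  ))
  s1 <- motif_set_enrichment(fg_plus, bg, list(hox = p))$score
  expect_gte(s1, s0)
})
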