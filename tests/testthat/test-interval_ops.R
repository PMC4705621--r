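# Reciprocal-overlap algebra, partitions, per-focal-set Venn counts, and
# chromatin-state prevalence, each checked against brute-force oracles.

toy_set <- function(df, name = "toy") {
  peak_set(df, set_name = name, whitelist = NULL)
}

test_that("the reciprocal rule requires the fraction of BOTH peaks", {
  a <- toy_set(data.frame(chrom = "c", start = 100, end = 200), "a")
  b <- toy_set(data.frame(chrom = "c", start = 195, end = 400), "b")
  # ov = 5 covers 5% of a (100 bp) but not 5% of b (205 bp)
  ov <- reciprocal_overlap(a, b, 0.05)
  expect_equal(ov$n_a_overlapping, 0L)
  expect_equal(ov$pct_a, 0)
  # at f small enough that 5 bases satisfy both, the pair qualifies
  ov <- reciprocal_overlap(a, b, 0.02)
  expect_equal(ov$n_a_overlapping, 1L)
})

test_that("identical peak sets overlap 100% at any fraction", {
  set.seed(7)
  df <- random_peak_df(40, c(chrA = 1e5L))
  a <- toy_set(df, "a")
  for (f in c(0.05, 0.5, 1)) {
    ov <- reciprocal_overlap(a, a, f)
    expect_equal(ov$pct_a, 100)
    expect_equal(ov$pct_b, 100)
  }
})

test_that("empty sets give zero counts and NA percentages", {
  a <- toy_set(data.frame(chrom = "c", start = 1, end = 10)[0, ], "a")
  b <- toy_set(data.frame(chrom = "c", start = 1, end = 10), "b")
  ov <- reciprocal_overlap(a, b)
  expect_equal(ov$n_a_overlapping, 0L)
  expect_true(is.na(ov$pct_a))
  expect_false(is.na(ov$pct_b))
})

test_that("overlap counts match the all-pairs oracle on random instances", {
  set.seed(11)
  lens <- c(chrA = 5e5L, chrB = 5e5L)
  for (rep in 1:4) {
    a <- toy_set(random_peak_df(200, lens, 50, 2000), "a")
    b <- toy_set(random_peak_df(200, lens, 50, 2000), "b")
    for (f in c(0.05, 0.3)) {
      ov <- suppressWarnings(reciprocal_overlap(a, b, f))
      expect_equal(ov$n_a_overlapping, oracle_overlap_count(a, b, f))
      expect_equal(ov$n_b_overlapping, oracle_overlap_count(b, a, f))
      expect_equal(ov$n_a_overlapping + nrow(ov$specific_a), nrow(a))
    }
  }
})

test_that("pair qualification is symmetric and pct is non-increasing in f", {
  set.seed(13)
  lens <- c(chrA = 2e5L)
  a <- toy_set(random_peak_df(80, lens, 50, 1500), "a")
  b <- toy_set(random_peak_df(80, lens, 50, 1500), "b")
  m_ab <- oracle_qualify_matrix(a, b, 0.05)
  m_ba <- oracle_qualify_matrix(b, a, 0.05)
  expect_identical(m_ab, t(m_ba))
  pcts <- vapply(c(0.02, 0.05, 0.2, 0.5, 1),
                 function(f) suppressWarnings(
                   reciprocal_overlap(a, b, f))$pct_a, numeric(1))
  expect_true(all(diff(pcts) <= 1e-9))
})

test_that("partition_by_reference splits exactly and matches the oracle", {
  set.seed(17)
  lens <- c(chrA = 3e5L)
  a <- toy_set(random_peak_df(150, lens, 50, 1000), "a")
  expect_equal(nrow(partition_by_reference(a, a)$specific), 0L)
  far <- toy_set(data.frame(chrom = "chrB", start = 0, end = 100), "far")
  expect_equal(nrow(partition_by_reference(a, far)$common), 0L)

  ref <- toy_set(random_peak_df(150, lens, 50, 1000), "ref")
  parts <- suppressWarnings(partition_by_reference(a, ref, 0.05))
  expect_equal(nrow(parts$common), oracle_overlap_count(a, ref, 0.05))
  expect_equal(nrow(parts$common) + nrow(parts$specific), nrow(a))
  joined <- dplyr::arrange(rbind(tibble::as_tibble(parts$common),
                                 tibble::as_tibble(parts$specific)),
                           chrom, start)
  expect_equal(joined$start, a$start)
})

test_that("venn counts classify per focal set and agree with the oracle", {
  a <- toy_set(data.frame(chrom = "c", start = c(0, 1000), end = c(100, 1100)),
               "a")
  b <- toy_set(data.frame(chrom = "c", start = 5000, end = 5100), "b")
  v <- venn_counts(list(a = a, b = b))
  expect_true(all(v$pattern == "none"))

  v <- venn_counts(list(a = a, b = a))
  expect_setequal(v$pattern, c("b", "a"))
  expect_true(all(v$pct == 100))

  set.seed(19)
  lens <- c(chrA = 2e5L)
  sets <- list(x = toy_set(random_peak_df(60, lens, 50, 800), "x"),
               y = toy_set(random_peak_df(60, lens, 50, 800), "y"),
               z = toy_set(random_peak_df(60, lens, 50, 800), "z"))
  v <- venn_counts(sets, 0.05)
  for (focal in names(sets)) {
    others <- setdiff(names(sets), focal)
    qm <- sapply(others, function(o)
      apply(oracle_qualify_matrix(sets[[focal]], sets[[o]], 0.05), 1, any))
    pat <- apply(qm, 1, function(r)
      if (!any(r)) "none" else paste(others[r], collapse = ","))
    expected <- table(pat)
    got <- v[v$focal_set == focal, ]
    expect_equal(setNames(got$n_peaks, got$pattern),
                 setNames(as.integer(expected), names(expected)))
  }
  expect_error(venn_counts(sets[1]), "2 or 3")
})

test_that("a stringent subset lies entirely within its relaxed superset", {
  set.seed(23)
  relaxed <- toy_set(random_peak_df(100, c(chrA = 2e5L), 100, 500), "rel")
  stringent <- toy_set(tibble::as_tibble(relaxed)[sample(100, 30), ], "str")
  expect_equal(stringent_vs_relaxed(stringent, relaxed)$pct, 100)
})

test_that("state prevalence fractions are exact and sum to one", {
  states <- state_annotation(data.frame(chrom = "c", start = 0, end = 1000,
                                        state = "RED"))
  p <- toy_set(data.frame(chrom = "c", start = 0, end = 100))
  sp <- state_prevalence(p, states)
  expect_equal(sp$fraction[sp$state == "RED"], 1)

  states <- state_annotation(data.frame(chrom = "c", start = 0, end = 50,
                                        state = "RED"))
  sp <- state_prevalence(p, states)
  expect_equal(sp$fraction[sp$state == "RED"], 0.5)
  expect_equal(sp$fraction[sp$state == "UNKNOWN"], 0.5)
  expect_equal(sum(sp$fraction), 1, tolerance = 1e-12)

  expect_error(state_prevalence(p[0, ], states), "non-zero")
})

test_that("state prevalence matches per-base counting on random annotations", {
  set.seed(29)
  lens <- c(chrA = 5e4L, chrB = 5e4L)
  for (rep in 1:3) {
    peaks <- toy_set(random_peak_df(50, lens, 20, 500))
    states <- state_annotation(random_states_df(lens))
    sp <- state_prevalence(peaks, states)
    oracle <- oracle_state_prevalence(peaks, states, lens)
    expect_equal(setNames(sp$fraction, as.character(sp$state)),
                 oracle, tolerance = 1e-12)
    expect_equal(sum(sp$fraction), 1, tolerance = 1e-9)
  }
})

test_that("whole-genome prevalence equals the annotation's composition", {
  set.seed(31)
  lens <- c(chrA = 4e4L, chrB = 3e4L)
  states <- state_annotation(random_states_df(lens))
  comp <- genome_state_composition(states, lens)
  by_state <- tapply(states$end - states$start, states$state, sum)
  for (s in names(by_state)) {
    expect_equal(comp$bases[comp$state == s], unname(by_state[s]))
  }
  expect_equal(sum(comp$bases), sum(lens))
})

test_that("state labels outside the five colours are rejected", {
  expect_error(
    state_annotation(data.frame(chrom = "c", start = 0, end = 10,
                                state = "PURPLE")),
    "unknown chromatin state")
})
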