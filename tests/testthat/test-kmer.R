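# Sequence extraction, TSS backgrounds, k-mer counting and fingerprint
# enrichment.

toy_set <- function(df, name = "toy") {
  peak_set(df, set_name = name, whitelist = NULL)
}

test_that("peak sequences are sliced 0-based half-open with Ns retained", {
  g <- Biostrings::DNAStringSet(c(c1 = "AACGTT", c2 = "ANNNAT"))
  peaks <- toy_set(data.frame(chrom = c("c1", "c2"), start = c(2, 0),
                              end = c(6, 5), name = c("x", "y")))
  seqs <- extract_peak_sequences(peaks, g)
  expect_equal(as.character(seqs[["x"]]), "CGTT")
  expect_equal(as.character(seqs[["y"]]), "ANNNA")

  bad <- toy_set(data.frame(chrom = "c1", start = 2, end = 10,
                            name = "over"))
  expect_error(extract_peak_sequences(bad, g), "over")
})

test_that("extracted sequence lengths equal peak lengths", {
  set.seed(59)
  lens <- c(chrA = 2e4L, chrB = 1e4L)
  g <- random_genome(lens)
  peaks <- toy_set(random_peak_df(50, lens, 10, 300))
  seqs <- extract_peak_sequences(peaks, g)
  expect_equal(unname(Biostrings::width(seqs)), peaks$end - peaks$start)
})

test_that("TSS background windows follow the strand-aware upstream rule", {
  g <- Biostrings::DNAStringSet(c(chrA = paste(rep("ACGT", 1500),
                                               collapse = "")))
  tss <- tibble::tibble(chrom = "chrA", pos = 2000L, strand = "+",
                        name = "t1")
  bg <- build_tss_background(tss, g, span = 2000)
  expect_equal(as.character(bg[[1]]),
               as.character(Biostrings::subseq(g[[1]], 1, 2000)))

  tss <- tibble::tibble(chrom = "chrA", pos = 1000L, strand = "-",
                        name = "t2")
  bg <- build_tss_background(tss, g, span = 2000)
  expect_equal(as.character(bg[[1]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::subseq(g[[1]], 1001, 3000))))

  # edge TSS dropped with a warning; none left is an error
  tss <- tibble::tibble(chrom = "chrA", pos = c(0L, 2000L),
                        strand = c("+", "+"), name = c("e", "ok"))
  expect_warning(bg <- build_tss_background(tss, g, span = 2000), "dropped")
  expect_length(bg, 1)
  expect_error(
    suppressWarnings(build_tss_background(tss[1, ], g, span = 2000)),
    "no TSS")
})

test_that("background length is span times the number of valid TSS", {
  set.seed(61)
  lens <- c(chrA = 5e4L)
  g <- random_genome(lens)
  tss <- tibble::tibble(chrom = "chrA",
                        pos = sample(2000:48000, 25),
                        strand = sample(c("+", "-"), 25, replace = TRUE),
                        name = paste0("t", 1:25))
  bg <- build_tss_background(tss, g, span = 2000)
  expect_equal(sum(Biostrings::width(bg)), 2000L * 25L)
})

test_that("k-mer counting is overlapping, N-blocking and strand-aware", {
  expect_equal(count_kmer("AAAA", "AA"), 3L)
  expect_equal(count_kmer("AANAA", "AA"), 2L)
  expect_equal(count_kmer("ATAAA", "TTTAT"), 0L)
  expect_equal(count_kmer("ATAAA", "TTTAT", strands = "both"), 1L)
  # palindromic word counted once per position in both-strand mode
  expect_equal(count_kmer("AATT", "AATT", strands = "both"), 1L)
  expect_error(count_kmer("ACGT", "AXGT"), "A,C,G,T")
})

test_that("k-mer counts match the sliding-window oracle", {
  set.seed(67)
  g <- random_genome(c(a = 3000L, b = 2000L), n_frac = 0.02)
  for (kmer in c("TTTAT", "TGATTTAT", "AA")) {
    expect_equal(count_kmer(g, kmer), oracle_kmer_count(g, kmer))
    expect_equal(count_kmer(g, kmer, strands = "both"),
                 oracle_kmer_count(g, kmer) +
                   oracle_kmer_count(g, revcomp(kmer)))
  }
})

test_that("counting is additive over sequences and scale-invariant per kb", {
  set.seed(71)
  seqs <- random_genome(c(a = 1000L, b = 800L, c = 1200L))
  total <- count_kmer(seqs, "TTAAT")
  per_seq <- vapply(seq_along(seqs), function(i)
    count_kmer(seqs[i], "TTAAT"), integer(1))
  expect_equal(total, sum(per_seq))

  bg <- random_genome(c(bg = 5000L), gc = 0.42)
  fp1 <- fingerprint(seqs, bg, hox_monomer_panel())
  fp2 <- fingerprint(c(seqs, seqs), bg, hox_monomer_panel())
  expect_equal(fp1$enrichment, fp2$enrichment, tolerance = 1e-12)
})

test_that("fingerprint is zero when foreground equals background", {
  set.seed(73)
  seqs <- random_genome(c(a = 20000L))
  fp <- fingerprint(seqs, seqs, hox_monomer_panel())
  expect_true(all(fp$defined))
  expect_equal(fp$enrichment, rep(0, 4))
})

test_that("fingerprint reproduces an exact constructed ratio", {
  # foreground: exactly 10 TTTAT in 5 kb; background: exactly 1 per kb
  pad <- function(n) strrep("C", n)
  fg <- Biostrings::DNAStringSet(
    paste0(paste(rep(paste0("TTTAT", pad(495)), 10), collapse = ""))
  )
  expect_equal(sum(Biostrings::width(fg)), 5000L)
  bg <- Biostrings::DNAStringSet(
    paste(rep(paste0("TTTAT", pad(995)), 8), collapse = "")
  )
  fp <- fingerprint(fg, bg, kmer_panel("TTTAT"))
  expect_equal(fp$fg_per_kb, 2)
  expect_equal(fp$bg_per_kb, 1)
  expect_equal(fp$enrichment, 1)
})

test_that("zero background count flags the enrichment as undefined", {
  fg <- Biostrings::DNAStringSet("TTTATTTTAT")
  bg <- Biostrings::DNAStringSet(strrep("C", 1000))
  fp <- fingerprint(fg, bg, kmer_panel("TTTAT"))
  expect_false(fp$defined)
  expect_true(is.na(fp$enrichment))
})

test_that("a word planted at four times background is recovered at log2 4", {
  rate3x <- 3 * expected_kmer_rate("TTTAT", 0.42)
  spec <- scenario_spec(
    chrom_lengths = c(chrA = 1.2e6L, chrB = 1.2e6L),
    factors = list(
      fg = list(n_peaks = 450,
                motifs = list(list(word = "TTTAT",
                                   rate_per_kb = rate3x)))
    ),
    peak_length = list(min = 400, mode = 500, max = 700),
    n_tss = 250, seed = 77
  )
  bundle <- generate_scenario(spec)
  fg_seqs <- extract_peak_sequences(bundle$peaks$fg, bundle$genome)
  expect_gte(sum(Biostrings::width(fg_seqs)), 2e5)  # >= 200 kb of foreground
  bg <- build_tss_background(bundle$tss, bundle$genome)
  fp <- fingerprint(fg_seqs, bg, kmer_panel("TTTAT"))
  expect_equal(fp$enrichment, 2, tolerance = 0.15)
})

test_that("panel files parse and validate", {
  p <- hox_monomer_panel()
  expect_equal(p$kmer, c("TTTAT", "TTAAT", "TTGAT", "TGGAT"))
  expect_equal(attr(p, "k"), 5L)
  p8 <- exd_hox_dimer_panel()
  expect_equal(nrow(p8), 8)
  expect_true(all(substr(p8$kmer, 1, 3) == "TGA"))
  expect_error(kmer_panel(c("AC", "ACG")), "same length")
  expect_error(kmer_panel("ACGN"), "A,C,G,T")
})
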