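test_that("overlapping motif counting and strand handling behave as specified", {
  expect_equal(count_motif("GACGAGACGAG", "GACGAG"), 2L)
  expect_equal(count_motif("AAAA", "GACGAG"), 0L)
  # palindrome: both-strand count equals given-strand count
  s <- "TTCTCGAGGCTCGAGTT"
  expect_equal(count_motif(s, "CTCGAG", "both"),
               count_motif(s, "CTCGAG", "given"))
  # nonpalindrome gains its reverse-complement occurrences in both mode
  s2 <- "GACGAGTTTCTCGTC"   # CTCGTC = revcomp(GACGAG)
  expect_equal(count_motif(s2, "GACGAG", "given"), 1L)
  expect_equal(count_motif(s2, "GACGAG", "both"), 2L)
  # ambiguity codes break matches
  expect_equal(count_motif("GACGNG", "GACGAG"), 0L)
})

test_that("maximal-order Markov expectation matches the worked example and degenerate case", {
  # whole sequence equal to the motif
  expect_equal(expected_count("GACGAG", "GACGAG"), 1)
  # N(GACGA) = 2, N(ACGAG) = 2, N(ACGA) = 2 -> E = 2
  expect_equal(expected_count("GACGAGACGAG", "GACGAG"), 2)
  st <- classify_enrichment(motif_stats(c(g = "GACGAGACGAG"), "GACGAG"))
  expect_equal(st$observed, 2)
  expect_equal(st$oe_ratio, 1)
  expect_equal(st$enrichment_class, "neutral")
  # absent middle word -> undefined expectation
  expect_warning(e <- expected_count("AAAATTTT", "GACGAG"), "undefined")
  expect_true(is.na(e))
})

test_that("expected counts equal the brute-force scan oracle on random sequences", {
  set.seed(77)
  motifs <- c("GACGAG", "CTCGAG", "CTGCTC", "GAT", "AT")
  for (i in 1:30) {
    s <- random_dna(sample(30:200, 1), gc = stats::runif(1, 0.3, 0.7))
    m <- sample(motifs, 1)
    got <- suppressWarnings(expected_count(s, m))
    want <- oracle_expected_count(s, m)
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want)
  }
})

test_that("O/E with both-strand counting is invariant under reverse complement", {
  set.seed(5)
  s <- random_dna(5000, gc = 0.45)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (m in c("GACGAG", "CTGCTC")) {
    expect_equal(suppressWarnings(expected_count(s, m, "both")),
                 suppressWarnings(expected_count(rc, m, "both")))
    expect_equal(count_motif(s, m, "both"), count_motif(rc, m, "both"))
  }
})

test_that("enrichment classes follow the O/E thresholds and expectation filter", {
  st <- tibble::tibble(genome_id = letters[1:4], motif = "GACGAG",
                       observed = c(10, 4, 20, 4),
                       expected = c(10, 9.3, 10, 4.9))
  st$oe_ratio <- st$observed / st$expected
  cl <- classify_enrichment(st)
  expect_equal(cl$enrichment_class, c("neutral", "under", "over", "neutral"))
  expect_equal(cl$passes_min_expected, c(TRUE, TRUE, TRUE, FALSE))
  # O/E = 0.43 classifies as underenriched
  one <- classify_enrichment(tibble::tibble(genome_id = "x", motif = "m",
                                            observed = 43, expected = 100,
                                            oe_ratio = 0.43))
  expect_equal(one$enrichment_class, "under")
  # raising min_expected never admits more genomes
  n5 <- sum(classify_enrichment(st, min_expected = 5)$passes_min_expected)
  n9 <- sum(classify_enrichment(st, min_expected = 9)$passes_min_expected)
  expect_lte(n9, n5)
})

test_that("cohort summaries use only filtered genomes", {
  st <- tibble::tibble(genome_id = letters[1:4], motif = "m",
                       observed = 1, expected = c(10, 10, 10, 2),
                       oe_ratio = c(0.5, 0.8, 1.1, 0.1))
  cs <- cohort_summary(classify_enrichment(st))
  expect_equal(cs$n_analyzed, 3L)
  expect_equal(cs$n_excluded, 1L)
  expect_equal(cs$mean_oe, 0.8)
  expect_equal(cs$frac_below, 1 / 3)
})

test_that("sliding-window GC follows the chop/stagger convention", {
  expect_equal(gc_sliding_window("ATGC", window = 4)$gc_fraction[1], 0.5)
  g <- gc_sliding_window(strrep("G", 40), window = 10, step = 10)
  expect_true(all(g$gc_fraction == 1))
  expect_equal(g$start, c(0, 10, 20, 30))
  expect_equal(g$end, c(10, 20, 30, 40))
  # truncated final windows; ambiguous bases excluded from both sides
  w <- gc_sliding_window("GGNNCCAT", window = 8, step = 4)
  expect_equal(w$gc_fraction[1], 4 / 6)
  expect_equal(w$end[nrow(w)], 8)

  set.seed(2)
  s <- random_dna(20000, gc = 0.5)
  gw <- gc_sliding_window(s, window = 1000, step = 10)
  full <- gw[gw$end - gw$start == 1000, ]
  expect_lt(abs(mean(full$gc_fraction) - 0.5),
            3 * 0.5 / sqrt(1000))   # windows overlap; bound is conservative
  gc_direct <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / 20000
  expect_equal(mean_gc(s, 0, 20000), gc_direct)
})
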