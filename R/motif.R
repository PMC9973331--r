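#' Count overlapping motif occurrences in a sequence
#'
#' Overlapping occurrences on the given strand; in `both` mode, occurrences
#' of the reverse complement are added, counting the reverse complement only
#' when it differs from the motif so palindromes are not double counted.
#' Ambiguity codes (N etc.) never match, breaking any word that spans them.
#'
#' @param seq DNA string.
#' @param motif DNA motif over `{A,C,G,T}`.
#' @param strand_mode `"given"` (default) or `"both"`.
#' @return integer count.
#' @export
count_motif <- function(seq, motif, strand_mode = c("given", "both")) {
  strand_mode <- match.arg(strand_mode)
  motif <- toupper(motif)
  if (!grepl("^[ACGT]+$", motif)) {
    stop("motif must be over the alphabet {A,C,G,T}")
  }
  s <- Biostrings::DNAString(toupper(seq))
  n <- Biostrings::countPattern(motif, s, fixed = TRUE)
  if (strand_mode == "both") {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    if (rc != motif) n <- n + Biostrings::countPattern(rc, s, fixed = TRUE)
  }
  n
}

#' Expected motif count by the maximal-order Markov estimator
#'
#' Compositional-bias expectation for a k-mer `w`:
#' `E(w) = N(w[1..k-1]) * N(w[2..k]) / N(w[2..k-1])`, where `N` is the
#' overlapping count of the word on the same strand(s) used for the
#' observed counts. This is the expectation under a Markov model of maximal
#' order `k - 2` estimated from the sequence itself.
#'
#' @inheritParams count_motif
#' @return expected count (float), or `NA` with a warning when the middle
#'   word never occurs (expectation undefined; such genomes are excluded
#'   from summaries).
#' @export
expected_count <- function(seq, motif, strand_mode = c("given", "both")) {
  strand_mode <- match.arg(strand_mode)
  motif <- toupper(motif)
  k <- nchar(motif)
  if (k < 2L) stop("motif must have length >= 2")
  prefix <- substr(motif, 1L, k - 1L)
  suffix <- substr(motif, 2L, k)
  middle <- substr(motif, 2L, k - 1L)
  n_pre <- count_motif(seq, prefix, strand_mode)
  n_suf <- count_motif(seq, suffix, strand_mode)
  if (k == 2L) {
    # middle word is empty: N(middle) = number of counting positions
    n_mid <- nchar(seq) + 1L
  } else {
    n_mid <- count_motif(seq, middle, strand_mode)
  }
  if (n_mid == 0L) {
    warning("middle word ", middle, " absent; expected count undefined")
    return(NA_real_)
  }
  n_pre * n_suf / n_mid
}

#' Observed/expected motif statistics for one or more genomes
#'
#' @param seqs named character vector of genome sequences.
#' @param motif DNA motif.
#' @param strand_mode strand convention for both observed and expected
#'   counts.
#' @return tibble `genome_id, motif, observed, expected, oe_ratio`.
#' @export
motif_stats <- function(seqs, motif, strand_mode = c("given", "both")) {
  strand_mode <- match.arg(strand_mode)
  if (is.null(names(seqs))) {
    names(seqs) <- sprintf("genome%03d", seq_along(seqs))
  }
  obs <- unname(vapply(seqs, count_motif, numeric(1), motif = motif,
                       strand_mode = strand_mode))
  exp <- unname(vapply(seqs, function(s) {
    suppressWarnings(expected_count(s, motif, strand_mode))
  }, numeric(1)))
  tibble::tibble(
    genome_id = names(seqs), motif = motif,
    observed = as.numeric(obs), expected = exp,
    oe_ratio = ifelse(!is.na(exp) & exp > 0, obs / exp, NA_real_)
  )
}

#' Classify motif enrichment from O/E ratios
#'
#' A genome is underenriched when O/E < `lower`, overenriched when
#' O/E > `upper`, otherwise neutral. Genomes with fewer than `min_expected`
#' expected motifs are flagged for exclusion from cohort summaries because
#' low expectations destabilize the ratio.
#'
#' @param stats tibble from [motif_stats()].
#' @param lower,upper enrichment thresholds on the O/E ratio (defaults 0.72
#'   and 1.30).
#' @param min_expected minimum expected count for inclusion (default 5).
#' @return `stats` with added `enrichment_class` (`under`/`neutral`/`over`)
#'   and `passes_min_expected`.
#' @export
classify_enrichment <- function(stats, lower = 0.72, upper = 1.30,
                                min_expected = 5) {
  stopifnot(lower < upper)
  cls <- rep(NA_character_, nrow(stats))
  ok <- !is.na(stats$oe_ratio)
  cls[ok & stats$oe_ratio < lower] <- "under"
  cls[ok & stats$oe_ratio > upper] <- "over"
  cls[ok & stats$oe_ratio >= lower & stats$oe_ratio <= upper] <- "neutral"
  stats$enrichment_class <- cls
  stats$passes_min_expected <- !is.na(stats$expected) &
    stats$expected >= min_expected
  stats
}

#' Cohort summary of per-genome motif enrichment
#'
#' Summaries are computed only over genomes passing the minimum-expected
#' filter (see [classify_enrichment()]).
#'
#' @param stats classified tibble from [classify_enrichment()].
#' @param lower threshold defining "below threshold" (default 0.72).
#' @return tibble with one row per motif: `n_analyzed, n_excluded,
#'   mean_oe, n_below, frac_below`.
#' @export
cohort_summary <- function(stats, lower = 0.72) {
  stopifnot("passes_min_expected" %in% names(stats))
  stats |>
    dplyr::group_by(.data$motif) |>
    dplyr::summarise(
      n_analyzed = sum(.data$passes_min_expected),
      n_excluded = sum(!.data$passes_min_expected),
      mean_oe = mean(.data$oe_ratio[.data$passes_min_expected]),
      n_below = sum(.data$oe_ratio[.data$passes_min_expected] < lower),
      frac_below = .data$n_below / .data$n_analyzed,
      .groups = "drop"
    )
}

#' Sliding-window GC content
#'
#' Windows start at 0, `step`, `2*step`, ... (0-based half-open
#' coordinates); the final windows are truncated at the sequence end. GC is
#' `(#G + #C) / (#A + #C + #G + #T)` per window, so ambiguous bases are
#' excluded from both numerator and denominator.
#'
#' @param seq DNA string.
#' @param window window size in bp (default 1000).
#' @param step step size in bp (default 10).
#' @param sequence_id identifier for the output.
#' @return tibble `sequence_id, start, end, gc_fraction` (BED-style
#'   coordinates).
#' @export
gc_sliding_window <- function(seq, window = 1000L, step = 10L,
                              sequence_id = "seq") {
  stopifnot(window >= 1, step >= 1)
  s <- Biostrings::DNAString(toupper(seq))
  n <- length(s)
  starts0 <- seq.int(0L, n - 1L, by = step)
  ends0 <- pmin(starts0 + window, n)
  v <- Biostrings::Views(s, start = starts0 + 1L, end = ends0)
  gc <- as.vector(Biostrings::letterFrequency(v, "CG", OR = "|"))
  acgt <- as.vector(Biostrings::letterFrequency(v, "ACGT", OR = "|"))
  tibble::tibble(
    sequence_id = sequence_id, start = starts0, end = ends0,
    gc_fraction = ifelse(acgt > 0, gc / acgt, NA_real_)
  )
}

#' Mean GC content of an interval
#'
#' @param seq DNA string.
#' @param start,end 0-based half-open interval; defaults to the whole
#'   sequence.
#' @return GC fraction in `[0, 1]` over unambiguous bases.
#' @export
mean_gc <- function(seq, start = 0L, end = nchar(seq)) {
  stopifnot(start >= 0, end <= nchar(seq), end > start)
  s <- Biostrings::DNAString(toupper(substr(seq, start + 1L, end)))
  gc <- Biostrings::letterFrequency(s, "CG", OR = "|")
  acgt <- Biostrings::letterFrequency(s, "ACGT", OR = "|")
  as.numeric(gc / acgt)
}
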