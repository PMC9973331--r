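#' Configuration for the genome simulator
#'
#' @param length genome length in bp.
#' @param gc_fraction target GC content in `[0, 1]`; G and C (and A and T)
#'   are equiprobable within their class.
#' @param markov_order order of the generating chain: 0 (i.i.d. bases) or 1
#'   (first-order chain whose stationary composition equals the target;
#'   see [simulate_genome()]).
#' @param planted_motif DNA motif over `{A,C,G,T}` whose abundance is
#'   adjusted after generation, or `NULL` for no intervention.
#' @param planting_factor multiplier on the spontaneous motif count:
#'   `< 1` depletes, `> 1` enriches, `1` leaves the sequence untouched,
#'   `0` removes every occurrence.
#' @param seed integer seed.
#' @return object of class `genome_sim_config`.
#' @export
genome_sim_config <- function(length = 50000L, gc_fraction = 0.435,
                              markov_order = 0L, planted_motif = NULL,
                              planting_factor = 1, seed = 1L) {
  stopifnot(length >= 1, gc_fraction >= 0, gc_fraction <= 1,
            markov_order >= 0, planting_factor >= 0)
  if (markov_order > 1) {
    stop("markov_order > 1 is not supported by this generator")
  }
  if (!is.null(planted_motif)) {
    planted_motif <- toupper(planted_motif)
    if (!grepl("^[ACGT]+$", planted_motif)) {
      stop("planted_motif must be over the alphabet {A,C,G,T}")
    }
    if (length < 10L * nchar(planted_motif)) {
      stop("genome length must be >= 10x the planted motif length")
    }
  }
  structure(
    list(length = as.integer(length), gc_fraction = gc_fraction,
         markov_order = as.integer(markov_order),
         planted_motif = planted_motif, planting_factor = planting_factor,
         seed = as.integer(seed)),
    class = "genome_sim_config"
  )
}

# overlapping occurrence start positions of a plain motif in a plain string
.motif_starts <- function(seq, motif) {
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq))
  Biostrings::start(hits)
}

#' Simulate a genome sequence with a planted motif bias
#'
#' Generates a random sequence matching the target GC content (order 0:
#' i.i.d. bases; order 1: a "sticky" first-order chain that mixes the
#' stationary base distribution with base persistence, preserving the target
#' composition exactly in expectation). Afterwards, occurrences of
#' `planted_motif` on the generated strand are thinned (factor < 1, by
#' mutating one position of randomly chosen occurrences) or injected
#' (factor > 1, by overwriting the motif at uniformly random positions) until
#' the realized count matches `round(planting_factor * spontaneous_count)`.
#'
#' @param config a [genome_sim_config()].
#' @return single upper-case DNA string.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "genome_sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  bases <- c("A", "C", "G", "T")
  gc <- config$gc_fraction
  pi0 <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  n <- config$length
  if (config$markov_order == 0L) {
    seq_vec <- sample(bases, n, replace = TRUE, prob = pi0)
  } else {
    # sticky kernel: P(next = b | prev) = (1 - rho) * pi0[b] + rho * [b == prev]
    # has stationary distribution pi0 for any persistence rho
    rho <- 0.2
    seq_vec <- character(n)
    seq_vec[1] <- sample(bases, 1, prob = pi0)
    persist <- stats::runif(n - 1) < rho
    fresh <- sample(bases, n - 1, replace = TRUE, prob = pi0)
    for (i in seq_len(n - 1)) {
      seq_vec[i + 1] <- if (persist[i]) seq_vec[i] else fresh[i]
    }
  }
  seq <- paste(seq_vec, collapse = "")

  motif <- config$planted_motif
  if (is.null(motif) || config$planting_factor == 1) return(seq)
  k <- nchar(motif)
  target <- as.integer(round(config$planting_factor *
                               length(.motif_starts(seq, motif))))

  for (pass in 1:100) {
    starts <- .motif_starts(seq, motif)
    count <- length(starts)
    if (count == target) break
    if (count > target) {
      # destroy surplus occurrences: mutate one random position inside each
      kill <- sample(starts, count - target)
      sv <- strsplit(seq, "", fixed = TRUE)[[1]]
      for (s in kill) {
        pos <- s + sample.int(k, 1) - 1L
        sv[pos] <- sample(setdiff(bases, sv[pos]), 1)
      }
      seq <- paste(sv, collapse = "")
    } else {
      # inject at uniformly random positions by overwriting with the motif
      need <- target - count
      at <- sample.int(nchar(seq) - k + 1L, need)
      sv <- strsplit(seq, "", fixed = TRUE)[[1]]
      for (s in at) sv[s:(s + k - 1L)] <- strsplit(motif, "")[[1]]
      seq <- paste(sv, collapse = "")
    }
  }
  seq
}

#' Write genomes to a FASTA file
#'
#' @param seqs named character vector of DNA strings (names become record
#'   ids).
#' @param path output file path.
#' @param width line-wrap width in columns.
#' @return `path`, invisibly.
#' @export
write_genomes_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read genomes from a FASTA file
#'
#' Multi-record files are returned one string per record; use
#' [motif_stats()] with a grouping of records per genome if needed
#' (counts never span record boundaries).
#'
#' @param path FASTA file path.
#' @return named character vector of upper-case sequences.
#' @export
read_genomes_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}
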