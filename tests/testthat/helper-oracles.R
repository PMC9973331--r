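# Independent oracles used across tests. These deliberately avoid the
# package's own code paths (plain substring scans, permutation enumeration)
# so that agreement is evidence, not tautology.

# minimum-cost assignment by exhaustive permutation enumeration (n <= 7)
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    s <- sum(cost[cbind(seq_len(n), p)])
    if (s < best) best <- s
  }
  best
}

# overlapping word count by a plain character scan
scan_count <- function(seq, word) {
  k <- nchar(word)
  n <- nchar(seq)
  if (n < k) return(0L)
  sum(vapply(seq_len(n - k + 1L),
             function(i) substr(seq, i, i + k - 1L) == word, logical(1)))
}

# maximal-order Markov expectation from scanned counts
oracle_expected_count <- function(seq, motif) {
  k <- nchar(motif)
  pre <- scan_count(seq, substr(motif, 1, k - 1))
  suf <- scan_count(seq, substr(motif, 2, k))
  mid <- if (k == 2) nchar(seq) + 1L else scan_count(seq, substr(motif, 2, k - 1))
  if (mid == 0) return(NA_real_)
  pre * suf / mid
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# normalized-coordinate point cloud with a Gaussian hotspot
hotspot_points <- function(n, centers_u, centers_v, sd = 0.12,
                           frac_uniform = 0.3) {
  n_unif <- round(n * frac_uniform)
  n_hot <- n - n_unif
  idx <- sample(seq_along(centers_u), n_hot, replace = TRUE)
  u <- c(stats::runif(n_unif, -1, 1),
         stats::rnorm(n_hot, centers_u[idx], sd))
  v <- c(stats::runif(n_unif, -1, 1),
         stats::rnorm(n_hot, centers_v[idx], sd))
  tibble::tibble(u = pmin(pmax(u, -1), 1), v = pmin(pmax(v, -1), 1))
}

# ellipse mask: semi-axes a_um, b_um, rotated by theta, on a pixel grid
ellipse_mask <- function(a_um, b_um, theta = 0, pixel_size = 0.05,
                        pad_um = 1) {
  half <- max(a_um, b_um) + pad_um
  npx <- ceiling(2 * half / pixel_size)
  xs <- ((seq_len(npx)) - 0.5) * pixel_size - half
  grid_x <- matrix(rep(xs, each = npx), npx)       # columns -> x
  grid_y <- matrix(rep(xs, times = npx), npx)      # rows -> y
  xr <- cos(theta) * grid_x + sin(theta) * grid_y
  yr <- -sin(theta) * grid_x + cos(theta) * grid_y
  (xr / a_um)^2 + (yr / b_um)^2 <= 1
}
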