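test_that("immobile molecules with zero localization noise report constant positions", {
  cfg <- tracking_sim_config(states = list(c(0, 1)), sigma_loc = 0,
                             n_tracks = 20, seed = 7)
  sim <- simulate_trajectories(cfg)
  per_track <- split(sim$localizations, sim$localizations$track_id)
  for (tr in per_track) {
    expect_equal(diff(range(tr$x_um)), 0)
    expect_equal(diff(range(tr$y_um)), 0)
  }
})

test_that("unconfined single-frame displacements match the Brownian moment 4*D*dt + 4*sigma^2", {
  D <- 0.1; dt <- 0.04; sig <- 0.03
  cfg <- tracking_sim_config(cell_length = 100, cell_width = 100,
                             states = list(c(D, 1)), sigma_loc = sig,
                             frame_interval = dt, n_tracks = 1500,
                             mean_track_length = 9, seed = 11)
  sim <- simulate_trajectories(cfg)
  sq <- unlist(lapply(split(sim$localizations, sim$localizations$track_id),
                      function(tr) diff(tr$x_um)^2 + diff(tr$y_um)^2))
  expect_gt(length(sq), 1e4)
  expected <- 4 * D * dt + 4 * sig^2
  se <- stats::sd(sq) / sqrt(length(sq))
  expect_lt(abs(mean(sq) - expected), 3 * se)
})

test_that("trajectory simulation is deterministic for a fixed seed and confined before noise", {
  cfg <- tracking_sim_config(states = list(c(0.3, 0.4), c(0.02, 0.6)),
                             n_tracks = 50, seed = 5)
  a <- simulate_trajectories(cfg)
  b <- simulate_trajectories(cfg)
  expect_identical(a, b)
  # true (pre-noise) positions lie inside the capsule projection
  r <- cfg$cell_width / 2
  half_seg <- cfg$cell_length / 2 - r
  cx <- pmin(pmax(a$localizations$x_true, -half_seg), half_seg)
  d <- sqrt((a$localizations$x_true - cx)^2 + a$localizations$y_true^2)
  expect_true(all(d <= r + 1e-12))
})

test_that("state assignment fractions converge to the configured weights", {
  cfg <- tracking_sim_config(states = list(c(0.05, 0.3), c(1, 0.7)),
                             n_tracks = 2000, seed = 2)
  sim <- simulate_trajectories(cfg)
  phat <- mean(sim$truth$state_index == 1L)
  # 99.9% binomial CI half-width at n = 2000, p = 0.3
  expect_lt(abs(phat - 0.3), 3.3 * sqrt(0.3 * 0.7 / 2000))
})

test_that("config validation rejects unnormalized weights and oversized steps", {
  expect_error(tracking_sim_config(states = list(c(0.1, 0.6), c(1, 0.6))),
               "sum to 1")
  expect_error(tracking_sim_config(states = list(c(50, 1)),
                                   cell_length = 2, cell_width = 0.8),
               "confinement dominates")
})

test_that("genome simulator respects composition, planting, and determinism", {
  all_gc <- simulate_genome(genome_sim_config(length = 500, gc_fraction = 1,
                                              seed = 1))
  expect_true(grepl("^[GC]+$", all_gc))

  cfg0 <- genome_sim_config(length = 20000, gc_fraction = 0.5,
                            planted_motif = "GACGAG", planting_factor = 0,
                            seed = 3)
  expect_identical(count_motif(simulate_genome(cfg0), "GACGAG"), 0L)

  cfg <- genome_sim_config(length = 30000, gc_fraction = 0.5, seed = 9)
  expect_identical(simulate_genome(cfg), simulate_genome(cfg))
})

test_that("neutral planting leaves motif counts at the multinomial expectation", {
  # order-0 model: E[count] = (L - k + 1) * p(motif)
  L <- 40000; motif <- "GACGAG"
  p <- 0.25^6
  counts <- vapply(1:30, function(s) {
    g <- simulate_genome(genome_sim_config(length = L, gc_fraction = 0.5,
                                           planted_motif = motif,
                                           planting_factor = 1, seed = s))
    count_motif(g, motif)
  }, integer(1))
  expected <- (L - 6 + 1) * p
  se <- sqrt(expected / 30)   # Poisson-scale error of the mean
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("neighborhood simulator honors occupancy, defense rate, and binomial mean", {
  cfg <- neighborhood_sim_config(
    n_neighborhoods = 50,
    conserved_families = list(list(family_id = "PFhelicase", rel_pos = 1L,
                                   occupancy = 1)),
    defense_rate = 0, seed = 4)
  sim <- simulate_neighborhoods(cfg)
  at1 <- sim$neighborhoods[sim$neighborhoods$rel_pos == 1L, ]
  expect_true(all(at1$family_id == "PFhelicase"))

  cfg0 <- neighborhood_sim_config(n_neighborhoods = 40, defense_rate = 0,
                                  seed = 4)
  sim0 <- simulate_neighborhoods(cfg0)
  counts0 <- count_defense_families(as_neighborhoods(sim0$neighborhoods),
                                    sim0$defense_families)
  expect_true(all(counts0$defense_count == 0))

  p <- 0.15
  cfgp <- neighborhood_sim_config(n_neighborhoods = 300, defense_rate = p,
                                  seed = 8)
  simp <- simulate_neighborhoods(cfgp)
  countsp <- count_defense_families(as_neighborhoods(simp$neighborhoods),
                                    simp$defense_families)
  se <- sqrt(20 * p * (1 - p) / 300)
  expect_lt(abs(mean(countsp$defense_count) - 20 * p), 4 * se)
})

test_that("titration simulator reproduces 4PL identities at zero noise", {
  p <- c(b = -1.2, c = 0.05, d = 0.95, e = 40)
  cfg <- titration_sim_config(params_4pl = p,
                              concentrations = c(0, 40, 1e6),
                              noise_sd = 0, replicates = 1, seed = 1)
  sim <- simulate_titration(cfg)
  expect_equal(sim$fraction_bound[sim$conc_nM == 40],
               (p[["c"]] + p[["d"]]) / 2)
  expect_equal(sim$fraction_bound[sim$conc_nM == 0], p[["c"]])

  cfg0 <- titration_sim_config(params_4pl = c(b = -1, c = 0, d = 1, e = 40),
                               concentrations = c(0, 10, 40),
                               noise_sd = 0, replicates = 1, seed = 1)
  sim0 <- simulate_titration(cfg0)
  expect_equal(sim0$fraction_bound[sim0$conc_nM == 0], 0)
})
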