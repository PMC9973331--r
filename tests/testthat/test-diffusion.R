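make_traj <- function(x, y = rep(0, length(x))) {
  tibble::tibble(frame = seq_along(x) - 1L, x_um = x, y_um = y)
}

test_that("time-averaged MSD matches hand-enumerated displacement pairs", {
  # stationary track: zero at every lag
  st <- compute_tamsd(make_traj(rep(1, 5)), max_lag = 4, frame_interval = 1)
  expect_equal(st$msd, rep(0, 4))

  # two points separated by d: msd(1 lag) = d^2
  two <- compute_tamsd(make_traj(c(0, 0.3)), frame_interval = 1)
  expect_equal(two$msd, 0.09)

  # x = 0, 1, 3, 6: lag-1 pairs (1, 4, 9), lag-2 pairs (9, 25)
  four <- compute_tamsd(make_traj(c(0, 1, 3, 6)), max_lag = 2,
                        frame_interval = 1)
  expect_equal(four$msd, c((1 + 4 + 9) / 3, (9 + 25) / 2))
  expect_equal(four$n_pairs, c(3L, 2L))
})

test_that("the MSD fit inverts exact model curves to machine precision", {
  D <- 0.05; sig <- 0.02; dt <- 0.04
  curve <- tibble::tibble(tau_s = (1:5) * dt,
                          msd = 4 * D * (1:5) * dt + 2 * sig^2)
  ft <- fit_diffusion(curve)
  expect_equal(ft$D, D, tolerance = 1e-12)
  expect_equal(ft$sigma, sig, tolerance = 1e-12)
  expect_equal(ft$r_squared, 1)

  zero <- fit_diffusion(tibble::tibble(tau_s = (1:3) * dt, msd = rep(0, 3)))
  expect_equal(zero$sigma, 0)
  expect_true(zero$d_clipped)   # D floored for log-scale use
})

test_that("fitted intercepts grow with the generating localization noise", {
  dt <- 0.04
  sig <- c(0.01, 0.03, 0.05)
  intercepts <- vapply(sig, function(s) {
    curve <- tibble::tibble(tau_s = (1:5) * dt,
                            msd = 4 * 0.1 * (1:5) * dt + 2 * s^2)
    fit_diffusion(curve)$sigma
  }, numeric(1))
  expect_true(all(diff(intercepts) > 0))
})

test_that("ensemble median of per-track D is close to the simulator truth", {
  cfg <- tracking_sim_config(cell_length = 20, cell_width = 20,
                             states = list(c(0.1, 1)), sigma_loc = 0.03,
                             frame_interval = 0.04, n_tracks = 400,
                             mean_track_length = 50, seed = 17)
  sim <- simulate_trajectories(cfg)
  trajs <- split_trajectories(sim$localizations)
  # long tracks only: per-track OLS on 5 lags needs enough pairs for the
  # median to sit close to the generating D
  long <- trajs[vapply(trajs, nrow, integer(1)) >= 30]
  fits <- fit_tracks(long)
  expect_lt(abs(stats::median(fits$D) - 0.1), 0.01)
})

test_that("log-D histogram weighting follows displacement counts and unit area", {
  fits <- tibble::tibble(track_id = c("a", "b"),
                         D = c(0.01, 1), sigma = 0, r_squared = 1,
                         n_lags = 5, d_clipped = FALSE,
                         track_length = c(11L, 31L))
  h <- log_d_distribution(fits, bin_width = 0.1)
  expect_equal(sum(h$density) * 0.1, 1)
  occ <- h$weights[h$weights > 0]
  expect_equal(unname(occ[2] / occ[1]), 3)   # 30 vs 10 displacements

  same <- tibble::tibble(track_id = c("a", "b"), D = 0.1, sigma = 0,
                         r_squared = 1, n_lags = 5, d_clipped = FALSE,
                         track_length = 10L)
  hs <- log_d_distribution(same, bin_width = 0.1)
  expect_equal(sum(hs$density > 0), 1L)

  # histogram mean equals the weighted mean of log10 D to within half a bin
  set.seed(3)
  fits2 <- tibble::tibble(track_id = as.character(1:200),
                          D = 10^stats::rnorm(200, -1, 0.4), sigma = 0,
                          r_squared = 1, n_lags = 5, d_clipped = FALSE,
                          track_length = sample(4:40, 200, TRUE))
  h2 <- log_d_distribution(fits2, bin_width = 0.1)
  hist_mean <- sum(h2$mids * h2$density) / sum(h2$density)
  w <- fits2$track_length - 1
  expect_lt(abs(hist_mean - sum(w * log10(fits2$D)) / sum(w)), 0.05)
})

test_that("Gaussian fits to histograms recover one and two modes", {
  set.seed(5)
  x <- stats::rnorm(4000, -1, 0.3)
  fits <- tibble::tibble(track_id = as.character(seq_along(x)), D = 10^x,
                         sigma = 0, r_squared = 1, n_lags = 5,
                         d_clipped = FALSE, track_length = 10L)
  h <- log_d_distribution(fits, bin_width = 0.1)
  g1 <- fit_gaussian_mixture(h, k = 1)
  expect_lt(abs(g1$mean - (-1)), 0.05)
  expect_equal(g1$weight, 1)

  x2 <- c(stats::rnorm(4000, -1.5, 0.15), stats::rnorm(4000, -0.2, 0.15))
  fits2 <- tibble::tibble(track_id = as.character(seq_along(x2)),
                          D = 10^x2, sigma = 0, r_squared = 1, n_lags = 5,
                          d_clipped = FALSE, track_length = 10L)
  h2 <- log_d_distribution(fits2, bin_width = 0.1)
  g2 <- fit_gaussian_mixture(h2, k = 2)
  expect_lt(abs(g2$mean[1] - (-1.5)), 0.05)
  expect_lt(abs(g2$mean[2] - (-0.2)), 0.05)
  expect_true(all(abs(g2$weight - 0.5) < 0.05))
  expect_true(all(g2$weight >= 0))
  expect_equal(sum(g2$weight), 1)
})

test_that("jump-length mixture model is a proper CDF and honors bounds", {
  R <- seq(0, 10, 0.01)
  p <- jump_cdf_model(R, tau = 0.04, D = c(0.05, 1), f = c(0.3, 0.7),
                      sigma = 0.03)
  expect_true(all(diff(p) >= 0))
  expect_equal(p[length(p)], 1, tolerance = 1e-10)
  expect_equal(p[1], 0)

  expect_error(fit_jump_mixture(list(), d_bounds = list(c(1, 0.5), c(1, 2))),
               "empty constraint box")
})

test_that("jump mixture recovers a single state and respects constraint boxes", {
  cfg <- tracking_sim_config(states = list(c(0.3, 1)), sigma_loc = 0.02,
                             n_tracks = 600, mean_track_length = 8,
                             seed = 23)
  sim <- simulate_trajectories(cfg)
  trajs <- split_trajectories(sim$localizations)
  jm <- suppressWarnings(
    fit_jump_mixture(trajs, n_states = 2L,
                     d_bounds = list(c(1e-4, 0.08), c(0.08, 5)),
                     sigma = 0.02, seed = 1))
  # effectively one state: nearly all weight on the component containing 0.3
  expect_gt(jm$f[2], 0.9)
  expect_lt(abs(jm$D[2] - 0.3), 0.06)
  for (i in 1:2) {
    expect_gte(jm$D[i], jm$d_bounds[[i]][1])
    expect_lte(jm$D[i], jm$d_bounds[[i]][2])
  }
  expect_equal(sum(jm$f), 1)
})
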