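#' Configuration for the single-molecule trajectory simulator
#'
#' Describes a population of molecules diffusing in the 2D projection of a
#' rod-shaped (spherocylindrical) bacterial cell, imaged with finite
#' localization precision and photobleaching-limited track lengths.
#'
#' @param cell_length cell long dimension in micrometers (pole to pole).
#' @param cell_width cell short dimension in micrometers; also the diameter
#'   of the hemispherical poles of the 2D capsule projection.
#' @param states list of `c(D, f)` pairs: diffusion coefficient in um^2/s and
#'   the weight fraction of tracks in that state. Fractions must sum to 1.
#' @param sigma_loc per-axis localization precision in micrometers (Gaussian
#'   error added to each reported coordinate).
#' @param frame_interval camera frame interval in seconds.
#' @param n_tracks number of tracks to simulate (one molecule per cell).
#' @param mean_track_length mean track length in frames; lengths are drawn
#'   as 2 + Geometric so that photobleaching is memoryless and every track
#'   has at least one displacement.
#' @param seed integer seed making the simulation reproducible.
#' @return an object of class `tracking_sim_config`.
#' @export
tracking_sim_config <- function(cell_length = 3, cell_width = 1,
                                states = list(c(0.1, 1)),
                                sigma_loc = 0.03, frame_interval = 0.04,
                                n_tracks = 100, mean_track_length = 8,
                                seed = 1L) {
  stopifnot(cell_length >= cell_width, cell_width > 0, frame_interval > 0,
            sigma_loc >= 0, n_tracks >= 1, mean_track_length >= 2)
  d <- vapply(states, `[`, numeric(1), 1L)
  f <- vapply(states, `[`, numeric(1), 2L)
  if (any(d < 0)) stop("all state diffusion coefficients must be >= 0")
  if (abs(sum(f) - 1) > 1e-8) {
    stop("state weight fractions must sum to 1 (got ", sum(f), ")")
  }
  # confinement must not dominate a single frame: reject step scales on the
  # order of the cell itself, where the mirrored-overshoot reflection breaks
  step_sd <- sqrt(2 * max(d) * frame_interval)
  if (step_sd > cell_width / 2) {
    stop("per-frame step scale (", signif(step_sd, 3),
         " um) exceeds the cell half-width; confinement dominates")
  }
  structure(
    list(cell_length = cell_length, cell_width = cell_width,
         D = d, f = f, sigma_loc = sigma_loc,
         frame_interval = frame_interval, n_tracks = n_tracks,
         mean_track_length = mean_track_length, seed = as.integer(seed)),
    class = "tracking_sim_config"
  )
}

# squared distance from points to the capsule's central segment (capsule is
# centered at the origin with long axis along x)
.capsule_axis_dist <- function(x, y, half_seg) {
  cx <- pmin(pmax(x, -half_seg), half_seg)
  sqrt((x - cx)^2 + y^2)
}

.inside_capsule <- function(x, y, half_seg, r) {
  .capsule_axis_dist(x, y, half_seg) <= r
}

# reflect a point that left the capsule back inside by mirroring the radial
# overshoot about the boundary (repeat in the rare multi-bounce case)
.reflect_into_capsule <- function(x, y, half_seg, r) {
  for (iter in 1:50) {
    cx <- pmin(pmax(x, -half_seg), half_seg)
    dx <- x - cx
    dy <- y
    d <- sqrt(dx^2 + dy^2)
    if (d <= r) return(c(x, y))
    if (d == 0) return(c(x, 0))
    scale <- (2 * r - d) / d
    x <- cx + dx * scale
    y <- dy * scale
  }
  stop("reflection failed to return point into the cell")
}

#' Simulate confined single-molecule trajectories
#'
#' Each track is assigned one diffusive state (no interconversion) drawn from
#' the configured weight fractions. True positions perform 2D Brownian steps
#' with per-axis variance `2 * D * dt`, reflected at the projected
#' spherocylinder boundary by mirroring the overshoot; reported positions add
#' independent Gaussian localization error (`sigma_loc` per axis). Track
#' lengths are geometric with the configured mean and a minimum of 2 frames.
#' One molecule is placed per cell so that ground-truth linking is
#' unambiguous.
#'
#' @param config a [tracking_sim_config()].
#' @return list with elements
#'   * `localizations`: tibble `cell_id, track_id, frame, x_um, y_um`
#'   * `truth`: tibble `track_id, state_index, D_true, track_length`
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "tracking_sim_config"))
  withr_seed <- config$seed
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(withr_seed)

  r <- config$cell_width / 2
  half_seg <- config$cell_length / 2 - r
  dt <- config$frame_interval
  n <- config$n_tracks

  states <- sample.int(length(config$D), n, replace = TRUE, prob = config$f)
  # length = 2 + Geometric(p) has mean 2 + (1 - p) / p = mean_track_length
  p_geom <- 1 / (config$mean_track_length - 1)
  lens <- 2L + stats::rgeom(n, p_geom)

  loc_list <- vector("list", n)
  for (i in seq_len(n)) {
    L <- lens[i]
    D <- config$D[states[i]]
    step_sd <- sqrt(2 * D * dt)
    # uniform initial position inside the capsule by rejection
    repeat {
      x0 <- stats::runif(1, -config$cell_length / 2, config$cell_length / 2)
      y0 <- stats::runif(1, -r, r)
      if (.inside_capsule(x0, y0, half_seg, r)) break
    }
    xs <- numeric(L)
    ys <- numeric(L)
    xs[1] <- x0
    ys[1] <- y0
    if (step_sd > 0) {
      dxs <- stats::rnorm(L - 1, 0, step_sd)
      dys <- stats::rnorm(L - 1, 0, step_sd)
      for (t in seq_len(L - 1)) {
        pt <- .reflect_into_capsule(xs[t] + dxs[t], ys[t] + dys[t],
                                    half_seg, r)
        xs[t + 1] <- pt[1]
        ys[t + 1] <- pt[2]
      }
    } else {
      xs[] <- x0
      ys[] <- y0
    }
    if (config$sigma_loc > 0) {
      xr <- xs + stats::rnorm(L, 0, config$sigma_loc)
      yr <- ys + stats::rnorm(L, 0, config$sigma_loc)
    } else {
      xr <- xs
      yr <- ys
    }
    loc_list[[i]] <- tibble::tibble(
      cell_id = sprintf("cell%05d", i),
      track_id = sprintf("track%05d", i),
      frame = seq_len(L) - 1L,
      x_um = xr, y_um = yr,
      x_true = xs, y_true = ys
    )
  }
  locs <- dplyr::bind_rows(loc_list)
  truth <- tibble::tibble(
    track_id = sprintf("track%05d", seq_len(n)),
    state_index = states,
    D_true = config$D[states],
    track_length = lens
  )
  list(localizations = locs, truth = truth)
}

# save/restore the global RNG state so simulators do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
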