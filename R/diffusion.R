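#' Time-averaged mean squared displacement of one trajectory
#'
#' For lag `tau = m * dt`, the time-averaged MSD is the mean over all start
#' frames of the squared 2D displacement `|r(t + m*dt) - r(t)|^2`.
#'
#' @param traj data frame with columns `frame, x_um, y_um`, frames strictly
#'   increasing with unit step.
#' @param max_lag largest lag in frames; truncated to `length - 1`.
#' @param frame_interval frame interval in seconds.
#' @return tibble `lag_frames, tau_s, msd, n_pairs`.
#' @export
compute_tamsd <- function(traj, max_lag = 5L, frame_interval = 0.04) {
  n <- nrow(traj)
  if (n < 2L) stop("trajectory must have at least 2 localizations")
  if (any(diff(traj$frame) != 1L)) {
    stop("trajectory frames must be contiguous (unit steps)")
  }
  max_lag <- min(max_lag, n - 1L)
  x <- traj$x_um
  y <- traj$y_um
  lags <- seq_len(max_lag)
  msd <- vapply(lags, function(m) {
    dx <- x[(m + 1):n] - x[1:(n - m)]
    dy <- y[(m + 1):n] - y[1:(n - m)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  tibble::tibble(lag_frames = lags, tau_s = lags * frame_interval,
                 msd = msd, n_pairs = n - lags)
}

#' Fit a diffusion coefficient and localization precision to an MSD curve
#'
#' Ordinary least squares of `MSD = 4 * D * tau + 2 * sigma^2`:
#' `D = slope / 4` and `sigma = sqrt(intercept / 2)`. A negative fitted
#' slope is clipped to the positivity floor `d_floor` (needed for log-scale
#' histograms) and flagged; a negative intercept yields `sigma = 0`.
#'
#' @param curve output of [compute_tamsd()] (needs `tau_s` and `msd`).
#' @param d_floor positivity floor for D in um^2/s.
#' @return tibble row `D, sigma, r_squared, n_lags, d_clipped`.
#' @export
fit_diffusion <- function(curve, d_floor = 1e-4) {
  stopifnot(all(c("tau_s", "msd") %in% names(curve)))
  if (nrow(curve) < 2L) stop("need at least 2 lag points")
  if (length(unique(curve$tau_s)) < 2L) stop("all lag values identical")
  fit <- stats::lm(msd ~ tau_s, data = curve)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((curve$msd - mean(curve$msd))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  D_raw <- slope / 4
  tibble::tibble(
    D = max(D_raw, d_floor),
    sigma = sqrt(max(intercept, 0) / 2),
    r_squared = r2,
    n_lags = nrow(curve),
    d_clipped = D_raw < d_floor
  )
}

#' Per-track diffusion fits for a set of trajectories
#'
#' Applies [compute_tamsd()] and [fit_diffusion()] to every trajectory with
#' at least `min_length` localizations, using lags `1..min(max_lag, L - 1)`.
#'
#' @param trajs list of trajectory tibbles (see [split_trajectories()]).
#' @param max_lag maximum lag in frames for the per-track fit.
#' @param frame_interval frame interval in seconds.
#' @param min_length minimum localizations per track (default 4).
#' @param d_floor positivity floor passed to [fit_diffusion()].
#' @return tibble `track_id, D, sigma, r_squared, n_lags, d_clipped,
#'   track_length`.
#' @export
fit_tracks <- function(trajs, max_lag = 5L, frame_interval = 0.04,
                       min_length = 4L, d_floor = 1e-4) {
  keep <- vapply(trajs, nrow, integer(1)) >= min_length
  trajs <- trajs[keep]
  if (length(trajs) == 0L) stop("no trajectory meets the minimum length")
  rows <- lapply(names(trajs), function(id) {
    tr <- trajs[[id]]
    curve <- compute_tamsd(tr, max_lag = max_lag,
                           frame_interval = frame_interval)
    ft <- fit_diffusion(curve, d_floor = d_floor)
    ft$track_id <- id
    ft$track_length <- nrow(tr)
    ft
  })
  out <- dplyr::bind_rows(rows)
  out[, c("track_id", "D", "sigma", "r_squared", "n_lags", "d_clipped",
          "track_length")]
}

#' Track-length-weighted histogram of log10 diffusion coefficients
#'
#' Each track contributes weight proportional to its number of displacements
#' (`track_length - 1`); the histogram is normalized to unit area. Tracks
#' whose fitted D sat at the positivity floor are excluded and counted.
#'
#' @param fits output of [fit_tracks()].
#' @param bin_width histogram bin width in log10(um^2/s) units.
#' @return list with `breaks`, `mids`, `density` (unit area), `weights`
#'   (bin weight totals), and `n_excluded` (floor-clipped tracks).
#' @export
log_d_distribution <- function(fits, bin_width = 0.1) {
  stopifnot(nrow(fits) > 0)
  keep <- !fits$d_clipped
  n_excluded <- sum(!keep)
  fits <- fits[keep, ]
  if (nrow(fits) == 0L) stop("all tracks were clipped at the D floor")
  logd <- log10(fits$D)
  w <- fits$track_length - 1
  lo <- floor(min(logd) / bin_width) * bin_width
  hi <- ceiling(max(logd) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (max(breaks) < max(logd)) breaks <- c(breaks, max(breaks) + bin_width)
  bin <- findInterval(logd, breaks, rightmost.closed = TRUE)
  wsum <- vapply(seq_len(length(breaks) - 1L),
                 function(b) sum(w[bin == b]), numeric(1))
  density <- wsum / (sum(wsum) * bin_width)
  list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       density = density, weights = wsum, n_excluded = n_excluded)
}

.gauss_sum <- function(x, amp, mu, sd) {
  y <- 0
  for (i in seq_along(amp)) {
    y <- y + amp[i] * exp(-(x - mu[i])^2 / (2 * sd[i]^2))
  }
  y
}

#' Fit a 1- or 2-component Gaussian to a log10-D histogram
#'
#' Nonlinear least squares of a sum of `k` Gaussian bumps to the histogram
#' bin heights (the histogram, not the raw sample, is the fitting target).
#' For `k = 2`, five seeded starting points are tried and the best
#' residual-sum-of-squares solution is kept. Component weights are the
#' Gaussian areas normalized to sum to 1; components are ordered by
#' increasing mean.
#'
#' @param hist output of [log_d_distribution()].
#' @param k number of components, 1 or 2.
#' @param seed seed for the multi-start initialization.
#' @return list with `k`, `mean`, `sd`, `weight` (each length `k`, ordered
#'   by mean), and `rss`.
#' @export
fit_gaussian_mixture <- function(hist, k = 2L, seed = 1L) {
  stopifnot(k %in% c(1L, 2L))
  x <- hist$mids
  y <- hist$density
  occupied <- sum(y > 0)
  if (occupied < 3 * (3 * k - 1) / 3) {
    warning("few occupied bins (", occupied, ") for a ", k,
            "-component fit")
  }
  wmean <- sum(x * y) / sum(y)
  wsd <- sqrt(sum(y * (x - wmean)^2) / sum(y))
  amp0 <- max(y)
  starts <- if (k == 1L) {
    list(c(a1 = amp0, m1 = wmean, s1 = wsd))
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    qs <- list(c(0.25, 0.75), c(0.1, 0.9), c(0.3, 0.6), c(0.4, 0.8),
               c(0.2, 0.5))
    cdf <- cumsum(y) / sum(y)
    lapply(qs, function(q) {
      m <- vapply(q, function(p) x[which.min(abs(cdf - p))], numeric(1))
      m <- m + stats::rnorm(2, 0, 0.01)
      c(a1 = amp0 / 2, m1 = min(m), s1 = max(wsd / 2, 0.05),
        a2 = amp0 / 2, m2 = max(m), s2 = max(wsd / 2, 0.05))
    })
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch({
      if (k == 1L) {
        minpack.lm::nlsLM(
          y ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)),
          start = as.list(st),
          lower = c(0, min(x) - 1, 1e-3),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          y ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)) +
            a2 * exp(-(x - m2)^2 / (2 * s2^2)),
          start = as.list(st),
          lower = c(0, min(x) - 1, 1e-3, 0, min(x) - 1, 1e-3),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("Gaussian mixture fit failed to converge from any start")
  }
  cf <- stats::coef(best$fit)
  if (k == 1L) {
    amp <- cf[["a1"]]; mu <- cf[["m1"]]; sd <- cf[["s1"]]
  } else {
    amp <- c(cf[["a1"]], cf[["a2"]])
    mu <- c(cf[["m1"]], cf[["m2"]])
    sd <- c(cf[["s1"]], cf[["s2"]])
  }
  ord <- order(mu)
  amp <- amp[ord]; mu <- mu[ord]; sd <- sd[ord]
  area <- amp * sd * sqrt(2 * pi)
  weight <- if (sum(area) > 0) area / sum(area) else rep(0, k)
  list(k = k, mean = mu, sd = sd, weight = weight, rss = best$rss)
}

#' Cumulative jump-length distribution of a Brownian mixture
#'
#' `P(r <= R | lag m*dt) = sum_i f_i * (1 - exp(-R^2 / (4 * (D_i * m * dt +
#' sigma^2))))`: the 2D Rayleigh mixture with static localization error.
#'
#' @param R displacement radii (um).
#' @param tau lag times (s), recycled against `R`.
#' @param D,f per-state diffusion coefficients and weight fractions.
#' @param sigma localization precision (um).
#' @return vector of cumulative probabilities.
#' @export
jump_cdf_model <- function(R, tau, D, f, sigma) {
  stopifnot(length(D) == length(f))
  y <- 0
  for (i in seq_along(D)) {
    y <- y + f[i] * (1 - exp(-R^2 / (4 * (D[i] * tau + sigma^2))))
  }
  y
}

#' Fit a 2- or 3-state jump-length mixture to pooled displacements
#'
#' Pools single-molecule displacements at the requested frame lags and fits
#' the empirical cumulative jump-length distribution, jointly over lags, to
#' a Brownian mixture by bound-constrained least squares (multi-start
#' L-BFGS-B; weight fractions through a stick-breaking parameterization so
#' they always sum to 1). Each state's diffusion coefficient is confined to
#' its constraint box, which is how a reference data set's confidence
#' intervals are imposed when comparing weight fractions across conditions.
#' States are returned ordered by increasing D; `F_bound` is the weight of
#' the slowest state.
#'
#' @param trajs list of trajectory tibbles.
#' @param n_states 2 or 3.
#' @param d_bounds list of `c(lower, upper)` per state (um^2/s), ordered by
#'   state. Defaults to broad boxes `[1e-4, 0.08]` / `[0.08, 5]` for 2
#'   states.
#' @param sigma localization precision in um (fixed during the fit).
#' @param lags frame lags to pool (default `1:5`).
#' @param frame_interval frame interval in seconds.
#' @param n_grid number of radii per lag at which the CDF is matched.
#' @param seed seed for the multi-start.
#' @return list with `D`, `f` (ordered by D), `F_bound`, `loss`, `n_disp`
#'   (pooled displacements per lag).
#' @export
fit_jump_mixture <- function(trajs, n_states = 2L, d_bounds = NULL,
                             sigma = 0.03, lags = 1:5,
                             frame_interval = 0.04, n_grid = 60L,
                             seed = 1L) {
  stopifnot(n_states %in% c(2L, 3L))
  if (is.null(d_bounds)) {
    d_bounds <- if (n_states == 2L) {
      list(c(1e-4, 0.08), c(0.08, 5))
    } else {
      list(c(1e-4, 0.05), c(0.05, 0.5), c(0.5, 5))
    }
  }
  if (length(d_bounds) != n_states) {
    stop("`d_bounds` must supply one box per state")
  }
  for (b in d_bounds) {
    if (length(b) != 2L || b[1] > b[2]) stop("empty constraint box")
  }
  for (i in seq_len(n_states - 1L)) {
    if (d_bounds[[i]][2] > d_bounds[[i + 1]][1]) {
      warning("overlapping d_bounds between states ", i, " and ", i + 1,
              "; states may be unidentifiable")
    }
  }

  # pool displacements per lag
  disp <- lapply(lags, function(m) {
    unlist(lapply(trajs, function(tr) {
      n <- nrow(tr)
      if (n <= m) return(numeric(0))
      dx <- tr$x_um[(m + 1):n] - tr$x_um[1:(n - m)]
      dy <- tr$y_um[(m + 1):n] - tr$y_um[1:(n - m)]
      sqrt(dx^2 + dy^2)
    }), use.names = FALSE)
  })
  n_disp <- vapply(disp, length, integer(1))
  if (any(n_disp < 100)) {
    warning("fewer than 100 pooled displacements at lag(s) ",
            paste(lags[n_disp < 100], collapse = ", "))
  }
  if (all(n_disp == 0)) stop("no displacements at any requested lag")

  grids <- lapply(disp, function(r) {
    if (length(r) == 0) return(NULL)
    seq(0, max(r), length.out = n_grid)
  })
  ecdfs <- lapply(seq_along(disp), function(i) {
    if (is.null(grids[[i]])) return(NULL)
    stats::ecdf(disp[[i]])(grids[[i]])
  })

  k <- n_states
  lo_d <- vapply(d_bounds, `[`, numeric(1), 1L)
  hi_d <- vapply(d_bounds, `[`, numeric(1), 2L)

  stick_to_f <- function(q) {
    f <- numeric(k)
    rem <- 1
    for (i in seq_len(k - 1L)) {
      f[i] <- rem * q[i]
      rem <- rem - f[i]
    }
    f[k] <- rem
    f
  }

  objective <- function(par) {
    D <- par[seq_len(k)]
    f <- stick_to_f(par[k + seq_len(k - 1L)])
    loss <- 0
    for (i in seq_along(lags)) {
      if (is.null(grids[[i]])) next
      pred <- jump_cdf_model(grids[[i]], lags[i] * frame_interval, D, f,
                             sigma)
      loss <- loss + sum((pred - ecdfs[[i]])^2)
    }
    loss
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  starts <- list()
  d_mid <- sqrt(lo_d * hi_d)
  for (q1 in c(0.3, 0.5, 0.7)) {
    q <- rep(q1, k - 1L)
    starts[[length(starts) + 1L]] <- c(d_mid, q)
    starts[[length(starts) + 1L]] <-
      c(pmin(pmax(d_mid * stats::runif(k, 0.5, 2), lo_d), hi_d), q)
  }
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      stats::optim(st, objective, method = "L-BFGS-B",
                   lower = c(lo_d, rep(1e-6, k - 1L)),
                   upper = c(hi_d, rep(1 - 1e-6, k - 1L))),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) stop("jump-mixture fit failed from every start")
  D <- best$par[seq_len(k)]
  f <- stick_to_f(best$par[k + seq_len(k - 1L)])
  ord <- order(D)
  D <- D[ord]
  f <- f[ord]
  list(D = D, f = f, F_bound = f[1], loss = best$value, n_disp = n_disp,
       d_bounds = d_bounds[ord])
}
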