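#' Fraction bound from EMSA band intensities
#'
#' The background is subtracted from the shifted (bound) and unshifted
#' (unbound) band intensities, negatives are clipped to zero, and the
#' fraction bound is `bound / (bound + unbound)`. Rows where both corrected
#' intensities are zero are undefined and returned as `NA` with a flag.
#'
#' @param bound,unbound,background nonnegative band intensities (arbitrary
#'   units), vectorized.
#' @return tibble `fraction_bound, undefined, n_clipped_neg` (the last as an
#'   attribute-free per-row count of clipped values, 0-2).
#' @export
fraction_bound <- function(bound, unbound, background = 0) {
  stopifnot(all(bound >= 0), all(unbound >= 0), all(background >= 0))
  b <- bound - background
  u <- unbound - background
  n_clip <- (b < 0) + (u < 0)
  b <- pmax(b, 0)
  u <- pmax(u, 0)
  undef <- (b + u) == 0
  f <- ifelse(undef, NA_real_, b / (b + u))
  tibble::tibble(fraction_bound = f, undefined = undef,
                 n_clipped_neg = as.integer(n_clip))
}

#' Four-parameter log-logistic function
#'
#' `f(x) = c + (d - c) / (1 + exp(b * (log(x) - log(e))))` (the LL.4
#' convention): `c` and `d` are the lower and upper asymptotes, `e` the
#' concentration of half-maximal response (EC50), and `b` the slope —
#' negative `b` gives a response rising with concentration. At `x = 0` the
#' limit is `c` for `b < 0` and `d` for `b > 0`.
#'
#' @param x concentrations (>= 0).
#' @param b,c,d,e model parameters; `e > 0`.
#' @return response values.
#' @export
four_param_loglogistic <- function(x, b, c, d, e) {
  out <- numeric(length(x))
  zero <- x == 0
  out[zero] <- if (b < 0) c else d
  xz <- x[!zero]
  out[!zero] <- c + (d - c) / (1 + exp(b * (log(xz) - log(e))))
  out
}

#' Fit a four-parameter log-logistic binding curve
#'
#' Bound-constrained nonlinear least squares (Levenberg-Marquardt) of the
#' LL.4 model to fraction-bound vs concentration data. Starting values come
#' from the data: `c`/`d` from the extreme responses, `e` from the
#' concentration nearest the half-maximal response, and both slope signs
#' are tried; the best residual sum of squares wins. EC50 is the fitted `e`.
#'
#' @param conc concentrations in nM (zeros allowed; handled by the model's
#'   limit).
#' @param fraction measured responses (fraction bound).
#' @return list `b, c, d, e, ec50, rss, n` with `c <= d` guaranteed by
#'   orientation handling.
#' @export
fit_4pl <- function(conc, fraction) {
  stopifnot(length(conc) == length(fraction), all(conc >= 0))
  ok <- !is.na(fraction)
  conc <- conc[ok]
  fraction <- fraction[ok]
  n_distinct <- length(unique(conc))
  if (n_distinct < 4L) stop("need at least 4 distinct concentrations")
  if (n_distinct < 5L) {
    warning("fewer than 5 distinct concentrations; fit may be unstable")
  }
  c0 <- min(fraction)
  d0 <- max(fraction)
  if (d0 - c0 < 1e-12) stop("response has no dynamic range")
  half <- (c0 + d0) / 2
  pos <- conc[conc > 0]
  e0 <- if (length(pos)) pos[which.min(abs(fraction[conc > 0] - half))]
        else stop("need at least one positive concentration")
  e0 <- max(e0, min(pos))

  dat <- data.frame(x = conc, y = fraction)
  best <- NULL
  for (b0 in c(-1, 1)) {
    for (e_try in unique(c(e0, stats::median(pos)))) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ four_param_loglogistic(x, b, cc, d, e),
          data = dat,
          start = list(b = b0, cc = c0, d = d0, e = e_try),
          lower = c(-Inf, -Inf, -Inf, 1e-12),
          control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::residuals(fit)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = fit,
                                                          rss = rss)
      }
    }
  }
  if (is.null(best)) stop("4PL fit failed to converge from every start")
  cf <- stats::coef(best$fit)
  b <- cf[["b"]]; cc <- cf[["cc"]]; d <- cf[["d"]]; e <- cf[["e"]]
  if (cc > d) {
    # reparameterize to the equivalent orientation with c <= d
    tmp <- cc; cc <- d; d <- tmp; b <- -b
  }
  list(b = b, c = cc, d = d, e = e, ec50 = e, rss = best$rss,
       n = length(conc))
}

#' Fit titration replicates and summarize EC50 per group
#'
#' Fits one 4PL curve per `(group, replicate)` and reports the mean and
#' sample standard deviation of the per-replicate EC50 values per group,
#' following the convention of fitting each replicate experiment separately
#' and averaging the resulting EC50 estimates.
#'
#' @param data tibble with columns `conc_nM`, `fraction_bound`,
#'   `replicate`, and optionally a grouping column.
#' @param group name of the grouping column, or `NULL` for a single group.
#' @return list with `fits` (tibble `group, replicate, b, c, d, ec50,
#'   rss`) and `summary` (tibble `group, n, ec50_mean, ec50_sd`).
#' @export
ec50_summary <- function(data, group = NULL) {
  stopifnot(all(c("conc_nM", "fraction_bound", "replicate") %in%
                  names(data)))
  data$group <- if (is.null(group)) "all" else as.character(data[[group]])
  keys <- unique(data[, c("group", "replicate")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- data[data$group == keys$group[i] &
                  data$replicate == keys$replicate[i], ]
    ft <- fit_4pl(sub$conc_nM, sub$fraction_bound)
    tibble::tibble(group = keys$group[i], replicate = keys$replicate[i],
                   b = ft$b, c = ft$c, d = ft$d, ec50 = ft$ec50,
                   rss = ft$rss)
  })
  fits <- dplyr::bind_rows(rows)
  summary <- fits |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), ec50_mean = mean(.data$ec50),
                     ec50_sd = stats::sd(.data$ec50), .groups = "drop")
  list(fits = fits, summary = summary)
}
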