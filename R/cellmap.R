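#' Construct a cell outline from a binary mask or polygon
#'
#' @param mask logical/0-1 matrix (rows = y, columns = x) marking the cell's
#'   pixels, or `NULL` if `polygon` is given.
#' @param pixel_size pixel edge length in micrometers.
#' @param polygon optional 2-column matrix of boundary vertices in
#'   micrometers (x, y); used instead of a mask.
#' @param cell_id identifier.
#' @return object of class `cell_outline` holding the point set in
#'   micrometers.
#' @export
cell_outline <- function(mask = NULL, pixel_size = 0.1, polygon = NULL,
                         cell_id = "cell") {
  if (is.null(mask) == is.null(polygon)) {
    stop("supply exactly one of `mask` or `polygon`")
  }
  if (!is.null(mask)) {
    stopifnot(is.matrix(mask))
    idx <- which(mask != 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("mask is empty")
    # pixel centers: column -> x, row -> y
    pts <- cbind(x = (idx[, 2] - 0.5) * pixel_size,
                 y = (idx[, 1] - 0.5) * pixel_size)
  } else {
    pts <- cbind(x = polygon[, 1], y = polygon[, 2])
    if (nrow(pts) < 3L) stop("polygon needs at least 3 vertices")
  }
  structure(list(cell_id = cell_id, points = pts, pixel_size = pixel_size,
                 from_mask = !is.null(mask)),
            class = "cell_outline")
}

#' Cell long/short axes from Feret properties
#'
#' The long axis is the direction of the maximum Feret diameter (largest
#' pairwise distance between outline points, computed on the convex hull);
#' the short axis length is the maximal extent perpendicular to it. For mask
#' input, half a pixel is added at each end so lengths measure the outer
#' pixel edges rather than pixel centers.
#'
#' @param outline a [cell_outline()].
#' @return list with `centroid` (x, y in um), `long_axis` (unit vector),
#'   `long_length`, `short_length` (um).
#' @export
cell_axes <- function(outline) {
  stopifnot(inherits(outline, "cell_outline"))
  pts <- outline$points
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  if (nrow(hp) < 2L) stop("degenerate outline: fewer than 2 hull points")
  d2 <- as.matrix(stats::dist(hp))
  dmax <- max(d2)
  if (dmax == 0) stop("degenerate outline: all points coincide")
  mx <- which(d2 == dmax, arr.ind = TRUE)[1, ]
  p1 <- hp[mx[1], ]
  p2 <- hp[mx[2], ]
  ref <- (p2 - p1) / dmax
  # the diameter is flat in the angle near its maximum, so for rasterized
  # outlines the single best pair is angularly noisy; averaging all
  # near-maximal antipodal directions cancels the quantization error
  tol <- if (outline$from_mask) outline$pixel_size else 1e-9
  near <- which(d2 >= dmax - tol & upper.tri(d2), arr.ind = TRUE)
  dirs <- (hp[near[, 2], , drop = FALSE] - hp[near[, 1], , drop = FALSE]) /
    d2[near]
  flip <- dirs %*% ref < 0
  dirs[flip, ] <- -dirs[flip, ]
  axis <- colMeans(dirs)
  axis <- axis / sqrt(sum(axis^2))
  # deterministic orientation: positive x (break ties toward positive y)
  if (axis[1] < 0 || (axis[1] == 0 && axis[2] < 0)) axis <- -axis
  perp <- c(-axis[2], axis[1])
  proj_l <- pts %*% axis
  proj_s <- pts %*% perp
  pad <- if (outline$from_mask) outline$pixel_size else 0
  long_length <- max(dmax, diff(range(proj_l))) + pad
  short_length <- diff(range(proj_s)) + pad
  if (short_length <= 0) stop("degenerate outline: zero short-axis extent")
  centroid <- unname(colMeans(pts))
  list(centroid = centroid, long_axis = as.numeric(axis),
       long_length = as.numeric(long_length),
       short_length = as.numeric(short_length))
}

#' Project localizations into normalized cell coordinates
#'
#' `u = 2 * ((r - centroid) . long_axis) / long_length` and analogously `v`
#' with the perpendicular axis and the short length, so that the cell poles
#' map to `u = +/-1` and the lateral walls to `v = +/-1`. Points that fall
#' outside `[-1, 1]` (localization vs segmentation jitter) are clipped and
#' counted.
#'
#' @param locs data frame with `x_um`, `y_um`.
#' @param axes output of [cell_axes()].
#' @return tibble `u, v` with attribute `n_clipped`.
#' @export
normalize_localizations <- function(locs, axes) {
  dx <- locs$x_um - axes$centroid[1]
  dy <- locs$y_um - axes$centroid[2]
  ax <- axes$long_axis
  perp <- c(-ax[2], ax[1])
  u <- 2 * (dx * ax[1] + dy * ax[2]) / axes$long_length
  v <- 2 * (dx * perp[1] + dy * perp[2]) / axes$short_length
  n_clipped <- sum(abs(u) > 1 | abs(v) > 1)
  out <- tibble::tibble(u = pmin(pmax(u, -1), 1), v = pmin(pmax(v, -1), 1))
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Symmetrize normalized positions about both cell axes
#'
#' Rod-shaped cells are assumed mirror-symmetric about their long and short
#' axes, so each `(u, v)` is replaced by the four sign combinations
#' `(+/-u, +/-v)`; the output has exactly four times as many points.
#'
#' @param points data frame with `u`, `v`.
#' @return tibble `u, v` of length `4 * nrow(points)`.
#' @export
symmetrize <- function(points) {
  u <- points$u
  v <- points$v
  tibble::tibble(u = c(u, -u, u, -u), v = c(v, v, -v, -v))
}

#' Localization probability density map in normalized cell coordinates
#'
#' 2D histogram over `[-1, 1] x [-1, 1]` normalized to total probability 1.
#' Odd default bin counts (41 along the long axis, 21 along the short) place
#' a bin center at the origin so that the reflection symmetry of
#' symmetrized input is exact at bin level.
#'
#' @param points data frame with `u`, `v` in `[-1, 1]`.
#' @param grid_shape `c(n_u, n_v)` bin counts.
#' @return object of class `density_map`: list with `prob` (n_u x n_v
#'   matrix summing to 1), `u_breaks`, `v_breaks`, `n_points`.
#' @export
density_map <- function(points, grid_shape = c(41L, 21L)) {
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 1L))
  if (nrow(points) == 0L) stop("no points to bin")
  if (any(abs(points$u) > 1 + 1e-12) || any(abs(points$v) > 1 + 1e-12)) {
    stop("points must lie in [-1, 1]^2; normalize/clip first")
  }
  u_breaks <- seq(-1, 1, length.out = grid_shape[1] + 1L)
  v_breaks <- seq(-1, 1, length.out = grid_shape[2] + 1L)
  bu <- pmin(pmax(findInterval(points$u, u_breaks, rightmost.closed = TRUE),
                  1L), grid_shape[1])
  bv <- pmin(pmax(findInterval(points$v, v_breaks, rightmost.closed = TRUE),
                  1L), grid_shape[2])
  counts <- matrix(0, grid_shape[1], grid_shape[2])
  tab <- table(factor(bu, levels = seq_len(grid_shape[1])),
               factor(bv, levels = seq_len(grid_shape[2])))
  counts[] <- as.numeric(tab)
  structure(list(prob = counts / sum(counts), u_breaks = u_breaks,
                 v_breaks = v_breaks, n_points = nrow(points)),
            class = "density_map")
}

#' Pearson correlation between two density maps
#'
#' Computed over the flattened bin probabilities; invariant to positive
#' rescaling of either map, so sum-to-1 and max normalizations give the
#' same value.
#'
#' @param a,b `density_map` objects on identical grids.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
heatmap_correlation <- function(a, b) {
  stopifnot(inherits(a, "density_map"), inherits(b, "density_map"))
  if (!identical(dim(a$prob), dim(b$prob))) {
    stop("density maps must share an identical grid shape")
  }
  va <- as.vector(a$prob)
  vb <- as.vector(b$prob)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("correlation undefined: a map has zero variance across bins")
  }
  stats::cor(va, vb)
}
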