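#' Link localizations into trajectories by optimal assignment
#'
#' Connects per-frame single-molecule localizations into trajectories with
#' frame-to-frame minimum-cost bipartite assignment (the Hungarian
#' algorithm), independently within each cell. The cost of linking a track
#' end to a next-frame localization is the Euclidean distance; the cost
#' matrix is augmented with birth/death entries equal to `max_displacement`,
#' making the gate the exact indifference point between extending a track
#' and terminating it. Links farther than the gate are forbidden. There is
#' no gap closing: a track whose cell has no acceptable localization in the
#' immediately following frame terminates.
#'
#' Rows are sorted by `(cell_id, frame, x_um, y_um)` before linking, so the
#' result is invariant to input row order; equal-cost ties resolve
#' deterministically in that order.
#'
#' @param locs data frame with columns `cell_id, frame, x_um, y_um`.
#' @param max_displacement linking gate in micrometers per frame. Default
#'   0.8 um (about 5 camera pixels at ~0.16 um/px).
#' @param frame_interval frame interval in seconds, recorded in the output
#'   metadata.
#' @return tibble `cell_id, track_id, frame, x_um, y_um, singleton` with one
#'   row per input localization; `singleton` flags length-1 tracks.
#'   Attributes `max_displacement` and `frame_interval` record the linking
#'   parameters.
#' @export
link_localizations <- function(locs, max_displacement = 0.8,
                               frame_interval = 0.04) {
  stopifnot(max_displacement > 0, frame_interval > 0)
  req <- c("cell_id", "frame", "x_um", "y_um")
  if (!all(req %in% names(locs))) {
    stop("`locs` must have columns ", paste(req, collapse = ", "))
  }
  if (!all(is.finite(locs$x_um)) || !all(is.finite(locs$y_um))) {
    stop("localization coordinates must be finite")
  }
  dup <- duplicated(locs[, req]) | duplicated(locs[, req], fromLast = TRUE)
  if (any(dup)) {
    stop("duplicate (cell, frame, x, y) rows: ",
         paste(which(dup), collapse = ", "))
  }

  locs <- tibble::as_tibble(locs)[order(locs$cell_id, locs$frame,
                                        locs$x_um, locs$y_um), ]
  BIG <- 4 * max_displacement + 1e3   # finite stand-in for a forbidden link

  out <- vector("list", 0L)
  track_counter <- 0L
  for (cell in unique(locs$cell_id)) {
    cl <- locs[locs$cell_id == cell, ]
    frames <- sort(unique(cl$frame))
    # active track ends: list of (track_id, x, y) from the previous frame
    active <- NULL
    assigned_track <- integer(nrow(cl))
    row_idx_by_frame <- split(seq_len(nrow(cl)), cl$frame)
    prev_frame <- NULL
    for (fr in frames) {
      idx <- row_idx_by_frame[[as.character(fr)]]
      xs <- cl$x_um[idx]
      ys <- cl$y_um[idx]
      m <- length(idx)
      carried <- !is.null(prev_frame) && fr == prev_frame + 1L &&
        !is.null(active) && nrow(active) > 0L
      if (!carried) {
        # all previous tracks terminate; every localization starts a track
        new_ids <- track_counter + seq_len(m)
        track_counter <- track_counter + m
        assigned_track[idx] <- new_ids
        active <- data.frame(track = new_ids, x = xs, y = ys)
      } else {
        n <- nrow(active)
        sz <- n + m
        cost <- matrix(0, sz, sz)
        d <- sqrt(outer(active$x, xs, "-")^2 + outer(active$y, ys, "-")^2)
        d[d > max_displacement] <- BIG
        cost[seq_len(n), seq_len(m)] <- d
        death <- matrix(BIG, n, n)
        diag(death) <- max_displacement
        cost[seq_len(n), m + seq_len(n)] <- death
        birth <- matrix(BIG, m, m)
        diag(birth) <- max_displacement
        cost[n + seq_len(m), seq_len(m)] <- birth
        # bottom-right block stays 0 (dummy-dummy pairings are free)
        a <- solve_assignment(cost)
        new_active_track <- integer(m)
        for (j in seq_len(m)) {
          i <- which(a == j)
          if (i <= n && d[i, j] <= max_displacement) {
            new_active_track[j] <- active$track[i]      # link
          } else {
            track_counter <- track_counter + 1L          # birth
            new_active_track[j] <- track_counter
          }
        }
        assigned_track[idx] <- new_active_track
        active <- data.frame(track = new_active_track, x = xs, y = ys)
      }
      prev_frame <- fr
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      cell_id = cl$cell_id, track_id = assigned_track,
      frame = cl$frame, x_um = cl$x_um, y_um = cl$y_um
    )
  }
  res <- dplyr::bind_rows(out)
  res$track_id <- sprintf("track%05d", res$track_id)
  len <- table(res$track_id)
  res$singleton <- as.vector(len[res$track_id] == 1L)
  res <- res[order(res$cell_id, res$track_id, res$frame), ]
  attr(res, "max_displacement") <- max_displacement
  attr(res, "frame_interval") <- frame_interval
  res
}

#' Split a linked localization table into trajectories
#'
#' @param tracks output of [link_localizations()] (or a simulator
#'   localization table, which already carries track ids).
#' @param min_length drop tracks shorter than this many localizations
#'   (default 2: singletons carry no displacement information).
#' @return named list of tibbles, one per trajectory, ordered by frame.
#' @export
split_trajectories <- function(tracks, min_length = 2L) {
  stopifnot(all(c("track_id", "frame", "x_um", "y_um") %in% names(tracks)))
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  parts <- split(tibble::as_tibble(tracks), tracks$track_id)
  parts[vapply(parts, nrow, integer(1)) >= min_length]
}
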