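#' Solve the linear assignment problem
#'
#' Minimum-cost perfect matching on a square cost matrix via the
#' shortest-augmenting-path (Jonker-Volgenant style) algorithm with dual
#' potentials, O(n^3). Used internally by [link_localizations()] to realize
#' Hungarian-algorithm trajectory linking; exported because an exact
#' assignment solver is broadly useful.
#'
#' @param cost square numeric matrix of finite costs (use a large finite
#'   penalty, not `Inf`, for forbidden pairings).
#' @return integer vector `a` of length `nrow(cost)`; row `i` is assigned to
#'   column `a[i]`. The assignment minimizes `sum(cost[cbind(seq_len(n), a)])`.
#' @examples
#' m <- rbind(c(1, 2), c(2, 4))
#' solve_assignment(m)  # 2, 1 is not optimal here; expect 1, 2
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost) || nrow(cost) != ncol(cost)) {
    stop("`cost` must be a square matrix")
  }
  if (!all(is.finite(cost))) {
    stop("`cost` must be finite; encode forbidden pairs as a large penalty")
  }
  n <- nrow(cost)
  if (n == 0L) return(integer(0))
  # index 1 plays the role of the virtual column 0; real columns are 2..n+1
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j]: row currently matched to column j-1 (0 = free)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 1L] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) {
          u[p[j] + 1L] <- u[p[j] + 1L] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assignment <- integer(n)
  for (j in 2:(n + 1)) assignment[p[j]] <- j - 1L
  assignment
}
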