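#' Zone occupancy and position heatmap for a trajectory
#'
#' Classifies every in-window frame's body-center position into the corner /
#' wall / center zones of the arena grid and aggregates to time fractions,
#' plus a dwell-time heatmap over the grid cells (normalized to sum 1).
#'
#' @param traj An `of_trajectory`.
#' @param window Numeric length-2 in seconds; default full session.
#' @return An `occupancy_result`: list with `fractions` (named numeric,
#'   corner/wall/center, summing to 1) and `heatmap` (n x n matrix, `[i, j]`
#'   = x cell i from the left, y cell j from the bottom).
#' @export
zone_occupancy <- function(traj, window = NULL) {
  if (is.null(window)) window <- c(0, duration_s(traj))
  f <- traj$frames
  sel <- f$t >= window[1] - 1e-9 & f$t < window[2] - 1e-9
  if (!any(sel)) stop("no frames inside window", call. = FALSE)
  arena <- traj$arena
  x <- f$center_x[sel]; y <- f$center_y[sel]
  zones <- assign_zone(x, y, arena)
  fr <- c(corner = 0, wall = 0, center = 0)
  tab <- table(zones) / length(zones)
  fr[names(tab)] <- as.numeric(tab)
  n <- arena$n_cells_side
  ix <- pmin(floor(x / arena$grid_cell), n - 1L) + 1L
  iy <- pmin(floor(y / arena$grid_cell), n - 1L) + 1L
  hm <- matrix(0, n, n)
  counts <- table(factor(ix, levels = 1:n), factor(iy, levels = 1:n))
  hm[] <- as.numeric(counts) / length(x)
  structure(list(fractions = fr, heatmap = hm, window = window),
            class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("<occupancy_result> corner %.3f | wall %.3f | center %.3f over [%g, %g) s\n",
              x$fractions[["corner"]], x$fractions[["wall"]],
              x$fractions[["center"]], x$window[1], x$window[2]))
  invisible(x)
}
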