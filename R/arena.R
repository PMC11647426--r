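#' Arena geometry for a single open-field quadrant
#'
#' The arena is one quadrant of the open-field platform, treated as an
#' independent square enclosure.  The default is a 50 x 50 cm floor with
#' 35 cm walls, decomposed for zone analysis into a 5 x 5 grid of
#' 10 x 10 cm cells.
#'
#' @param side_length Side of the square floor, in cm.
#' @param grid_cell Side of one grid cell, in cm.  `side_length` must be an
#'   integer multiple of `grid_cell`.
#' @param wall_height Wall height in cm (informational only).
#' @return An object of class `arena_geometry`.
#' @examples
#' arena_geometry()            # 50 cm arena, 25 cells
#' arena_geometry(40, 10)      # 4 x 4 grid
#' @export
arena_geometry <- function(side_length = 50, grid_cell = 10, wall_height = 35) {
  stopifnot(is.numeric(side_length), length(side_length) == 1L, side_length > 0,
            is.numeric(grid_cell), length(grid_cell) == 1L, grid_cell > 0)
  n <- side_length / grid_cell
  if (abs(n - round(n)) > 1e-9)
    stop("side_length (", side_length, ") must be an integer multiple of grid_cell (",
         grid_cell, ")", call. = FALSE)
  structure(
    list(side_length = side_length, grid_cell = grid_cell,
         wall_height = wall_height, n_cells_side = as.integer(round(n))),
    class = "arena_geometry")
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat(sprintf("<arena_geometry> %g x %g cm, %d x %d grid of %g cm cells\n",
              x$side_length, x$side_length, x$n_cells_side, x$n_cells_side,
              x$grid_cell))
  invisible(x)
}

#' Zone labels for every grid cell of an arena
#'
#' Classifies the cells of the arena grid into the three canonical
#' open-field zones: the 4 `corner` cells, the 12 `wall` cells centrally
#' located along the sides, and the 9 `center` cells (counts for the default
#' 5 x 5 grid).
#'
#' @param arena An [arena_geometry()].
#' @return A matrix of zone labels (`"corner"`, `"wall"`, `"center"`), with
#'   `[i, j]` addressing column i (x index, from the left) and row j (y index,
#'   from the bottom).
#' @export
zone_map <- function(arena = arena_geometry()) {
  n <- arena$n_cells_side
  if (n < 3) stop("zone decomposition needs at least a 3 x 3 grid", call. = FALSE)
  ix <- matrix(rep(seq_len(n) - 1L, n), n, n)          # x index, 0-based
  iy <- t(ix)                                          # y index, 0-based
  edge_x <- ix == 0L | ix == n - 1L
  edge_y <- iy == 0L | iy == n - 1L
  z <- matrix("center", n, n)
  z[edge_x | edge_y] <- "wall"
  z[edge_x & edge_y] <- "corner"
  z
}

#' Assign an in-arena point to its zone
#'
#' Cell membership uses half-open intervals `[k*cell, (k+1)*cell)` except at
#' the arena's far edges, where the boundary is closed, so every in-arena
#' point belongs to exactly one cell.
#'
#' @param x,y Coordinates in cm.  Vectorized.
#' @param arena An [arena_geometry()].
#' @return Character vector of zone labels.
#' @examples
#' assign_zone(5, 5)    # "corner"
#' assign_zone(25, 25)  # "center"
#' assign_zone(5, 25)   # "wall"
#' @export
assign_zone <- function(x, y, arena = arena_geometry()) {
  side <- arena$side_length
  if (any(x < 0 | x > side | y < 0 | y > side, na.rm = TRUE))
    stop("point outside arena [0, ", side, "]", call. = FALSE)
  n <- arena$n_cells_side
  ix <- pmin(floor(x / arena$grid_cell), n - 1L)
  iy <- pmin(floor(y / arena$grid_cell), n - 1L)
  edge_x <- ix == 0L | ix == n - 1L
  edge_y <- iy == 0L | iy == n - 1L
  out <- rep("center", length(x))
  out[edge_x | edge_y] <- "wall"
  out[edge_x & edge_y] <- "corner"
  out
}
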