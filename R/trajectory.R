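FRAME_COLS <- c("t", "head_x", "head_y", "center_x", "center_y",
                "tail_x", "tail_y")

#' Construct and validate a tracked trajectory
#'
#' A trajectory holds the per-frame head / body-center / tail positions of one
#' animal over one session, on a uniform time grid starting at injection
#' (t = 0 s).  Validation enforces uniform frame spacing, in-arena
#' coordinates, and the 90-minute maximum session length.
#'
#' @param frames `data.frame` with columns
#'   `t, head_x, head_y, center_x, center_y, tail_x, tail_y` (t in seconds,
#'   coordinates in cm).
#' @param dt Frame interval in seconds; inferred from the first gap when `NULL`.
#' @param arena An [arena_geometry()].
#' @param meta A [session_metadata()].
#' @return Object of class `of_trajectory`.
#' @export
trajectory <- function(frames, dt = NULL, arena = arena_geometry(),
                       meta = session_metadata("unknown")) {
  frames <- as.data.frame(frames)
  missing_cols <- setdiff(FRAME_COLS, names(frames))
  if (length(missing_cols))
    stop("trajectory format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  frames <- frames[FRAME_COLS]
  n <- nrow(frames)
  if (n < 1L) stop("trajectory must contain at least one frame", call. = FALSE)
  if (any(!is.finite(as.matrix(frames))))
    stop("trajectory contains non-finite values", call. = FALSE)
  t <- frames$t
  if (t[1] < 0) stop("validation error: t must be >= 0", call. = FALSE)
  if (n > 1L) {
    gaps <- diff(t)
    if (any(gaps <= 0))
      stop("validation error: timestamps must be strictly increasing (first violation at frame ",
           which(gaps <= 0)[1] + 1L, ")", call. = FALSE)
    if (is.null(dt)) dt <- gaps[1]
    if (any(abs(gaps - dt) > 1e-6))
      stop("validation error: non-uniform frame spacing (expected dt = ", dt,
           " s, first violation at frame ", which(abs(gaps - dt) > 1e-6)[1] + 1L,
           "); trajectories are not resampled", call. = FALSE)
  } else if (is.null(dt)) {
    stop("dt must be supplied for a single-frame trajectory", call. = FALSE)
  }
  if (t[n] + dt > 90 * 60 + 1e-6)
    stop("validation error: session exceeds 90 minutes", call. = FALSE)
  side <- arena$side_length
  coords <- as.matrix(frames[, setdiff(FRAME_COLS, "t")])
  bad <- which(coords < -1e-9 | coords > side + 1e-9, arr.ind = TRUE)
  if (nrow(bad))
    stop("validation error: coordinate outside arena at frame ", bad[1, 1],
         " (column ", colnames(coords)[bad[1, 2]], ")", call. = FALSE)
  structure(list(frames = frames, dt = dt, arena = arena, meta = meta),
            class = "of_trajectory")
}

#' @export
print.of_trajectory <- function(x, ...) {
  n <- nrow(x$frames)
  cat(sprintf("<of_trajectory> %d frames @ dt = %.4g s (%.1f min), animal %s, %s %g mg/kg\n",
              n, x$dt, n * x$dt / 60, x$meta$animal_id, x$meta$drug, x$meta$dose))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An `of_trajectory`.
#' @export
n_frames <- function(traj) nrow(traj$frames)

#' Session duration in seconds
#'
#' Each frame represents one `dt` interval, so a trajectory of n frames
#' starting at t = 0 covers `[0, n * dt)`.
#' @param traj An `of_trajectory`.
#' @export
duration_s <- function(traj) n_frames(traj) * traj$dt

#' Read a trajectory from its CSV representation
#'
#' The file dialect is a plain CSV with header
#' `t,head_x,head_y,center_x,center_y,tail_x,tail_y`, preceded by
#' `#`-prefixed `key=value` metadata lines carrying the [session_metadata()]
#' and arena geometry.  Non-uniform timestamps are rejected, not resampled.
#'
#' @param path Path to a trajectory CSV written by [write_trajectory()].
#' @return An `of_trajectory`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such trajectory file: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 64L)
  meta_lines <- grep("^#", head_lines, value = TRUE)
  kv <- list()
  for (ln in meta_lines) {
    ln <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq > 0)
      kv[[substr(ln, 1, eq - 1)]] <- substr(ln, eq + 1, nchar(ln))
  }
  required <- c("animal_id", "drug", "dose", "test_round", "quadrant", "sex", "slot")
  if (!all(required %in% names(kv)))
    stop("format error: metadata header incomplete in ", path,
         " (need ", paste(setdiff(required, names(kv)), collapse = ", "), ")",
         call. = FALSE)
  meta <- meta_from_list(kv)
  arena <- arena_geometry(
    side_length = if (is.null(kv$side_length)) 50 else as.numeric(kv$side_length),
    grid_cell = if (is.null(kv$grid_cell)) 10 else as.numeric(kv$grid_cell))
  dat <- data.table::fread(path, skip = length(meta_lines), header = TRUE,
                           data.table = FALSE)
  trajectory(dat, dt = if (is.null(kv$dt)) NULL else as.numeric(kv$dt),
             arena = arena, meta = meta)
}

#' Write a trajectory to CSV
#'
#' Emits the dialect accepted by [read_trajectory()].  Coordinates and
#' timestamps are written with 6 decimal places, so a read/write round trip
#' is lossless at that precision.
#'
#' @param traj An `of_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "of_trajectory"))
  if (nrow(traj$frames) == 0L)
    stop("refusing to write a trajectory with zero frames", call. = FALSE)
  m <- traj$meta
  hdr <- c(
    sprintf("# animal_id=%s", m$animal_id),
    sprintf("# sex=%s", m$sex),
    sprintf("# drug=%s", m$drug),
    sprintf("# dose=%.6g", m$dose),
    sprintf("# test_round=%d", m$test_round),
    sprintf("# quadrant=%d", m$quadrant),
    sprintf("# slot=%s", m$slot),
    sprintf("# dt=%.10g", traj$dt),
    sprintf("# side_length=%.6g", traj$arena$side_length),
    sprintf("# grid_cell=%.6g", traj$arena$grid_cell))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(FRAME_COLS, collapse = ","), con)
  fmt <- do.call(sprintf, c(list(paste(rep("%.6f", 7), collapse = ",")),
                            unname(as.list(traj$frames))))
  writeLines(fmt, con)
  invisible(path)
}

#' Frame-to-frame speed of a tracked point
#'
#' @param traj An `of_trajectory` with at least two frames.
#' @param point Which tracked point to use: `"center"` (default), `"head"`,
#'   or `"tail"`.
#' @return Numeric vector of length `n_frames - 1`, in cm/s; element i is the
#'   Euclidean displacement between frames i and i + 1 divided by `dt`.
#' @export
frame_speeds <- function(traj, point = c("center", "head", "tail")) {
  point <- match.arg(point)
  n <- n_frames(traj)
  if (n < 2L) stop("frame_speeds requires at least two frames", call. = FALSE)
  x <- traj$frames[[paste0(point, "_x")]]
  y <- traj$frames[[paste0(point, "_y")]]
  sqrt(diff(x)^2 + diff(y)^2) / traj$dt
}

#' Report tracking gaps in a trajectory file
#'
#' The reader rejects non-uniform timestamps outright; this helper inspects a
#' raw file and reports where timestamp gaps deviate from the modal frame
#' interval, so dropouts can be located before deciding how to handle them.
#'
#' @param path Trajectory CSV path.
#' @return Integer vector of frame indices (row numbers of the data block)
#'   whose preceding gap deviates from the modal dt by more than 1e-6 s.
#' @export
find_tracking_gaps <- function(path) {
  head_lines <- readLines(path, n = 64L)
  n_meta <- sum(grepl("^#", head_lines))
  dat <- data.table::fread(path, skip = n_meta, header = TRUE, data.table = FALSE)
  if (nrow(dat) < 3L) return(integer(0))
  gaps <- diff(dat$t)
  dt_mode <- as.numeric(names(sort(table(round(gaps, 9)), decreasing = TRUE))[1])
  which(abs(gaps - dt_mode) > 1e-6) + 1L
}
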