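#' Episode sets
#'
#' An `episode_set` is a data.frame of disjoint, time-ordered intervals
#' `(start, end, kind)` in seconds, produced by the segmentation functions.
#' `start` is inclusive and `end` exclusive.  For immobility segmentation the
#' immobile and mobile episodes partition the session.
#'
#' @param episodes data.frame with numeric `start`, `end` and character `kind`.
#' @param session_span Numeric length-2 `[0, duration)` of the source session.
#' @return An `episode_set`.
#' @export
episode_set <- function(episodes, session_span) {
  stopifnot(all(c("start", "end", "kind") %in% names(episodes)))
  episodes <- episodes[order(episodes$start), , drop = FALSE]
  if (nrow(episodes) && any(episodes$end <= episodes$start))
    stop("episodes must have positive duration", call. = FALSE)
  for (k in unique(episodes$kind)) {
    e <- episodes[episodes$kind == k, ]
    if (nrow(e) > 1L && any(e$start[-1] < e$end[-nrow(e)] - 1e-9))
      stop("episodes of kind '", k, "' overlap", call. = FALSE)
  }
  rownames(episodes) <- NULL
  structure(episodes, session_span = session_span,
            class = c("episode_set", "data.frame"))
}

#' @export
print.episode_set <- function(x, ...) {
  cat(sprintf("<episode_set> %d episodes over [%g, %g) s: %s\n", nrow(x),
              attr(x, "session_span")[1], attr(x, "session_span")[2],
              paste(sprintf("%s %d", names(table(x$kind)), table(x$kind)),
                    collapse = ", ")))
  invisible(x)
}

# Frame-level speed of a tracked point, one value per frame: frame i carries
# the displacement from frame i-1; frame 1 copies frame 2's value.
frame_speed_series <- function(traj, point) {
  v <- frame_speeds(traj, point)
  c(v[1], v)
}

# Centered boxcar mean with truncated windows at the edges.
boxcar_smooth <- function(v, width) {
  if (width <= 1L) return(v)
  half <- width %/% 2L
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Runs of TRUE in `flag` lasting >= min_dur seconds, as (start, end) times.
runs_to_episodes <- function(flag, dt, min_dur) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths * dt >= min_dur - 1e-9)
  data.frame(start = (starts[keep] - 1L) * dt, end = ends[keep] * dt)
}

# Merge sub-threshold gaps (short runs of FALSE flanked by TRUE) into TRUE.
merge_short_gaps <- function(flag, dt, max_gap) {
  r <- rle(flag)
  k <- length(r$values)
  if (k >= 3L) {
    short <- !r$values & (r$lengths * dt < max_gap) &
      seq_len(k) > 1L & seq_len(k) < k
    r$values[short] <- TRUE
  }
  inverse.rle(r)
}

#' Segment immobility from the body-center track
#'
#' Frames whose smoothed center speed is below `v_thresh` are immobile
#' candidates; candidate runs separated by less than `merge_gap` seconds of
#' supra-threshold frames are merged (single-frame tracking flicker), and
#' maximal runs lasting at least `min_dur` seconds become immobile episodes.
#' Everything else is mobile, so the returned immobile and mobile episodes
#' partition the session.
#'
#' @param traj An `of_trajectory`.
#' @param min_dur Minimum immobility duration, s (default 2 s).
#' @param v_thresh Center speed threshold, cm/s.
#' @param smooth_win Boxcar smoothing window for the speed series, s.
#' @param merge_gap Maximum supra-threshold gap to bridge, s.
#' @return An `episode_set` with kinds `immobile` and `mobile`.
#' @export
segment_immobility <- function(traj, min_dur = 2, v_thresh = 1,
                               smooth_win = 0.5, merge_gap = 0.2) {
  if (min_dur <= 0) stop("min_dur must be > 0", call. = FALSE)
  dt <- traj$dt
  v <- boxcar_smooth(frame_speed_series(traj, "center"),
                     max(1L, round(smooth_win / dt)))
  cand <- merge_short_gaps(v < v_thresh, dt, merge_gap)
  imm <- runs_to_episodes(cand, dt, min_dur)
  span <- c(0, n_frames(traj) * dt)
  # mobile intervals are the complement of the immobile episodes
  bounds <- c(span[1], as.vector(t(imm[, c("start", "end")])), span[2])
  mob_start <- bounds[seq(1, length(bounds) - 1, by = 2)]
  mob_end <- bounds[seq(2, length(bounds), by = 2)]
  keep <- mob_end - mob_start > 1e-9
  eps <- rbind(
    if (nrow(imm)) data.frame(start = imm$start, end = imm$end, kind = "immobile"),
    if (any(keep)) data.frame(start = mob_start[keep], end = mob_end[keep],
                              kind = "mobile"))
  if (is.null(eps)) eps <- data.frame(start = numeric(0), end = numeric(0),
                                      kind = character(0))
  episode_set(eps, span)
}

#' Segment freezing within immobile episodes
#'
#' Freezing is stricter than immobility: within immobile episodes, frames
#' where the smoothed head AND tail speeds are also below `v_thresh` are
#' freezing candidates, and maximal runs of at least `min_dur` seconds become
#' freezing episodes.  Freezing time is a subset of immobile time by
#' construction.
#'
#' @param traj The same `of_trajectory` used for `immobile`.
#' @param immobile The `episode_set` from [segment_immobility()].
#' @param min_dur Minimum freezing duration, s (default 2 s).
#' @param v_thresh Head/tail speed threshold, cm/s.
#' @param smooth_win Boxcar smoothing window, s.
#' @return An `episode_set` with kind `freezing`.
#' @export
segment_freezing <- function(traj, immobile, min_dur = 2, v_thresh = 1,
                             smooth_win = 0.5) {
  if (min_dur <= 0) stop("min_dur must be > 0", call. = FALSE)
  dt <- traj$dt
  n <- n_frames(traj)
  w <- max(1L, round(smooth_win / dt))
  vh <- boxcar_smooth(frame_speed_series(traj, "head"), w)
  vt <- boxcar_smooth(frame_speed_series(traj, "tail"), w)
  in_imm <- logical(n)
  imm <- immobile[immobile$kind == "immobile", , drop = FALSE]
  t_frame <- (seq_len(n) - 1L) * dt
  for (i in seq_len(nrow(imm)))
    in_imm[t_frame >= imm$start[i] - 1e-9 & t_frame < imm$end[i] - 1e-9] <- TRUE
  cand <- in_imm & vh < v_thresh & vt < v_thresh
  frz <- runs_to_episodes(cand, dt, min_dur)
  eps <- if (nrow(frz)) data.frame(start = frz$start, end = frz$end,
                                   kind = "freezing")
         else data.frame(start = numeric(0), end = numeric(0),
                         kind = character(0))
  episode_set(eps, c(0, n * dt))
}

#' Percent of a window covered by episodes of one kind
#'
#' @param episodes An `episode_set`.
#' @param kind Episode kind to total (`"immobile"`, `"freezing"`, `"mobile"`).
#' @param window Numeric length-2 `(start, end)` in seconds; defaults to the
#'   full session span.
#' @return Percentage in `[0, 100]`.
#' @export
pct_time <- function(episodes, kind, window = attr(episodes, "session_span")) {
  if (diff(window) <= 0) stop("window duration must be > 0", call. = FALSE)
  e <- episodes[episodes$kind == kind, , drop = FALSE]
  if (!nrow(e)) return(0)
  overlap <- pmax(0, pmin(e$end, window[2]) - pmax(e$start, window[1]))
  100 * sum(overlap) / diff(window)
}

#' Number of mobile-episode onsets in a window
#'
#' Counts transitions into the mobile state whose onset falls inside
#' `window`; a session that starts mobile contributes its first episode if
#' the session start lies in the window.
#'
#' @param episodes `episode_set` from [segment_immobility()].
#' @param window Numeric length-2 `(start, end)` in seconds.
#' @return Integer count.
#' @export
mobile_episode_count <- function(episodes,
                                 window = attr(episodes, "session_span")) {
  if (diff(window) <= 0) stop("window must be non-empty", call. = FALSE)
  e <- episodes[episodes$kind == "mobile", , drop = FALSE]
  sum(e$start >= window[1] - 1e-9 & e$start < window[2] - 1e-9)
}
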