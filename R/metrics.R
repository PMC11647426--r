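#' Distance travelled by the body center
#'
#' Sums center displacements over frames in the window, after discarding
#' steps whose implied speed exceeds `filter_cap` (one-frame tracking
#' jitter, same rationale as the maximum-speed filter).
#'
#' @param traj An `of_trajectory` with at least two frames.
#' @param window Numeric length-2 `(start, end)` in seconds; default full
#'   session.  A step between frames i and i+1 belongs to the window if the
#'   later frame's timestamp does.
#' @param filter_cap Speed cap in cm/s (default 80 = 0.8 m/s).
#' @return Distance in cm.
#' @export
distance_travelled <- function(traj, window = NULL, filter_cap = 80) {
  n <- n_frames(traj)
  if (n < 2L) stop("distance requires at least two frames", call. = FALSE)
  if (is.null(window)) window <- c(0, duration_s(traj))
  dx <- diff(traj$frames$center_x)
  dy <- diff(traj$frames$center_y)
  step <- sqrt(dx^2 + dy^2)
  t_later <- traj$frames$t[-1]
  keep <- t_later >= window[1] - 1e-9 & t_later < window[2] - 1e-9 &
    step / traj$dt <= filter_cap
  sum(step[keep])
}

#' Count full-body rotations from the body-axis heading
#'
#' The heading is the angle of the tail-to-head axis.  Per-frame heading
#' changes (wrapped to `(-pi, pi]`) feed a signed accumulator; every time it
#' reaches +/-360 degrees one rotation of that sign is recorded and the
#' accumulator is ratcheted back.  Counter-clockwise is the positive
#' mathematical direction.  Frames whose body axis is shorter than
#' `min_body_length` are skipped and reported in `n_degenerate`.
#'
#' @param traj An `of_trajectory`.
#' @param window Numeric length-2 in seconds; default full session.
#' @param min_body_length Minimum head-tail distance (cm) for a usable axis.
#' @return List with `cw`, `ccw`, `total`, and `n_degenerate`.
#' @export
count_rotations <- function(traj, window = NULL, min_body_length = 1) {
  if (is.null(window)) window <- c(0, duration_s(traj))
  f <- traj$frames
  sel <- f$t >= window[1] - 1e-9 & f$t < window[2] - 1e-9
  if (sum(sel) < 2L) stop("rotation counting needs >= 2 frames in window",
                          call. = FALSE)
  dx <- f$head_x[sel] - f$tail_x[sel]
  dy <- f$head_y[sel] - f$tail_y[sel]
  ok <- sqrt(dx^2 + dy^2) >= min_body_length
  n_degenerate <- sum(!ok)
  if (n_degenerate > 0)
    warning(n_degenerate, " frame(s) with degenerate body axis skipped")
  theta <- atan2(dy[ok], dx[ok])
  if (length(theta) < 2L)
    return(list(cw = 0L, ccw = 0L, total = 0L, n_degenerate = n_degenerate))
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi)) # wrap to (-pi, pi]
  counts <- count_rotations_core(d)
  list(cw = unname(counts["cw"]), ccw = unname(counts["ccw"]),
       total = unname(counts["cw"] + counts["ccw"]),
       n_degenerate = n_degenerate)
}

#' Five-minute bin edges for a session
#' @param duration Session length in seconds.
#' @param bin_width Bin width in seconds (default 300 = 5 min).
#' @return data.frame with `bin_start`, `bin_end` (seconds).
#' @export
bin_edges <- function(duration = 90 * 60, bin_width = 300) {
  nb <- floor(duration / bin_width + 1e-9)
  starts <- (seq_len(nb) - 1) * bin_width
  if (duration > nb * bin_width + 1e-9) # trailing partial bin
    starts <- c(starts, nb * bin_width)
  data.frame(bin_start = starts, bin_end = pmin(starts + bin_width, duration))
}

#' Maximum center speed per 5-minute bin, with jitter filter
#'
#' Per bin, the maximum of the center frame speeds after discarding frames
#' faster than `filter_cap` (0.8 m/s: one-frame tracking jitter).  Bins with
#' no surviving frames are flagged missing (`NA` value).
#'
#' @param traj An `of_trajectory`.
#' @param filter_cap Discard speeds above this, cm/s.
#' @param bin_width Bin width, s.
#' @return A `bin_series` data.frame: `bin_start`, `bin_end`, `value`,
#'   `missing`, with attribute `metric = "max_speed"`.
#' @export
max_speed_binned <- function(traj, filter_cap = 80, bin_width = 300) {
  v <- frame_speeds(traj, "center")
  t_later <- traj$frames$t[-1]
  edges <- bin_edges(duration_s(traj), bin_width)
  keep <- v <= filter_cap
  idx <- findInterval(t_later, edges$bin_start)
  vals <- rep(NA_real_, nrow(edges))
  agg <- tapply(v[keep], idx[keep], max)
  vals[as.integer(names(agg))] <- agg
  bs <- data.frame(edges, value = vals, missing = is.na(vals))
  structure(bs, metric = "max_speed", class = c("bin_series", "data.frame"))
}

#' Absolute and averaged maximum speed over a window of bins
#'
#' `absolute` is the max of the in-window bin maxima; `averaged` is their
#' mean with missing (fully inactive) bins counted as 0 -- deliberately, so
#' the averaged variant is pulled down by long periods of inactivity, which
#' is what distinguishes the two readouts.
#'
#' @param bins A `bin_series` from [max_speed_binned()].
#' @param window Numeric length-2 in seconds, aligned to bin edges.
#' @return List with `absolute` and `averaged`, cm/s.
#' @export
abs_and_avg_max_speed <- function(bins, window) {
  sel <- bins$bin_start >= window[1] - 1e-9 & bins$bin_end <= window[2] + 1e-9
  if (!any(sel)) stop("no bins inside window", call. = FALSE)
  if (min(bins$bin_start[sel]) > window[1] + 1e-9 ||
      max(bins$bin_end[sel]) < window[2] - 1e-9)
    stop("window must be aligned to bin edges", call. = FALSE)
  v <- bins$value[sel]
  v0 <- ifelse(is.na(v), 0, v)
  list(absolute = max(v0), averaged = mean(v0))
}

#' All six motor metrics per 5-minute bin
#'
#' Time-based metrics (distance, % immobile, % freezing, max speed)
#' contribute each episode's overlap to every bin it spans; count-based
#' metrics (mobile episodes, freezing episodes) are attributed to the bin
#' containing the episode onset.
#'
#' @param traj An `of_trajectory`.
#' @param immobile,freezing Optional precomputed episode sets; segmented with
#'   defaults when `NULL`.
#' @param filter_cap Jitter filter cap, cm/s.
#' @param bin_width Bin width, s.
#' @return Long data.frame: `metric`, `bin_start`, `bin_end`, `value`.
#'   Metrics: `distance`, `max_speed`, `mobile_episodes`, `pct_immobile`,
#'   `freezing_episodes`, `pct_freezing`.
#' @export
bin_metrics <- function(traj, immobile = NULL, freezing = NULL,
                        filter_cap = 80, bin_width = 300) {
  if (is.null(immobile)) immobile <- segment_immobility(traj)
  if (is.null(freezing)) freezing <- segment_freezing(traj, immobile)
  edges <- bin_edges(duration_s(traj), bin_width)
  nb <- nrow(edges)
  ms <- max_speed_binned(traj, filter_cap, bin_width)
  one <- function(metric, f) data.frame(metric = metric, edges,
                                        value = vapply(seq_len(nb), f, 0))
  win <- function(i) c(edges$bin_start[i], edges$bin_end[i])
  out <- rbind(
    one("distance", function(i) distance_travelled(traj, win(i), filter_cap)),
    data.frame(metric = "max_speed", edges,
               value = ifelse(ms$missing, NA_real_, ms$value)),
    one("mobile_episodes", function(i) mobile_episode_count(immobile, win(i))),
    one("pct_immobile", function(i) pct_time(immobile, "immobile", win(i))),
    one("freezing_episodes", function(i) {
      e <- freezing[freezing$kind == "freezing", , drop = FALSE]
      sum(e$start >= edges$bin_start[i] - 1e-9 &
            e$start < edges$bin_end[i] - 1e-9)
    }),
    one("pct_freezing", function(i) pct_time(freezing, "freezing", win(i))))
  rownames(out) <- NULL
  out
}

#' Summary of all motor metrics over the timeframe of interest
#'
#' Aggregates every metric over the 10-60 min post-injection window (the
#' period of maximal drug effect), plus absolute maximum speed over the two
#' sub-windows 10-35 and 35-60 min, and the zone occupancy fractions.
#'
#' @param traj An `of_trajectory` covering the TOI.
#' @param toi Timeframe of interest `(start, end)` in seconds.
#' @param v_thresh,min_dur,smooth_win Segmentation parameters
#'   (see [segment_immobility()]).
#' @param filter_cap Jitter filter cap, cm/s.
#' @return One-row data.frame (class `toi_summary`) with columns
#'   `session_id, animal_id, drug, dose, test_round, distance_cm,
#'   rotations_total, rotations_cw, rotations_ccw, abs_max_speed,
#'   avg_max_speed, abs_max_speed_early, abs_max_speed_late,
#'   mobile_episode_count, pct_time_immobile, freezing_episode_count,
#'   pct_time_freezing, frac_corner, frac_wall, frac_center`.
#' @export
toi_summary <- function(traj, toi = c(600, 3600), v_thresh = 1, min_dur = 2,
                        smooth_win = 0.5, filter_cap = 80) {
  dur <- duration_s(traj)
  if (dur < toi[2] - 1e-9) {
    miss <- bin_edges(toi[2])
    miss <- miss[miss$bin_start >= dur - 1e-9, ]
    stop("session too short for the TOI: missing bins starting at ",
         paste(miss$bin_start / 60, collapse = ", "), " min", call. = FALSE)
  }
  immobile <- segment_immobility(traj, min_dur = min_dur, v_thresh = v_thresh,
                                 smooth_win = smooth_win)
  freezing <- segment_freezing(traj, immobile, min_dur = min_dur,
                               v_thresh = v_thresh, smooth_win = smooth_win)
  ms <- max_speed_binned(traj, filter_cap)
  sp <- abs_and_avg_max_speed(ms, toi)
  mid <- (toi[1] + toi[2]) / 2
  rot <- count_rotations(traj, toi)
  occ <- zone_occupancy(traj, toi)
  m <- traj$meta
  out <- data.frame(
    session_id = sprintf("%s_r%d", m$animal_id, m$test_round),
    animal_id = m$animal_id, drug = m$drug, dose = m$dose,
    test_round = m$test_round,
    distance_cm = distance_travelled(traj, toi, filter_cap),
    rotations_total = rot$total, rotations_cw = rot$cw,
    rotations_ccw = rot$ccw,
    abs_max_speed = sp$absolute, avg_max_speed = sp$averaged,
    abs_max_speed_early = abs_and_avg_max_speed(ms, c(toi[1], mid))$absolute,
    abs_max_speed_late = abs_and_avg_max_speed(ms, c(mid, toi[2]))$absolute,
    mobile_episode_count = mobile_episode_count(immobile, toi),
    pct_time_immobile = pct_time(immobile, "immobile", toi),
    freezing_episode_count = sum(freezing$kind == "freezing" &
                                   freezing$start >= toi[1] - 1e-9 &
                                   freezing$start < toi[2] - 1e-9),
    pct_time_freezing = pct_time(freezing, "freezing", toi),
    frac_corner = occ$fractions[["corner"]],
    frac_wall = occ$fractions[["wall"]],
    frac_center = occ$fractions[["center"]],
    stringsAsFactors = FALSE)
  class(out) <- c("toi_summary", "data.frame")
  out
}
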