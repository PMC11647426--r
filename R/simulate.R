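# Evaluate thunk with a private RNG stream seeded by `seed`; the caller's
# global RNG state is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-session seed from (master seed, animal index, round),
# kept inside the positive 32-bit integer range.
derive_seed <- function(master, animal_index, test_round) {
  x <- (as.double(master) * 2654435761 + as.double(animal_index) * 40503 +
          as.double(test_round) * 69621) %% 2147483629
  as.integer(x) + 1L
}

#' Simulate one open-field session
#'
#' Generates a full tracked trajectory from a two-state semi-Markov model:
#' immobile periods (freezes with probability `freeze_frac`, otherwise
#' stationary with head/tail wobble) alternate with mobile bouts modelled as
#' a correlated random walk with log-normal frame speeds, wrapped-normal
#' turning, corner-directed thigmotactic drift and reflecting walls.  The
#' bout initiation hazard declines within the session (habituation), across
#' rounds (`round_factor`), and under drug according to the pharmacodynamic
#' suppression `E(t, dose)` from [dose_effect()]; the within-bout speed scale
#' is suppressed by the same factor.
#'
#' @param meta A [session_metadata()]; its drug/dose/round drive the model.
#' @param pd A [pd_params()] for the session's drug, or a named list of
#'   per-drug parameter sets (as [default_pd()]); ignored for saline.
#' @param bp A [behavior_params()].
#' @param seed Integer seed; the same seed reproduces the session exactly.
#' @param dt Frame interval, s.
#' @param duration Session length, s (defaults to the full 90 min).
#' @param arena An [arena_geometry()].
#' @return An `of_trajectory`.
#' @export
simulate_session <- function(meta, pd = default_pd(), bp = behavior_params(),
                             seed = 1, dt = 1 / 30, duration = 90 * 60,
                             arena = arena_geometry()) {
  stopifnot(inherits(meta, "session_metadata"), inherits(bp, "behavior_params"))
  if (duration <= 0 || duration > 90 * 60 + 1e-9)
    stop("duration must be in (0, 90] minutes", call. = FALSE)
  if (!inherits(pd, "pd_params")) {
    if (meta$drug != "saline") {
      pd <- pd[[meta$drug]]
      if (!inherits(pd, "pd_params"))
        stop("no pd_params supplied for drug ", meta$drug, call. = FALSE)
    } else pd <- pd_params() # unused (dose 0)
  }
  n <- floor(duration / dt + 1e-9)
  t_sec <- (seq_len(n) - 1) * dt

  with_seed(seed, {
    supp <- if (meta$dose > 0) dose_effect(t_sec / 60, meta$dose, pd) else
      numeric(n)
    state <- sim_state_sequence(n, dt, meta, pd, bp)
    speed_eff <- pmax(bp$speed_scale * (1 - supp), 1e-6)
    turn_sd <- sqrt(dt / bp$heading_persistence)
    x0 <- runif(1, 0.1, arena$side_length - 0.1)
    y0 <- runif(1, 0.1, arena$side_length - 0.1)
    h0 <- runif(1, -pi, pi)
    m <- sim_walk_core(state, speed_eff, dt, arena$side_length, turn_sd,
                       bp$thigmotaxis_strength, bp$speed_sdlog,
                       bp$posture_noise, bp$body_length, x0, y0, h0)
    frames <- data.frame(t = t_sec,
                         head_x = m[, 1], head_y = m[, 2],
                         center_x = m[, 3], center_y = m[, 4],
                         tail_x = m[, 5], tail_y = m[, 6])
    trajectory(frames, dt = dt, arena = arena, meta = meta)
  })
}

# Per-frame state codes (0 immobile, 1 freeze, 2 mobile) from the alternating
# renewal process.  Immobile durations come from the time-varying bout hazard
# via thinning; mobile bout durations are exponential.
sim_state_sequence <- function(n, dt, meta, pd, bp) {
  dur <- n * dt
  h_base <- bp$bout_rate0 * bp$round_factor^(meta$test_round - 1) / 60 # per s
  hazard <- function(t_s) {
    e <- if (meta$dose > 0) dose_effect(t_s / 60, meta$dose, pd) else 0
    h_base * exp(-t_s / (bp$habituation_tau * 60)) * (1 - e)
  }
  state <- integer(n)
  t_cur <- 0
  mobile <- TRUE # animals start active after being placed in the arena
  while (t_cur < dur) {
    if (mobile) {
      d <- stats::rexp(1, rate = 1 / bp$bout_mean_dur)
      code <- 2L
    } else {
      # thinning against the constant upper bound h_base
      t_prop <- t_cur
      repeat {
        t_prop <- t_prop + stats::rexp(1, rate = h_base)
        if (t_prop >= dur || stats::runif(1) < hazard(t_prop) / h_base) break
      }
      d <- t_prop - t_cur
      code <- if (stats::runif(1) < bp$freeze_frac) 1L else 0L
    }
    i0 <- floor(t_cur / dt) + 1
    i1 <- min(ceiling((t_cur + d) / dt), n)
    if (i1 >= i0) state[i0:i1] <- code
    t_cur <- t_cur + d
    mobile <- !mobile
  }
  state
}

#' Simulate a full cohort from a design plan
#'
#' One session per row of the plan.  Per-session seeds are derived
#' deterministically from the master seed and the (animal, round) pair, so a
#' cohort regenerated with the same master seed is identical.
#'
#' @param plan A `design_plan` from [make_lattice_design()].
#' @param pd Named list of per-drug [pd_params()] (default [default_pd()]).
#' @param bp A [behavior_params()].
#' @param seed Master integer seed.
#' @param dt,duration,arena Passed to [simulate_session()].
#' @param dir Optional output directory; when given, trajectories are written
#'   as CSVs plus a `manifest.csv`, and only the manifest is returned.
#' @return If `dir` is `NULL`, a list with `trajectories` (list of
#'   `of_trajectory`) and `manifest` (data.frame); otherwise the manifest with
#'   a `path` column, invisibly.
#' @export
simulate_cohort <- function(plan, pd = default_pd(), bp = behavior_params(),
                            seed = 1, dt = 1 / 30, duration = 90 * 60,
                            arena = arena_geometry(), dir = NULL) {
  validate_design(plan)
  animal_index <- match(plan$animal_id, sort(unique(plan$animal_id)))
  manifest <- data.frame(
    session_id = sprintf("%s_r%d", plan$animal_id, plan$test_round),
    animal_id = plan$animal_id, drug = plan$drug, dose = plan$dose,
    test_round = plan$test_round, quadrant = plan$quadrant,
    slot = plan$slot,
    seed = derive_seed(seed, animal_index, plan$test_round),
    stringsAsFactors = FALSE)
  make_one <- function(i) {
    meta <- session_metadata(plan$animal_id[i], drug = plan$drug[i],
                             dose = plan$dose[i],
                             test_round = plan$test_round[i],
                             quadrant = plan$quadrant[i], slot = plan$slot[i])
    simulate_session(meta, pd = pd, bp = bp, seed = manifest$seed[i],
                     dt = dt, duration = duration, arena = arena)
  }
  if (is.null(dir)) {
    trajs <- lapply(seq_len(nrow(plan)), make_one)
    names(trajs) <- manifest$session_id
    return(list(trajectories = trajs, manifest = manifest))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest$path <- file.path(dir, paste0(manifest$session_id, ".csv"))
  for (i in seq_len(nrow(plan))) write_trajectory(make_one(i), manifest$path[i])
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
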