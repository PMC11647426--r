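# Fixture builders and independent brute-force oracles.
# The oracles re-derive every quantity from its verbal definition with plain
# loops; they deliberately share no code with the package implementations.

# Build a trajectory from center coordinates; head/tail ride along at a fixed
# offset unless given explicitly.
make_traj <- function(cx, cy, dt = 0.1, hx = pmin(cx + 1, 50), hy = cy,
                      tx = pmax(cx - 1, 0), ty = cy,
                      meta = session_metadata("fix"),
                      arena = arena_geometry()) {
  n <- length(cx)
  trajectory(data.frame(t = (seq_len(n) - 1) * dt,
                        head_x = hx, head_y = hy,
                        center_x = cx, center_y = cy,
                        tail_x = tx, tail_y = ty),
             dt = dt, arena = arena, meta = meta)
}

# A wandering synthetic trajectory with planted stationary stretches, used to
# exercise the segmenters on irregular inputs.
random_fixture_traj <- function(seed, n = 1200, dt = 0.1) {
  set.seed(seed)
  state <- integer(0)
  while (length(state) < n) {
    len <- sample(3:80, 1)
    state <- c(state, rep(sample(0:2, 1), len)) # 0 freeze 1 wobble 2 move
  }
  state <- state[1:n]
  cx <- cy <- hx <- hy <- tx <- ty <- numeric(n)
  x <- runif(1, 10, 40); y <- runif(1, 10, 40); th <- runif(1, -pi, pi)
  for (i in 1:n) {
    if (state[i] == 2L) {
      th <- th + rnorm(1, 0, 0.4)
      x <- min(max(x + cos(th) * rlnorm(1, log(1), 0.5), 0), 50)
      y <- min(max(y + sin(th) * rlnorm(1, log(1), 0.5), 0), 50)
    }
    wob <- if (state[i] == 1L) 0.4 else 0
    cx[i] <- x; cy[i] <- y
    hx[i] <- min(max(x + 2 * cos(th) + rnorm(1, 0, wob), 0), 50)
    hy[i] <- min(max(y + 2 * sin(th) + rnorm(1, 0, wob), 0), 50)
    tx[i] <- min(max(x - 2 * cos(th) + rnorm(1, 0, wob), 0), 50)
    ty[i] <- min(max(y - 2 * sin(th) + rnorm(1, 0, wob), 0), 50)
  }
  make_traj(cx, cy, dt, hx, hy, tx, ty)
}

# --- brute-force segmentation oracle -----------------------------------------

oracle_point_speed <- function(traj, point) {
  f <- traj$frames
  x <- f[[paste0(point, "_x")]]; y <- f[[paste0(point, "_y")]]
  n <- nrow(f)
  v <- numeric(n)
  for (i in 2:n) v[i] <- sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2) / traj$dt
  v[1] <- v[2]
  v
}

oracle_smooth <- function(v, dt, smooth_win) {
  w <- max(1L, round(smooth_win / dt)); half <- w %/% 2L
  n <- length(v)
  out <- numeric(n)
  for (i in 1:n) out[i] <- mean(v[max(1, i - half):min(n, i + half)])
  out
}

# Candidate flags -> episodes, scanning every run explicitly.
oracle_runs <- function(flag, dt, min_dur) {
  n <- length(flag)
  eps <- NULL
  i <- 1
  while (i <= n) {
    if (flag[i]) {
      j <- i
      while (j < n && flag[j + 1]) j <- j + 1
      if ((j - i + 1) * dt >= min_dur - 1e-9)
        eps <- rbind(eps, data.frame(start = (i - 1) * dt, end = j * dt))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(eps)) data.frame(start = numeric(0), end = numeric(0)) else eps
}

oracle_segment_immobility <- function(traj, min_dur = 2, v_thresh = 1,
                                      smooth_win = 0.5, merge_gap = 0.2) {
  dt <- traj$dt
  cand <- oracle_smooth(oracle_point_speed(traj, "center"), dt, smooth_win) < v_thresh
  n <- length(cand)
  # bridge every supra-threshold gap shorter than merge_gap between candidates
  i <- 1
  while (i <= n) {
    if (!cand[i]) {
      j <- i
      while (j < n && !cand[j + 1]) j <- j + 1
      if (i > 1 && j < n && (j - i + 1) * dt < merge_gap) cand[i:j] <- TRUE
      i <- j + 1
    } else i <- i + 1
  }
  oracle_runs(cand, dt, min_dur)
}

oracle_segment_freezing <- function(traj, imm_eps, min_dur = 2, v_thresh = 1,
                                    smooth_win = 0.5) {
  dt <- traj$dt
  n <- nrow(traj$frames)
  vh <- oracle_smooth(oracle_point_speed(traj, "head"), dt, smooth_win)
  vt <- oracle_smooth(oracle_point_speed(traj, "tail"), dt, smooth_win)
  in_imm <- logical(n)
  for (k in seq_len(nrow(imm_eps))) {
    for (i in 1:n) {
      t <- (i - 1) * dt
      if (t >= imm_eps$start[k] - 1e-9 && t < imm_eps$end[k] - 1e-9)
        in_imm[i] <- TRUE
    }
  }
  oracle_runs(in_imm & vh < v_thresh & vt < v_thresh, dt, min_dur)
}

# --- rotation oracle: plain R ratchet over raw headings ----------------------

oracle_rotations <- function(theta) {
  acc <- 0; cw <- 0L; ccw <- 0L
  for (i in 2:length(theta)) {
    d <- theta[i] - theta[i - 1]
    while (d > pi) d <- d - 2 * pi
    while (d <= -pi) d <- d + 2 * pi
    acc <- acc + d
    full <- 2 * pi - 1e-9 # same exact-turn tie-break as the implementation
    while (acc >= full) { ccw <- ccw + 1L; acc <- acc - 2 * pi }
    while (acc <= -full) { cw <- cw + 1L; acc <- acc + 2 * pi }
  }
  c(cw = cw, ccw = ccw)
}

# --- Dunnett max-|t| null oracle (independent Monte Carlo) -------------------

oracle_dunnett_p <- function(q, ns, n0, df, n_draws = 2e5, seed = 4242) {
  set.seed(seed)
  k <- length(ns)
  z0 <- rnorm(n_draws)
  mx <- rep(0, n_draws)
  for (j in 1:k) {
    lam <- sqrt(ns[j] / (ns[j] + n0))
    mx <- pmax(mx, abs(lam * z0 + sqrt(1 - lam^2) * rnorm(n_draws)))
  }
  mx <- mx / sqrt(rchisq(n_draws, df) / df)
  mean(mx >= q)
}

# Demo config used by pipeline tests: tiny cohort, short sessions, coarse dt.
demo_config <- function(seed = 7) {
  cfg <- default_config()
  cfg$seed <- seed
  cfg$session$dt <- 0.25
  cfg$session$duration_min <- 20
  cfg$design <- list(n_animals = 8, n_rounds = 1,
                     doses = list(SCH23390 = 0.5, haloperidol = 1))
  cfg$metrics$toi_min <- c(5, 15)
  cfg
}
options(parkfield.log_level = "quiet")
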