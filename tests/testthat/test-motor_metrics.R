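test_that("immobility segmentation honours the 2 s threshold", {
  dt <- 0.1
  # 5 s of walking, 10 s still, 5 s walking
  cx <- c(seq(5, 15, by = 0.2), rep(15, 100), seq(15, 25, by = 0.2))
  tr <- make_traj(cx, rep(25, length(cx)), dt = dt)
  imm <- segment_immobility(tr)
  ep <- imm[imm$kind == "immobile", ]
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$end - ep$start, 10, tolerance = 0.1) # smoothing blurs edges
  # stationary for only 1.5 s -> no episode
  cx2 <- c(seq(5, 15, by = 0.2), rep(15, 15), seq(15, 25, by = 0.2))
  imm2 <- segment_immobility(make_traj(cx2, rep(25, length(cx2)), dt = dt))
  expect_equal(nrow(imm2[imm2$kind == "immobile", ]), 0L)
  expect_error(segment_immobility(tr, min_dur = 0), "min_dur")
})

test_that("head movement separates immobility from freezing", {
  dt <- 0.1; n <- 100
  still <- rep(20, n)
  # center still, head oscillating by 5 cm: immobile yes, freezing no
  osc <- 20 + rep(c(0, 5), length.out = n)
  tr <- make_traj(still, still, dt, hx = osc, hy = still,
                  tx = still - 2, ty = still)
  imm <- segment_immobility(tr)
  expect_equal(pct_time(imm, "immobile"), 100)
  frz <- segment_freezing(tr, imm)
  expect_equal(nrow(frz), 0L)
  # everything still for the whole 10 s -> one freezing episode
  tr2 <- make_traj(still, still, dt)
  frz2 <- segment_freezing(tr2, segment_immobility(tr2))
  expect_equal(nrow(frz2), 1L)
  expect_equal(frz2$end - frz2$start, 10)
})

test_that("segmentation matches the brute-force oracle on synthetic traces", {
  for (s in 1:6) {
    tr <- random_fixture_traj(seed = 900 + s, n = 600)
    imm <- segment_immobility(tr)
    ora <- oracle_segment_immobility(tr)
    got <- imm[imm$kind == "immobile", c("start", "end")]
    expect_equal(as.matrix(got), as.matrix(ora), ignore_attr = TRUE)
    frz <- segment_freezing(tr, imm)
    ora_f <- oracle_segment_freezing(tr, ora)
    expect_equal(as.matrix(frz[, c("start", "end")]), as.matrix(ora_f),
                 ignore_attr = TRUE)
  }
})

test_that("mobile episode counting follows the onset convention", {
  # alternating 10 s mobile / 10 s immobile over 5 min = 15 mobile onsets
  dt <- 0.1
  cx <- numeric(0); x <- 5; dir <- 1
  for (k in 1:15) {
    cx <- c(cx, x + dir * seq(0.2, 20, by = 0.2)) # 10 s moving at 2 cm/s
    x <- x + dir * 20; dir <- -dir
    cx <- c(cx, rep(x, 100))                      # 10 s still
  }
  tr <- make_traj(cx, rep(25, length(cx)), dt = dt)
  imm <- segment_immobility(tr)
  expect_equal(mobile_episode_count(imm, c(0, 300)), 15L)
  # fully immobile window -> 0
  still <- make_traj(rep(9, 300), rep(9, 300), dt = dt)
  expect_equal(mobile_episode_count(segment_immobility(still)), 0L)
  expect_error(mobile_episode_count(imm, c(10, 10)), "window")
  # recount from the raw episode list agrees
  sim <- simulate_session(session_metadata("m"), seed = 77, dt = 0.2,
                          duration = 900)
  imm_s <- segment_immobility(sim)
  mob <- imm_s[imm_s$kind == "mobile", ]
  for (win in list(c(0, 900), c(100, 500))) {
    expect_equal(mobile_episode_count(imm_s, win),
                 sum(mob$start >= win[1] & mob$start < win[2]))
  }
})

test_that("rotation counting matches examples and the oracle", {
  dt <- 0.1
  # heading increasing 4 deg per step through 180 steps (720 deg) -> ccw 2
  th <- (0:180) * 4 * pi / 180
  tr <- make_traj(rep(25, 181), rep(25, 181), dt,
                  hx = 25 + 2 * cos(th), hy = 25 + 2 * sin(th),
                  tx = 25 - 2 * cos(th), ty = 25 - 2 * sin(th))
  r <- count_rotations(tr)
  expect_equal(c(r$cw, r$ccw), c(0L, 2L))
  # oscillation +/-179 deg never completes a turn
  th2 <- rep(c(0, 179 * pi / 180), 50)
  tr2 <- make_traj(rep(25, 100), rep(25, 100), dt,
                   hx = 25 + 2 * cos(th2), hy = 25 + 2 * sin(th2),
                   tx = 25 - 2 * cos(th2), ty = 25 - 2 * sin(th2))
  r2 <- count_rotations(tr2)
  expect_equal(r2$total, 0L)
  # noisy random-walk headings match the plain-R accumulator oracle
  for (s in 1:10) {
    set.seed(1300 + s)
    th3 <- cumsum(rnorm(400, 0.05, 0.6))
    tr3 <- make_traj(rep(25, 400), rep(25, 400), dt,
                     hx = 25 + 2 * cos(th3), hy = 25 + 2 * sin(th3),
                     tx = 25 - 2 * cos(th3), ty = 25 - 2 * sin(th3))
    r3 <- count_rotations(tr3)
    ora <- oracle_rotations(atan2(2 * sin(th3), 2 * cos(th3)))
    expect_identical(c(r3$cw, r3$ccw), unname(as.integer(ora)))
  }
  # degenerate body axis frames are skipped with a warning
  trd <- make_traj(rep(25, 50), rep(25, 50), dt,
                   hx = rep(25.1, 50), hy = rep(25, 50),
                   tx = rep(25, 50), ty = rep(25, 50))
  expect_warning(rd <- count_rotations(trd), "degenerate")
  expect_equal(rd$n_degenerate, 50L)
  # time reversal swaps cw and ccw
  rev_tr <- make_traj(rep(25, 181), rep(25, 181), dt,
                      hx = rev(25 + 2 * cos(th)), hy = rev(25 + 2 * sin(th)),
                      tx = rev(25 - 2 * cos(th)), ty = rev(25 - 2 * sin(th)))
  rr <- count_rotations(rev_tr)
  expect_equal(c(rr$cw, rr$ccw), c(2L, 0L))
})

test_that("max speed binning applies the 0.8 m/s jitter filter", {
  dt <- 0.1
  # speeds 30, 120, 50 cm/s -> the 120 frame is discarded, bin max 50
  cx <- c(0, 3, 15, 20, rep(20, 26))
  tr <- make_traj(cx, rep(10, 30), dt = dt)
  bins <- max_speed_binned(tr, bin_width = 3)
  expect_equal(bins$value[1], 50)
  # stationary -> all zeros
  still <- make_traj(rep(10, 100), rep(10, 100), dt = dt)
  b2 <- max_speed_binned(still, bin_width = 5)
  expect_true(all(b2$value == 0))
  # simulated sessions never exceed the cap after filtering
  for (s in 1:5) {
    sim <- simulate_session(session_metadata("v"), seed = 200 + s, dt = 0.2,
                            duration = 600)
    b <- max_speed_binned(sim)
    expect_true(all(b$value[!b$missing] <= 80))
  }
})

test_that("absolute and averaged max speed follow the bin convention", {
  bins <- structure(data.frame(bin_start = c(0, 300, 600),
                               bin_end = c(300, 600, 900),
                               value = c(10, 20, 30),
                               missing = FALSE),
                    class = c("bin_series", "data.frame"))
  r <- abs_and_avg_max_speed(bins, c(0, 900))
  expect_equal(r$absolute, 30)
  expect_equal(r$averaged, 20)
  bins$value <- c(7, 7, 7)
  r2 <- abs_and_avg_max_speed(bins, c(0, 900))
  expect_equal(r2$absolute, r2$averaged)
  # missing bins count as zero in the average (inactivity pulls it down)
  bins$value <- c(10, NA, 30); bins$missing <- c(FALSE, TRUE, FALSE)
  r3 <- abs_and_avg_max_speed(bins, c(0, 900))
  expect_equal(r3$averaged, 40 / 3)
  expect_error(abs_and_avg_max_speed(bins, c(1000, 1200)), "no bins")
  expect_error(abs_and_avg_max_speed(bins, c(100, 900)), "aligned")
  # averaged <= absolute on random inputs
  set.seed(42)
  for (k in 1:20) {
    bins$value <- runif(3, 0, 60); bins$missing <- FALSE
    rr <- abs_and_avg_max_speed(bins, c(0, 900))
    expect_lte(rr$averaged, rr$absolute)
  }
})

test_that("distance travelled matches analytic paths", {
  sq <- make_traj(c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0), dt = 1)
  expect_equal(distance_travelled(sq), 40)
  expect_equal(distance_travelled(make_traj(rep(3, 10), rep(3, 10))), 0)
  nf <- 3000; period <- 300 # 3 revolutions, 1000 frames each
  ang <- 2 * pi * 3 * (0:nf) / nf
  circ <- make_traj(25 + 10 * cos(ang), 25 + 10 * sin(ang), dt = period / nf)
  expect_equal(distance_travelled(circ), 3 * 2 * pi * 10, tolerance = 1e-3)
})

test_that("pct_time computes window overlap", {
  eps <- episode_set(data.frame(start = 30, end = 60, kind = "immobile"),
                     c(0, 300))
  expect_equal(pct_time(eps, "immobile", c(0, 300)), 10)
  expect_equal(pct_time(eps, "freezing", c(0, 300)), 0)
  expect_equal(pct_time(eps, "immobile", c(45, 300)), 100 * 15 / 255)
})

test_that("partition and threshold-monotonicity invariants hold", {
  for (s in 1:4) {
    tr <- simulate_session(session_metadata("p"), seed = 300 + s, dt = 0.2,
                           duration = 600)
    imm <- segment_immobility(tr)
    expect_equal(pct_time(imm, "immobile") + pct_time(imm, "mobile"), 100,
                 tolerance = 1e-9)
    frz <- segment_freezing(tr, imm)
    expect_lte(pct_time(frz, "freezing"), pct_time(imm, "immobile") + 1e-9)
    # lowering v_thresh never increases immobile time
    lo <- segment_immobility(tr, v_thresh = 0.5)
    expect_lte(pct_time(lo, "immobile"), pct_time(imm, "immobile") + 1e-9)
    # raising min_dur never increases episode count
    hi <- segment_immobility(tr, min_dur = 5)
    expect_lte(sum(hi$kind == "immobile"), sum(imm$kind == "immobile"))
    # removing the speed filter can only increase reported maxima
    b80 <- max_speed_binned(tr, filter_cap = 80)
    binf <- max_speed_binned(tr, filter_cap = Inf)
    ok <- !b80$missing
    expect_true(all(binf$value[ok] >= b80$value[ok]))
  }
})

test_that("toi_summary aggregates consistently with the bin series", {
  tr <- simulate_session(session_metadata("t", drug = "haloperidol",
                                          dose = 0.5),
                         seed = 404, dt = 0.25, duration = 5400)
  s <- toi_summary(tr)
  expect_s3_class(s, "toi_summary")
  bm <- bin_metrics(tr)
  toi_bins <- bm$bin_start >= 600 & bm$bin_end <= 3600
  expect_equal(sum(bm$bin_start >= 600 & bm$bin_end <= 3600 &
                     bm$metric == "distance"), 10L) # TOI = 10 five-min bins
  expect_equal(s$distance_cm,
               sum(bm$value[toi_bins & bm$metric == "distance"]),
               tolerance = 1e-6)
  expect_equal(s$mobile_episode_count,
               sum(bm$value[toi_bins & bm$metric == "mobile_episodes"]))
  expect_equal(s$pct_time_immobile,
               mean(bm$value[toi_bins & bm$metric == "pct_immobile"]),
               tolerance = 1e-9)
  expect_equal(s$abs_max_speed,
               max(s$abs_max_speed_early, s$abs_max_speed_late))
  expect_lte(s$avg_max_speed, s$abs_max_speed)
  expect_equal(s$frac_corner + s$frac_wall + s$frac_center, 1, tolerance = 1e-9)
  # truncated session -> error naming missing bins
  short <- simulate_session(session_metadata("t2"), seed = 1, dt = 0.5,
                            duration = 1200)
  expect_error(toi_summary(short), "missing bins")
})

test_that("an all-still session yields the degenerate summary", {
  n <- 7200; dt <- 0.5
  tr <- make_traj(rep(25, n), rep(25, n), dt = dt)
  s <- toi_summary(tr)
  expect_equal(s$distance_cm, 0)
  expect_equal(s$mobile_episode_count, 0L)
  expect_equal(s$pct_time_immobile, 100)
  expect_equal(s$rotations_total, 0L)
  expect_equal(s$frac_center, 1)
})
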