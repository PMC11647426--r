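test_that("dose_effect obeys the Emax/Hill/Bateman identities", {
  pd <- pd_params()
  expect_equal(dose_effect(c(0, 5, 50), 0, pd), c(0, 0, 0)) # saline identity
  tstar <- bateman_peak_time(pd)
  expect_equal(dose_effect(tstar, pd$ed50, pd), pd$emax / 2) # Hill midpoint
  expect_equal(max(bateman(seq(0, 90, by = 0.01), pd)), 1, tolerance = 1e-6)
  expect_error(dose_effect(-1, 1, pd), "t must")
  expect_error(dose_effect(1, -1, pd), "dose must")
  expect_error(pd_params(ka = 0.01, ke = 0.04), "must exceed")
})

test_that("fast-onset limit: B(t) approaches exp(-ke t) at ka = 1000 ke", {
  pd <- pd_params(ka = 1000 * 0.04, ke = 0.04)
  t <- seq(1, 80, by = 1)
  expect_true(all(abs(bateman(t, pd) - exp(-0.04 * t)) < 0.01))
})

test_that("suppression is monotone in dose at fixed time", {
  pd <- pd_params(ed50 = 0.2)
  doses <- c(0, 0.05, 0.1, 0.2, 0.5, 1)
  for (t in c(5, 20, 60)) {
    e <- dose_effect(t, doses, pd)
    expect_true(all(diff(e) > 0))
    expect_true(all(e >= 0 & e <= pd$emax))
  }
})

test_that("simulate_session is seed-deterministic and respects the arena", {
  meta <- session_metadata("d1", drug = "SCH23390", dose = 0.05)
  a <- simulate_session(meta, seed = 5, dt = 0.2, duration = 300)
  b <- simulate_session(meta, seed = 5, dt = 0.2, duration = 300)
  expect_identical(a$frames, b$frames)
  c <- simulate_session(meta, seed = 6, dt = 0.2, duration = 300)
  expect_false(identical(a$frames, c$frames))
  xy <- as.matrix(a$frames[, -1])
  expect_true(all(xy >= 0 & xy <= 50))
  expect_equal(n_frames(a), 1500L)
})

test_that("drug suppresses TOI distance relative to saline", {
  pdl <- list(haloperidol = pd_params(ed50 = 0.2))
  d_sal <- d_drg <- numeric(6)
  for (s in 1:6) {
    sal <- simulate_session(session_metadata("s", test_round = 1),
                            seed = 20 + s, dt = 0.25, duration = 3600)
    drg <- simulate_session(session_metadata("d", drug = "haloperidol",
                                             dose = 2, test_round = 1),
                            pd = pdl, seed = 20 + s, dt = 0.25,
                            duration = 3600)
    d_sal[s] <- distance_travelled(sal, c(600, 3600))
    d_drg[s] <- distance_travelled(drg, c(600, 3600))
  }
  expect_lt(mean(d_drg), mean(d_sal))
})

test_that("across-round habituation lowers locomotor output", {
  d <- sapply(c(1, 4), function(r) {
    mean(sapply(1:6, function(s) {
      tr <- simulate_session(session_metadata("h", test_round = r),
                             seed = 40 + s, dt = 0.25, duration = 1800)
      distance_travelled(tr)
    }))
  })
  expect_lt(d[2], d[1]) # round_factor < 1
})

test_that("lattice design satisfies all invariants", {
  plan <- make_lattice_design(48, seed = 3)
  expect_s3_class(plan, "design_plan")
  expect_silent(validate_design(plan))
  # exactly one saline animal in every batch x round
  tab <- tapply(plan$drug == "saline",
                interaction(plan$batch, plan$test_round), sum)
  expect_true(all(tab == 1))
  # no repeated (drug, dose) per animal; <= 4 injections
  trt <- plan[plan$drug != "saline", ]
  expect_equal(anyDuplicated(paste(trt$animal_id, trt$drug, trt$dose)), 0L)
  expect_true(all(table(plan$animal_id) <= 4))
  # >= 5 days between an animal's sessions
  expect_true(all(unlist(tapply(plan$day, plan$animal_id,
                                function(d) diff(sort(d)))) >= 5))
  # balance: all ten combos used, with near-equal counts
  counts <- table(paste(trt$drug, trt$dose))
  expect_length(counts, 10L)
  expect_lte(max(counts) - min(counts), 1L)
  # each animal receives saline exactly once over four rounds
  sal_per_animal <- table(plan$animal_id[plan$drug == "saline"])
  expect_true(all(sal_per_animal == 1))
})

test_that("minimal and infeasible designs behave as specified", {
  p1 <- make_lattice_design(4, doses = list(haloperidol = c(0.1, 0.5, 1)),
                            n_rounds = 1, seed = 1)
  expect_equal(nrow(p1), 4L)
  expect_equal(sum(p1$drug == "saline"), 1L)
  expect_equal(anyDuplicated(paste(p1$drug, p1$dose)), 0L)
  expect_error(make_lattice_design(6), "divisible by 4")
  expect_error(make_lattice_design(4, n_rounds = 1,
                                   doses = list(SCH23390 = c(.005, .01, .02, .05, .5),
                                                haloperidol = c(.05, .1, .2, .5, 1))),
               "infeasible")
})

test_that("simulate_cohort is reproducible and traceable", {
  plan <- make_lattice_design(8, doses = list(SCH23390 = 0.5, haloperidol = 1),
                              n_rounds = 2, seed = 2)
  co1 <- simulate_cohort(plan, seed = 9, dt = 0.5, duration = 120)
  expect_length(co1$trajectories, nrow(plan))
  expect_identical(co1$manifest$session_id,
                   sprintf("%s_r%d", plan$animal_id, plan$test_round))
  co2 <- simulate_cohort(plan, seed = 9, dt = 0.5, duration = 120)
  expect_identical(co1$manifest, co2$manifest)
  expect_identical(co1$trajectories[[5]]$frames, co2$trajectories[[5]]$frames)
  # distinct per-session seeds derived from the master seed
  expect_equal(anyDuplicated(co1$manifest$seed), 0L)
})

test_that("freezing frames are a subset of immobile frames by construction", {
  for (s in 1:5) {
    tr <- simulate_session(session_metadata("f"), seed = 60 + s, dt = 0.2,
                           duration = 600)
    imm <- segment_immobility(tr)
    frz <- segment_freezing(tr, imm)
    t_imm <- sum(imm$end[imm$kind == "immobile"] - imm$start[imm$kind == "immobile"])
    t_frz <- sum(frz$end - frz$start)
    expect_lte(t_frz, t_imm + 1e-9)
    # every freezing episode lies inside some immobile episode
    for (k in seq_len(nrow(frz))) {
      inside <- any(imm$start[imm$kind == "immobile"] <= frz$start[k] + 1e-9 &
                      imm$end[imm$kind == "immobile"] >= frz$end[k] - 1e-9)
      expect_true(inside)
    }
  }
})
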