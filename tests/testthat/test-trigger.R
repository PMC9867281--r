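# scripted four-channel recording: unit spikes at given (time, muscle)
mk_script_rec <- function(spikes, fs = 100, dur = 20) {
  muscles <- c("R-Sol", "L-Sol", "R-ReFe", "L-ReFe")
  m <- matrix(0, dur * fs, 4, dimnames = list(NULL, muscles))
  for (i in seq_len(nrow(spikes))) {
    m[round(spikes$time[i] * fs) + 1, spikes$muscle[i]] <- 1
  }
  emg_recording(m, fs = fs, channel_map = muscles)
}

mk_thr4 <- function(usable = NULL, refractory = 0.4) {
  muscles <- c("R-Sol", "L-Sol", "R-ReFe", "L-ReFe")
  threshold_set(setNames(rep(0.5, 4), muscles),
                setNames(rep(0.1, 4), muscles),
                t_off = 0.05, refractory = refractory, usable = usable)
}

# independent hand-simulated FSM over a scripted onset sequence
oracle_fsm <- function(onsets, map, start_side, refractory) {
  pending <- start_side
  refr_end <- -Inf
  acc <- list()
  for (i in seq_len(nrow(onsets))) {
    t <- onsets$time[i]; m <- onsets$muscle[i]
    if (t < refr_end) next
    if (m %in% map[[pending]]) {
      acc[[length(acc) + 1]] <- data.frame(side = pending, time = t,
                                           muscle = m)
      refr_end <- t + refractory
      pending <- if (pending == "R") "L" else "R"
    }
  }
  do.call(rbind, acc)
}

test_that("the step map covers the four trigger muscles in both conventions", {
  m2 <- muscle_step_map("table2")
  expect_setequal(c(m2$R, m2$L), c("R-Sol", "L-Sol", "R-ReFe", "L-ReFe"))
  expect_true("R-ReFe" %in% m2$R && "L-Sol" %in% m2$R)
  ms <- muscle_step_map("sec233")
  expect_true("R-Sol" %in% ms$R && "L-ReFe" %in% ms$R)
  expect_setequal(c(ms$R, ms$L), c(m2$R, m2$L))
})

test_that("a pending-side onset triggers a step; refractory and wrong-side onsets do not", {
  spikes <- data.frame(
    time = c(1.0, 1.2, 2.0, 3.0),
    muscle = c("R-ReFe", "L-ReFe", "L-ReFe", "R-ReFe")
  )
  run <- run_trigger(mk_script_rec(spikes), mk_thr4(), muscle_step_map(),
                     start_side = "R")
  expect_equal(run$commands$side, c("R", "L", "R"))
  expect_equal(run$commands$time, c(1.0, 2.0, 3.0))
  expect_equal(run$commands$muscle[1], "R-ReFe")
  # the 1.2 s onset fell in the refractory period
  expect_true("refractory" %in% run$ignored$reason)
})

test_that("redundancy keeps the controller alternating when a channel is unusable", {
  # left steps must come from R-Sol (contralateral soleus) when L-ReFe is out
  spikes <- data.frame(
    time = c(1.0, 1.5, 2.0, 2.5, 3.0, 3.5, 4.0, 4.5),
    muscle = rep(c("R-ReFe", "L-ReFe", "R-Sol", "L-Sol"), 2)
  )
  muscles <- c("R-Sol", "L-Sol", "R-ReFe", "L-ReFe")
  thr <- mk_thr4(usable = setNames(c(TRUE, TRUE, TRUE, FALSE), muscles))
  run <- run_trigger(mk_script_rec(spikes), thr, muscle_step_map(), "R")
  expect_true(all(diff(match(run$commands$side, c("R", "L"))) != 0))
  left <- run$commands[run$commands$side == "L", ]
  expect_true(all(left$muscle == "R-Sol"))
  # hand-simulated FSM on the same scripted sequence
  ons <- spikes[spikes$muscle != "L-ReFe", ]
  want <- oracle_fsm(ons[order(ons$time), ], muscle_step_map(), "R", 0.4)
  expect_equal(run$commands$time, want$time)
  expect_equal(run$commands$muscle, want$muscle)
  expect_equal(run$commands$side, want$side)

  # both channels of the left step (L-ReFe + R-Sol) unusable: error
  thr_bad <- mk_thr4(usable = setNames(c(FALSE, TRUE, TRUE, FALSE), muscles))
  expect_error(run_trigger(mk_script_rec(spikes), thr_bad, muscle_step_map()),
               "unusable")
})

test_that("FSM agrees with the hand-simulated oracle on random onset scripts", {
  for (s in 1:50) {
    set.seed(s + 900)
    n_sp <- sample(5:25, 1)
    spikes <- data.frame(
      time = sort(sample(seq(0.5, 19, by = 0.01), n_sp)),
      muscle = sample(c("R-Sol", "L-Sol", "R-ReFe", "L-ReFe"), n_sp, TRUE)
    )
    refr <- sample(c(0.2, 0.4, 0.8), 1)
    run <- run_trigger(mk_script_rec(spikes), mk_thr4(refractory = refr),
                       muscle_step_map(), "R")
    # channel-level re-arm: drop same-muscle spikes within the refractory
    # (in integer samples, the clock the detector runs on)
    kept <- do.call(rbind, lapply(split(spikes, spikes$muscle), function(g) {
      si <- round(g$time * 100)
      keep <- logical(nrow(g)); last <- -Inf
      for (i in seq_len(nrow(g))) {
        if (si[i] >= last + round(refr * 100)) { keep[i] <- TRUE; last <- si[i] }
      }
      g[keep, ]
    }))
    kept <- kept[order(kept$time), ]
    want <- oracle_fsm(kept, muscle_step_map(), "R", refr)
    if (is.null(want)) {
      expect_equal(nrow(run$commands), 0)
    } else {
      expect_equal(run$commands$time, want$time)
      expect_equal(run$commands$side, want$side)
    }
    if (nrow(run$commands) > 1)
      expect_true(all(run$commands$side[-1] !=
                        run$commands$side[-nrow(run$commands)]))
  }
})

test_that("onset phases are expressed as % of the containing gait cycle", {
  bounds <- cbind(c(0, 1.2), c(1.2, 2.4))
  ev <- data.frame(muscle = c("R-ReFe", "R-ReFe", "L-Sol"),
                   time = c(0, 0.6, 1.8))
  st <- onset_cycle_stats(ev, bounds)
  expect_equal(st$onsets$phase, c(0, 50, 50))
  expect_warning(
    onset_cycle_stats(data.frame(muscle = "R-Sol", time = 99), bounds),
    "outside")
  s <- st$summary
  expect_equal(s$mean_phase[s$muscle == "R-ReFe"], 25)
})

test_that("detection shares are percentages that sum to 100", {
  ev <- data.frame(muscle = c("a", "a", "b", "c"))
  sh <- detection_shares(ev, muscles = c("a", "b", "c", "d"))
  expect_equal(sh$share, c(50, 25, 25, 0))
  expect_equal(sum(sh$share), 100, tolerance = 1e-9)

  ev1 <- data.frame(muscle = rep("a", 7))
  expect_equal(detection_shares(ev1, muscles = c("a", "b"))$share, c(100, 0))
  expect_error(detection_shares(ev1[0, , drop = FALSE]), "no accepted")

  # counting oracle on seeded mixed draws; removing a muscle never raises its share
  for (s in 1:30) {
    set.seed(s)
    levels <- c("R-Sol", "L-Sol", "R-ReFe", "L-ReFe")
    ms <- sample(levels, 50, TRUE, prob = c(0.5, 0.3, 0.15, 0.05))
    sh <- detection_shares(data.frame(muscle = ms), muscles = levels)
    expect_equal(setNames(sh$share, sh$muscle), oracle_shares(ms, levels))
    expect_equal(sum(sh$share), 100, tolerance = 1e-9)
    drop <- data.frame(muscle = ms[ms != "R-Sol"])
    if (nrow(drop) > 0) {
      sh2 <- detection_shares(drop, muscles = levels)
      expect_lte(sh2$share[sh2$muscle == "R-Sol"],
                 sh$share[sh$muscle == "R-Sol"])
    }
  }
})
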