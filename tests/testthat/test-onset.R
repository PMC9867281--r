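mk_thr <- function(h_on, h_off = h_on / 5, t_off = 0.05, refractory = 0.4,
                   muscle = "R-Sol") {
  threshold_set(setNames(h_on, muscle), setNames(h_off, muscle),
                t_off = t_off, refractory = refractory)
}

test_that("ST threshold is k_on times the baseline RMS", {
  base <- structure(list(P0 = c(1, 0.01), channel_map = c("R-Sol", "L-Sol")),
                    class = "baseline_stats")
  expect_equal(unname(st_threshold(base, 3)), c(3, 0.3))
  basez <- structure(list(P0 = 0, channel_map = "R-Sol"),
                     class = "baseline_stats")
  expect_warning(h <- st_threshold(basez, 3), "floored")
  expect_gt(unname(h), 0)
  expect_error(st_threshold(base, -1), "positive")

  set.seed(21)
  rec <- emg_recording(matrix(rnorm(20000, 0, 0.05)), fs = 2000,
                       channel_map = "R-Sol")
  b <- estimate_baseline(rec, c(0, 10))
  expect_equal(unname(st_threshold(b, 3)), 0.15, tolerance = 0.05)
})

test_that("ST onset detection fires at first threshold crossings", {
  x <- rep(0, 1000)
  rec <- emg_recording(matrix(x), fs = 1000, channel_map = "R-Sol")
  thr <- mk_thr(0.5)
  expect_equal(nrow(detect_onset_st(rec, thr)), 0)

  x[500:1000] <- 1  # step to 2 * h_on at sample 500
  rec <- emg_recording(matrix(x), fs = 1000, channel_map = "R-Sol")
  ev <- detect_onset_st(rec, thr, muscles = "R-Sol")
  # refractory re-arm: onsets every 400 samples while above threshold
  expect_equal(ev$sample[1], 500)
  expect_equal(ev$time[1], 499 / 1000)

  expect_error(detect_onset_st(rec, thr, muscles = "L-Sol"),
               "not in recording")
})

test_that("ST onsets match the brute-force scan on 1000 seeded burst signals", {
  mismatches <- 0L
  for (s in 1:1000) {
    set.seed(s)
    n <- 300
    x <- rnorm(n, 0, 0.1)
    nb <- sample(0:3, 1)
    if (nb > 0) {
      at <- sort(sample(seq_len(n - 20), nb))
      for (a in at) x[a:(a + 19)] <- x[a:(a + 19)] + runif(1, 0.5, 2)
    }
    h <- runif(1, 0.3, 0.8)
    rearm <- sample(c(10, 40, 80), 1)
    rec <- emg_recording(matrix(x), fs = 100, channel_map = "R-Sol")
    thr <- mk_thr(h, refractory = rearm / 100)
    got <- detect_onset_st(rec, thr, muscles = "R-Sol")$sample
    want <- oracle_st(x, h, rearm)
    if (!identical(as.integer(got), as.integer(want)))
      mismatches <- mismatches + 1L
  }
  expect_equal(mismatches, 0L)
})

test_that("raising the threshold never adds onsets and detection is scale-equivariant", {
  set.seed(33)
  for (i in 1:20) {
    x <- rnorm(500, 0, 0.2)
    x[sample(450, 3)] <- x[sample(450, 3)] + 1.5
    rec <- emg_recording(matrix(x), fs = 100, channel_map = "R-Sol")
    hs <- sort(runif(4, 0.2, 1.5))
    counts <- sapply(hs, function(h)
      nrow(detect_onset_st(rec, mk_thr(h), muscles = "R-Sol")))
    expect_true(all(diff(counts) <= 0))

    h <- hs[2]
    ev1 <- detect_onset_st(rec, mk_thr(h), muscles = "R-Sol")
    rec5 <- emg_recording(matrix(5 * x), fs = 100, channel_map = "R-Sol")
    ev5 <- detect_onset_st(rec5, mk_thr(5 * h), muscles = "R-Sol")
    expect_equal(ev1$sample, ev5$sample)
  }
})

test_that("DT offset requires a full sub-threshold dwell", {
  fs <- 100
  env_vals <- c(rep(1, 200), rep(0.01, 200))  # drops below h_off at t = 2.0 s
  env <- structure(list(values = matrix(env_vals,
                                        dimnames = list(NULL, "R-Sol")),
                        fs = fs, t0 = 0, channel_map = "R-Sol"),
                   class = "envelope")
  thr <- mk_thr(0.5, h_off = 0.1, t_off = 0.05)
  off <- detect_offset_dt(env, thr, list(muscle = "R-Sol", time = 0.5))
  expect_equal(off$time, 2.0)
  expect_gte(off$dwell, thr$t_off)

  # a dip of t_off/2 does not qualify
  env_vals2 <- rep(1, 400)
  env_vals2[200:202] <- 0.01  # 3 samples < dwell_n = 5
  env2 <- env
  env2$values <- matrix(env_vals2, dimnames = list(NULL, "R-Sol"))
  expect_null(detect_offset_dt(env2, thr, list(muscle = "R-Sol", time = 0.5)))
})

test_that("DT offsets match the exhaustive sliding-window oracle", {
  for (s in 1:200) {
    set.seed(s + 5000)
    n <- 250
    env_vals <- abs(rnorm(n, 0.2, 0.15))
    env <- structure(list(values = matrix(env_vals,
                                          dimnames = list(NULL, "R-Sol")),
                          fs = 100, t0 = 0, channel_map = "R-Sol"),
                     class = "envelope")
    h_off <- runif(1, 0.1, 0.4)
    t_off <- sample(c(0.03, 0.05, 0.1), 1)
    thr <- mk_thr(1, h_off = h_off, t_off = t_off)
    onset_i <- sample(5:100, 1)
    off <- detect_offset_dt(env, thr,
                            list(muscle = "R-Sol", time = (onset_i - 1) / 100))
    want <- oracle_dwell(env_vals, h_off, round(t_off * 100), onset_i + 1)
    if (is.na(want)) {
      expect_null(off)
    } else {
      expect_equal(off$time, (want - 1) / 100, tolerance = 1e-12)
    }
  }
})

test_that("onsets and DT offsets alternate when the envelope re-arms channels", {
  set.seed(77)
  fs <- 1000
  n <- 8000
  env_true <- rep(0.01, n)
  for (a in c(1000, 3000, 5000, 7000)) env_true[a:(a + 600)] <- 1
  x <- env_true * rnorm(n)
  rec <- emg_recording(matrix(x), fs = fs, channel_map = "R-Sol")
  env <- structure(list(values = matrix(env_true,
                                        dimnames = list(NULL, "R-Sol")),
                        fs = fs, t0 = 0, channel_map = "R-Sol"),
                   class = "envelope")
  thr <- mk_thr(0.15, h_off = 0.1, t_off = 0.05)
  ons <- detect_onset_st(rec, thr, muscles = "R-Sol", envelope = env)
  expect_equal(nrow(ons), 4)  # one onset per burst, not per crossing
  for (i in seq_len(nrow(ons))) {
    off <- detect_offset_dt(env, thr, ons[i, ])
    expect_gt(off$time, ons$time[i])
    expect_gte(off$dwell, thr$t_off)
    if (i < nrow(ons)) expect_lt(off$time, ons$time[i + 1])
  }
})

test_that("calibration flags silent channels and validates the walk", {
  cfg <- sim_config(n_cycles = 4)
  sim <- simulate_gait(cfg, seed = 301)
  thr <- calibrate(sim$emg, sim$events)
  expect_true(all(thr$usable[c("R-Sol", "L-Sol", "R-ReFe", "L-ReFe")]))
  # manual threshold oracle: k_on * RMS over the baseline window
  b <- estimate_baseline(sim$emg, sim$events$baseline_window)
  expect_equal(unname(thr$h_on["R-Sol"]),
               unname(6 * sqrt(b$P0["R-Sol"])), tolerance = 1e-12)

  simc <- simulate_gait(sim_config(n_cycles = 4,
                                   corrupt_channels = "L-ReFe"), seed = 302)
  expect_message(thrc <- calibrate(simc$emg, simc$events), "L-ReFe")
  expect_false(thrc$usable[["L-ReFe"]])
  expect_true(all(thrc$usable[c("R-Sol", "L-Sol", "R-ReFe")]))

  ev1 <- gait_events(left = c(2.0), right = c(2.5), source_fs = 100,
                     baseline_window = c(0, 1.9))
  expect_error(calibrate(sim$emg, ev1), "at least 2 steps")
})
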