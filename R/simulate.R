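# Seeded synthetic gait generator: foot-contact events, joint angles and
# multichannel surface EMG with known ground truth (synergy structure, burst
# phases, corrupt channels, joint extrema), so every pipeline stage can be
# tested end to end without recordings.

# default 4-synergy generative model over 6 muscles
# rows: Sol TiAn ReFe VaLa GaMe BiFe; columns: basic patterns
default_W0 <- function() {
  W <- rbind(
    Sol  = c(0.00, 1.00, 0.00, 0.00),
    TiAn = c(0.00, 0.00, 0.45, 0.80),
    ReFe = c(0.00, 0.00, 1.00, 0.00),
    VaLa = c(1.00, 0.00, 0.00, 0.20),
    GaMe = c(0.15, 0.90, 0.00, 0.00),
    BiFe = c(0.40, 0.00, 0.00, 0.90)
  )
  colnames(W) <- paste0("syn", 1:4)
  W
}

#' Synthetic gait simulation configuration
#'
#' Defines the study conditions the simulator emulates: quasi-periodic slow
#' exoskeleton treadmill walking, six-muscle envelopes generated from four
#' basic activation patterns (weight acceptance, push-off, swing initiation,
#' terminal swing), raw EMG as envelope-modulated band-limited Gaussian
#' noise over a resting-noise floor, and sinusoidal joint-angle templates.
#' Trigger-relevant muscles carry a single burst each: soleus at push-off
#' (~42% of its own leg's cycle), rectus femoris at swing initiation (~65%).
#'
#' @param n_cycles number of gait cycles.
#' @param period_mean,period_sd cycle period distribution, seconds (draws are
#'   redrawn while non-positive).
#' @param stance_fraction fraction of the cycle in stance, in (0,1);
#'   metadata shaping the angle templates.
#' @param baseline_s quiet-standing duration before walking starts, s; used
#'   as the baseline-noise calibration window.
#' @param fs_emg,fs_kin EMG and kinematics sampling rates, Hz.
#' @param carrier_band EMG carrier noise band, Hz (surface EMG power lives
#'   roughly in 20-450 Hz).
#' @param baseline_sd resting-noise SD in units of the unit peak envelope.
#' @param envelope_noise multiplicative envelope noise fraction (default 0.10).
#' @param W0 `6 x n_syn` non-negative synergy weights (rows Sol, TiAn, ReFe,
#'   VaLa, GaMe, BiFe).
#' @param bump_centers,bump_widths basic-pattern Gaussian bump centers and SD
#'   widths, % gait cycle (circular).
#' @param corrupt_channels muscle labels whose EMG is baseline noise only
#'   (no burst modulation), e.g. `"L-ReFe"`.
#' @param left_offset_frac left foot-contact offset as a fraction of the
#'   cycle (default 0.5, symmetric gait).
#' @param angle_templates data frame with columns `joint`, `offset`,
#'   `amplitude`, `phase` (degrees / % cycle); defaults shaped to slow
#'   exoskeleton walking.
#' @param angle_jitter per-cycle multiplicative amplitude jitter SD.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_cycles = 30, period_mean = 2.0, period_sd = 0.1,
                       stance_fraction = 0.6, baseline_s = 2,
                       fs_emg = 2000, fs_kin = 100,
                       carrier_band = c(20, 450), baseline_sd = 0.02,
                       envelope_noise = 0.10,
                       W0 = default_W0(),
                       bump_centers = c(8, 42, 65, 92),
                       bump_widths = c(6, 7, 5, 6),
                       corrupt_channels = character(0),
                       left_offset_frac = 0.5,
                       angle_templates = NULL,
                       angle_jitter = 0.05) {
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (period_mean <= 0 || period_sd < 0) stop("invalid period parameters")
  if (stance_fraction <= 0 || stance_fraction >= 1)
    stop("stance_fraction must lie in (0, 1)")
  if (carrier_band[2] >= fs_emg / 2)
    stop("carrier band exceeds the EMG Nyquist frequency")
  if (ncol(W0) != length(bump_centers) ||
      length(bump_centers) != length(bump_widths))
    stop("W0 columns, bump_centers and bump_widths must agree")
  if (any(W0 < 0)) stop("W0 must be non-negative")
  labels <- c(paste0("R-", rownames(W0)), "L-Sol", "L-ReFe")
  bad <- setdiff(corrupt_channels, labels)
  if (length(bad))
    stop("corrupt_channels not among simulated channels: ",
         paste(bad, collapse = ", "))
  if (is.null(angle_templates)) {
    angle_templates <- data.frame(
      joint = c("hip", "knee", "ankle"),
      offset = c(7, 26, 4.5),
      amplitude = c(18, 24, 8),
      phase = c(85, 70, 45)
    )
  }
  structure(list(
    n_cycles = n_cycles, period_mean = period_mean, period_sd = period_sd,
    stance_fraction = stance_fraction, baseline_s = baseline_s,
    fs_emg = fs_emg, fs_kin = fs_kin, carrier_band = carrier_band,
    baseline_sd = baseline_sd, envelope_noise = envelope_noise,
    W0 = W0, bump_centers = bump_centers, bump_widths = bump_widths,
    corrupt_channels = corrupt_channels, left_offset_frac = left_offset_frac,
    angle_templates = angle_templates, angle_jitter = angle_jitter,
    channels = labels
  ), class = "sim_config")
}

#' Generate foot-contact events
#'
#' Alternating left/right contact onsets with per-cycle period jitter; the
#' left contact is offset into each cycle by `left_offset_frac`. Walking
#' starts after `baseline_s` seconds of quiet standing, which is recorded as
#' the events' baseline window.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return list: `events` (a [gait_events()]) and `truth` (periods, onsets).
#' @export
gen_events <- function(cfg, seed = 1) {
  with_seed(seed, {
    periods <- numeric(cfg$n_cycles)
    for (i in seq_len(cfg$n_cycles)) {
      p <- -1
      while (p <= 0) p <- stats::rnorm(1, cfg$period_mean, cfg$period_sd)
      periods[i] <- p
    }
    right <- cfg$baseline_s + c(0, cumsum(periods))
    left <- right[seq_len(cfg$n_cycles)] + cfg$left_offset_frac * periods
    ev <- gait_events(left = left, right = right, source_fs = cfg$fs_kin,
                      baseline_window = c(0.1, cfg$baseline_s - 0.1))
    list(events = ev, truth = list(periods = periods))
  })
}

# circular distance on a 0-100 scale
circ_dist <- function(a, b) {
  d <- abs(a - b) %% 100
  pmin(d, 100 - d)
}

# basic-pattern value at phase (% cycle) for bump k
bump_value <- function(phase, center, width) {
  exp(-0.5 * (circ_dist(phase, center) / width)^2)
}

# per-sample gait phase (%) for one side's contact onsets; NA outside walking
side_phase <- function(t, onsets, mean_period) {
  idx <- findInterval(t, onsets)
  phase <- rep(NA_real_, length(t))
  k <- length(onsets)
  inside <- idx >= 1 & idx < k
  i <- idx[inside]
  phase[inside] <- 100 * (t[inside] - onsets[i]) / (onsets[i + 1] - onsets[i])
  # after the last onset: extrapolate with the mean period
  tail <- idx == k
  phase[tail] <- 100 * (t[tail] - onsets[k]) / mean_period
  phase[tail & phase > 100] <- NA_real_
  phase
}

# band-limited unit-variance Gaussian noise
bandlimited_noise <- function(n, fs, band) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / stats::sd(x)
}

#' Generate synthetic multichannel surface EMG
#'
#' Per muscle, the planted envelope is the synergy reconstruction
#' `sum_k W0[m,k] * bump_k(phase)` mapped onto each cycle's real-time extent
#' on the muscle's own side, degraded by multiplicative Gaussian noise. The
#' raw signal is that envelope modulating zero-mean unit-variance
#' band-limited noise, plus an independent resting-noise floor. Channels in
#' `corrupt_channels` emit the resting-noise floor only.
#'
#' @param cfg a [sim_config()].
#' @param events a [gait_events()] from [gen_events()].
#' @param seed RNG seed.
#' @return list: `emg` (an [emg_recording()]) and `truth` with the planted
#'   noisy envelopes, clean envelopes, `W0`, `H0` (patterns on a 100-point
#'   grid), and nominal burst-onset phases of the trigger muscles (own-side
#'   % cycle, taken as two bump widths before the bump center).
#' @export
gen_emg <- function(cfg, events, seed = 1) {
  with_seed(seed, {
    dur <- max(events$right, events$left) + 0.5
    n <- floor(dur * cfg$fs_emg) + 1L
    t <- (seq_len(n) - 1) / cfg$fs_emg
    ph <- list(R = side_phase(t, events$right, cfg$period_mean),
               L = side_phase(t, events$left, cfg$period_mean))
    env_clean <- env_noisy <- raw <-
      matrix(0, n, length(cfg$channels),
             dimnames = list(NULL, cfg$channels))
    for (j in seq_along(cfg$channels)) {
      lab <- cfg$channels[j]
      side <- sub("-.*", "", lab)
      mus <- sub("^[LR]-", "", lab)
      corrupt <- lab %in% cfg$corrupt_channels
      if (!corrupt) {
        phase <- ph[[side]]
        e <- numeric(n)
        ok <- !is.na(phase)
        for (k in seq_along(cfg$bump_centers)) {
          w <- cfg$W0[mus, k]
          if (w > 0)
            e[ok] <- e[ok] + w * bump_value(phase[ok], cfg$bump_centers[k],
                                            cfg$bump_widths[k])
        }
        env_clean[, j] <- e
        env_noisy[, j] <- pmax(
          e * (1 + cfg$envelope_noise * stats::rnorm(n)), 0)
        raw[, j] <- env_noisy[, j] *
          bandlimited_noise(n, cfg$fs_emg, cfg$carrier_band)
      }
      raw[, j] <- raw[, j] +
        cfg$baseline_sd * bandlimited_noise(n, cfg$fs_emg, cfg$carrier_band)
    }
    # nominal burst start: two bump widths before the dominant bump's center
    trig <- intersect(c("R-Sol", "L-Sol", "R-ReFe", "L-ReFe"), cfg$channels)
    onset_phase <- vapply(trig, function(lab) {
      mus <- sub("^[LR]-", "", lab)
      k <- which.max(cfg$W0[mus, ])
      (cfg$bump_centers[k] - 2 * cfg$bump_widths[k]) %% 100
    }, numeric(1))
    H0 <- t(vapply(seq_along(cfg$bump_centers), function(k)
      bump_value(seq(0, 100, length.out = 101)[1:100], cfg$bump_centers[k],
                 cfg$bump_widths[k]), numeric(100)))
    list(
      emg = emg_recording(raw, fs = cfg$fs_emg, channel_map = cfg$channels),
      truth = list(envelope = env_noisy, envelope_clean = env_clean,
                   W0 = cfg$W0, H0 = H0, onset_phase_own = onset_phase,
                   corrupt_channels = cfg$corrupt_channels)
    )
  })
}

#' Generate synthetic joint-angle trajectories
#'
#' Per joint and side, a sinusoidal template over the side's own gait cycle
#' (`offset + amplitude * cos(2*pi*(phase - peak_phase)/100)`) with per-cycle
#' multiplicative amplitude jitter; outside walking the joint rests at its
#' offset. Positive values follow the flexion/dorsiflexion-positive sign
#' convention.
#'
#' @param cfg a [sim_config()].
#' @param events a [gait_events()].
#' @param seed RNG seed.
#' @return list: `angles` (a [joint_trajectories()]) and `truth` with
#'   per-cycle amplitude, max, min and ROM per joint column (right-side
#'   cycles for right joints, left-side for left).
#' @export
gen_angles <- function(cfg, events, seed = 1) {
  with_seed(seed, {
    dur <- max(events$right, events$left) + 0.5
    n <- floor(dur * cfg$fs_kin) + 1L
    t <- (seq_len(n) - 1) / cfg$fs_kin
    joints <- as.vector(outer(c("R", "L"), cfg$angle_templates$joint,
                              paste, sep = "-"))
    ang <- matrix(NA_real_, n, length(joints),
                  dimnames = list(NULL, joints))
    truth <- list()
    for (side in c("R", "L")) {
      onsets <- if (side == "R") events$right else events$left
      idx <- findInterval(t, onsets)
      nc <- length(onsets) - 1L
      for (r in seq_len(nrow(cfg$angle_templates))) {
        tpl <- cfg$angle_templates[r, ]
        col <- paste0(side, "-", tpl$joint)
        amp_c <- tpl$amplitude *
          pmax(1 + cfg$angle_jitter * stats::rnorm(nc), 0.1)
        x <- rep(tpl$offset, n)
        for (i in seq_len(nc)) {
          sel <- idx == i & t < onsets[i + 1]
          phs <- 100 * (t[sel] - onsets[i]) / (onsets[i + 1] - onsets[i])
          x[sel] <- tpl$offset +
            amp_c[i] * cos(2 * pi * (phs - tpl$phase) / 100)
        }
        ang[, col] <- x
        truth[[col]] <- data.frame(
          cycle = seq_len(nc), amplitude = amp_c,
          max = tpl$offset + amp_c, min = tpl$offset - amp_c,
          rom = 2 * amp_c)
      }
    }
    list(angles = joint_trajectories(ang, fs = cfg$fs_kin,
                                     joint_map = joints),
         truth = truth)
  })
}

#' Run the full synthetic gait simulation
#'
#' Generates events, EMG and joint angles from one configuration and seed;
#' the output is fully reproducible from `(cfg, seed)`.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed (events, EMG and angles use `seed`, `seed + 1`,
#'   `seed + 2`).
#' @return object of class `sim_output`: `emg`, `events`, `angles`, `truth`.
#' @export
simulate_gait <- function(cfg = sim_config(), seed = 1) {
  ev <- gen_events(cfg, seed)
  em <- gen_emg(cfg, ev$events, seed + 1L)
  an <- gen_angles(cfg, ev$events, seed + 2L)
  structure(list(
    emg = em$emg, events = ev$events, angles = an$angles,
    truth = c(ev$truth, em$truth, list(angles = an$truth)),
    config = cfg, seed = seed
  ), class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf(
    "<sim_output> %d cycles, %d EMG channels @ %g Hz, seed %d\n",
    x$config$n_cycles, length(x$config$channels), x$config$fs_emg, x$seed))
  if (length(x$config$corrupt_channels))
    cat("  corrupt channels:",
        paste(x$config$corrupt_channels, collapse = ", "), "\n")
  invisible(x)
}

#' Planted (ground-truth) envelopes as a cycle matrix
#'
#' Convenience accessor: time-normalizes the simulator's planted noisy
#' envelopes of the six right-side analysis muscles onto the cycle grid, the
#' exact input a synergy analysis of the simulated trial would see with a
#' perfect envelope estimator.
#'
#' @param sim a `sim_output`.
#' @param grid points per cycle.
#' @param noisy use the noise-degraded envelopes (`TRUE`, default) or the
#'   clean generative ones.
#' @return a `cycle_matrix` over the six right-side muscles.
#' @export
sim_envelope_cycles <- function(sim, grid = 100, noisy = TRUE) {
  chans <- paste0("R-", rownames(sim$config$W0))
  env <- if (noisy) sim$truth$envelope else sim$truth$envelope_clean
  e <- structure(list(values = env[, chans, drop = FALSE],
                      fs = sim$config$fs_emg, t0 = 0, channel_map = chans,
                      provenance = list(cutoff = NA, order = NA,
                                        zero_phase = NA)),
                 class = "envelope")
  bounds <- segment_cycles(sim$events, side = "R")
  normalize_cycles(e, bounds, grid = grid, side = "R")
}
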