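# Envelope extraction, baseline-noise characterization, gait-cycle
# segmentation and 0-100% time normalization.

butter_lowpass <- function(cutoff, order, fs) {
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  if (order < 1) stop("filter order must be >= 1")
  signal::butter(order, cutoff / (fs / 2), type = "low")
}

#' Compute the linear EMG envelope
#'
#' Full-wave rectification followed by low-pass Butterworth filtering
#' (defaults: second order, 6 Hz cutoff). Offline analysis uses zero-phase
#' (forward-backward) filtering; the causal variant applies the same
#' coefficients forward only, as a real-time trigger path must, at the price
#' of group-delay latency.
#'
#' @param rec an [emg_recording()] or numeric matrix/vector.
#' @param cutoff low-pass cutoff, Hz; must be below Nyquist.
#' @param order Butterworth filter order.
#' @param zero_phase use forward-backward filtering (`TRUE`, offline default).
#' @param fs sampling rate; required when `rec` is a bare matrix.
#' @return object of class `envelope`: non-negative matrix `values` of the
#'   same shape as the input plus `fs` and filter provenance.
#' @export
compute_envelope <- function(rec, cutoff = 6, order = 2, zero_phase = TRUE,
                             fs = NULL) {
  if (inherits(rec, "emg_recording")) {
    x <- rec$samples; fs <- rec$fs; t0 <- rec$t0; cm <- rec$channel_map
  } else {
    if (is.null(fs)) stop("fs is required for matrix input")
    x <- as.matrix(rec); t0 <- 0; cm <- colnames(x)
  }
  bf <- butter_lowpass(cutoff, order, fs)
  r <- abs(x)
  out <- matrix(0, nrow(r), ncol(r), dimnames = dimnames(r))
  for (j in seq_len(ncol(r))) {
    f <- if (zero_phase) signal::filtfilt(bf, r[, j])
         else as.numeric(signal::filter(bf, r[, j]))
    out[, j] <- pmax(f, 0)  # ringing can undershoot zero; envelopes are >= 0
  }
  structure(list(values = out, fs = fs, t0 = t0, channel_map = cm,
                 provenance = list(cutoff = cutoff, order = order,
                                   zero_phase = zero_phase)),
            class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("<envelope> %d x %d @ %g Hz (%g Hz order-%d %s Butterworth)\n",
              nrow(x$values), ncol(x$values), x$fs,
              x$provenance$cutoff, x$provenance$order,
              if (x$provenance$zero_phase) "zero-phase" else "causal"))
  invisible(x)
}

#' Characterize baseline (resting) EMG noise
#'
#' Over a quiet window, computes per channel: the mean power `P0` of the raw
#' signal (the quantity the single-threshold onset detector is calibrated
#' from), mean and SD of the rectified raw signal, and mean and SD of the
#' envelope.
#'
#' @param rec an [emg_recording()].
#' @param window `c(start, end)` in seconds (same clock as the recording);
#'   windows of at least 0.5 s are recommended.
#' @param cutoff,order envelope filter parameters, see [compute_envelope()].
#' @return object of class `baseline_stats` with per-channel vectors `P0`,
#'   `rect_mean`, `rect_sd`, `env_mean`, `env_sd`, and the window.
#' @export
estimate_baseline <- function(rec, window, cutoff = 6, order = 2) {
  stopifnot(inherits(rec, "emg_recording"), length(window) == 2)
  tt <- sample_times(rec)
  idx <- which(tt >= window[1] & tt < window[2])
  if (!length(idx)) stop("empty baseline window")
  w <- rec$samples[idx, , drop = FALSE]
  if (cutoff < rec$fs / 2) {
    env <- compute_envelope(rec, cutoff = cutoff, order = order,
                            zero_phase = TRUE)$values[idx, , drop = FALSE]
  } else {
    # recording too slow for the envelope filter: amplitude stats only
    env <- matrix(NA_real_, length(idx), ncol(w))
  }
  structure(list(
    P0 = colMeans(w^2),
    rect_mean = colMeans(abs(w)),
    rect_sd = apply(abs(w), 2, stats::sd),
    env_mean = colMeans(env),
    env_sd = apply(env, 2, stats::sd),
    window = as.numeric(window),
    channel_map = rec$channel_map
  ), class = "baseline_stats")
}

#' @export
print.baseline_stats <- function(x, ...) {
  cat(sprintf("<baseline_stats> window [%.3f, %.3f) s\n",
              x$window[1], x$window[2]))
  print(data.frame(channel = x$channel_map, P0 = x$P0, rms = sqrt(x$P0),
                   env_mean = x$env_mean, env_sd = x$env_sd,
                   row.names = NULL))
  invisible(x)
}

#' Segment gait cycles from foot-contact events
#'
#' Consecutive same-side contact onsets delimit half-open cycles
#' `[start, end)`, so consecutive cycles partition time.
#'
#' @param events a [gait_events()].
#' @param side reference side, `"R"` (default) or `"L"`.
#' @return numeric matrix with columns `start`, `end`, one row per cycle.
#' @export
segment_cycles <- function(events, side = c("R", "L")) {
  side <- match.arg(side)
  on <- if (side == "R") events$right else events$left
  if (length(on) < 2)
    stop("need at least 2 contact onsets on side ", side,
         " to form a gait cycle")
  cbind(start = on[-length(on)], end = on[-1])
}

#' Time-normalize signals onto a 0-100% gait-cycle grid
#'
#' Each cycle is linearly resampled onto `grid` equally spaced points covering
#' `[start, end)` (point k at start + k/grid of the cycle, k = 0..grid-1),
#' i.e. 0% up to but excluding 100%, matching % gait cycle reporting.
#'
#' @param x an `envelope`, [emg_recording()] or [joint_trajectories()].
#' @param bounds cycle bounds from [segment_cycles()].
#' @param grid points per cycle (default 100).
#' @param side reference side recorded as metadata.
#' @return object of class `cycle_matrix`: array `data` of dimension
#'   `n_cycles x grid x n_channels`, plus `cycle_bounds`, `grid`, `side`.
#' @export
normalize_cycles <- function(x, bounds, grid = 100, side = "R") {
  if (grid < 2) stop("grid must be >= 2")
  if (inherits(x, "emg_recording")) {
    mat <- x$samples; fs <- x$fs; t0 <- x$t0; cm <- x$channel_map
  } else if (inherits(x, "envelope")) {
    mat <- x$values; fs <- x$fs; t0 <- x$t0; cm <- x$channel_map
  } else if (inherits(x, "joint_trajectories")) {
    mat <- x$angles; fs <- x$fs; t0 <- x$t0; cm <- x$joint_map
  } else stop("unsupported input type")
  bounds <- matrix(as.numeric(bounds), ncol = 2,
                   dimnames = list(NULL, c("start", "end")))
  if (any(bounds[, 1] >= bounds[, 2])) stop("cycle start must precede end")
  tmax <- t0 + (nrow(mat) - 1) / fs
  if (any(bounds[, 1] < t0) || any(bounds[, 2] > tmax + 1 / fs))
    stop("cycle bounds fall outside the signal")
  nc <- nrow(bounds)
  out <- array(NA_real_, c(nc, grid, ncol(mat)),
               dimnames = list(NULL, NULL, cm))
  frac <- (seq_len(grid) - 1) / grid
  for (i in seq_len(nc)) {
    ts <- bounds[i, 1] + frac * (bounds[i, 2] - bounds[i, 1])
    pos <- (ts - t0) * fs + 1
    lo <- pmin(pmax(floor(pos), 1), nrow(mat))
    hi <- pmin(lo + 1, nrow(mat))
    w <- pos - lo
    out[i, , ] <- mat[lo, , drop = FALSE] * (1 - w) +
      mat[hi, , drop = FALSE] * w
  }
  structure(list(data = out, grid = grid, cycle_bounds = bounds, side = side,
                 channel_map = cm),
            class = "cycle_matrix")
}

#' @export
print.cycle_matrix <- function(x, ...) {
  cat(sprintf("<cycle_matrix> %d cycles x %d points x %d channels (side %s)\n",
              dim(x$data)[1], x$grid, dim(x$data)[3], x$side))
  invisible(x)
}

#' Serialize a cycle matrix to long CSV (+ JSON sidecar of cycle bounds)
#' @param cm a `cycle_matrix`.
#' @param path CSV output path; bounds go to `<path>.bounds.json`.
#' @export
write_cycles <- function(cm, path) {
  d <- dim(cm$data)
  df <- data.frame(
    cycle = rep(seq_len(d[1]), times = d[2] * d[3]),
    point = rep(rep(seq_len(d[2]) - 1L, each = d[1]), times = d[3]),
    channel = rep(cm$channel_map, each = d[1] * d[2]),
    value = as.vector(cm$data)
  )
  con <- file(path, open = "wb")
  writeLines("cycle,point,channel,value", con)
  writeLines(paste(df$cycle, df$point, df$channel, fmt_num(df$value),
                   sep = ","), con)
  close(con)
  jsonlite::write_json(
    list(grid = cm$grid, side = cm$side,
         cycle_bounds = cm$cycle_bounds),
    paste0(path, ".bounds.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cycle matrix written by [write_cycles()]
#' @param path CSV path.
#' @return a `cycle_matrix`.
#' @export
read_cycles <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  side <- jsonlite::read_json(paste0(path, ".bounds.json"),
                              simplifyVector = TRUE)
  chans <- unique(df$channel)
  nc <- max(df$cycle); grid <- max(df$point) + 1L
  arr <- array(NA_real_, c(nc, grid, length(chans)),
               dimnames = list(NULL, NULL, chans))
  arr[cbind(df$cycle, df$point + 1L, match(df$channel, chans))] <- df$value
  structure(list(data = arr, grid = grid,
                 cycle_bounds = matrix(unlist(side$cycle_bounds), ncol = 2,
                                       dimnames = list(NULL, c("start", "end"))),
                 side = side$side, channel_map = chans),
            class = "cycle_matrix")
}
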