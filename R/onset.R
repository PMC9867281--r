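# Single-threshold (ST) onset detection on raw EMG, double-threshold (DT)
# offset detection on the envelope, and baseline-driven threshold calibration.

#' Per-muscle detection thresholds
#'
#' @param h_on named numeric vector, ST onset threshold per muscle (raw
#'   amplitude units); must be positive.
#' @param h_off named numeric vector, DT offset amplitude threshold per muscle
#'   (envelope units); non-negative.
#' @param t_off DT time threshold: minimum sub-threshold dwell, seconds.
#' @param refractory re-arm / trigger refractory period, seconds.
#' @param usable named logical vector; channels flagged unusable by
#'   calibration are excluded from triggering. Defaults to all usable.
#' @param meta calibration metadata (k_on, k_off, baseline window, ...).
#' @return object of class `threshold_set`.
#' @export
threshold_set <- function(h_on, h_off, t_off = 0.05, refractory = 0.4,
                          usable = NULL, meta = list()) {
  if (is.null(names(h_on)) || is.null(names(h_off)))
    stop("h_on and h_off must be named by muscle label")
  if (any(h_on <= 0)) stop("h_on must be positive")
  if (any(h_off < 0)) stop("h_off must be non-negative")
  if (t_off <= 0) stop("t_off must be positive")
  if (refractory < 0) stop("refractory must be non-negative")
  if (is.null(usable)) {
    usable <- stats::setNames(rep(TRUE, length(h_on)), names(h_on))
  }
  structure(list(h_on = h_on, h_off = h_off[names(h_on)], t_off = t_off,
                 refractory = refractory, usable = usable[names(h_on)],
                 meta = meta),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> t_off = %g s, refractory = %g s\n",
              x$t_off, x$refractory))
  print(data.frame(muscle = names(x$h_on), h_on = unname(x$h_on),
                   h_off = unname(x$h_off), usable = unname(x$usable),
                   row.names = NULL))
  invisible(x)
}

# floor used when a channel's baseline power is exactly zero
.H_ON_EPS <- 1e-12

#' Single-threshold onset level from baseline noise power
#'
#' The onset threshold is set from the mean power of the background noise:
#' `h_on = k_on * sqrt(P0)`, i.e. `k_on` times the baseline RMS, which keeps
#' amplitude units.
#'
#' @param base a `baseline_stats` from [estimate_baseline()].
#' @param k_on positive multiplier (default 6; see the methods vignette for
#'   why a single-sample amplitude test needs a high multiple of the noise
#'   RMS to stay silent on baseline noise).
#' @return named numeric vector of per-muscle onset thresholds.
#' @export
st_threshold <- function(base, k_on = 6) {
  if (k_on <= 0) stop("k_on must be positive")
  h <- k_on * sqrt(base$P0)
  zero <- h <= 0
  if (any(zero)) {
    warning("zero baseline power on channel(s) ",
            paste(base$channel_map[zero], collapse = ", "),
            "; onset threshold floored at ", .H_ON_EPS)
    h[zero] <- .H_ON_EPS
  }
  stats::setNames(h, base$channel_map)
}

# first indices where |x| >= h within armed periods; re-arm after `rearm_n`
# samples (refractory re-arming). Returns integer sample indices.
st_scan <- function(x, h, rearm_n) {
  cross <- which(abs(x) >= h)
  if (!length(cross)) return(integer(0))
  out <- integer(0)
  nxt <- 1L  # earliest sample index at which the channel is armed
  for (i in cross) {
    if (i >= nxt) {
      out <- c(out, i)
      nxt <- i + rearm_n
    }
  }
  out
}

#' Detect EMG onsets with the single-threshold (ST) method
#'
#' An onset fires at the first raw sample whose absolute amplitude reaches the
#' channel's threshold while the channel is armed. The single-sample test is
#' what gives the ST method its low detection latency; robustness against
#' false positives is delegated to threshold calibration and the trigger
#' state machine. After an onset the channel re-arms either at the
#' double-threshold offset of that contraction (when `envelope` is supplied)
#' or after the refractory period.
#'
#' @param rec an [emg_recording()].
#' @param thr a [threshold_set()].
#' @param muscles channels to monitor (default: all usable channels present
#'   in both the recording and the threshold set).
#' @param envelope optional `envelope` of `rec`; when given, channels re-arm
#'   at DT offsets instead of after the refractory period.
#' @return data frame of onset events: `muscle`, `time` (s), `sample`,
#'   `path` (`"ST"`), sorted by time.
#' @export
detect_onset_st <- function(rec, thr, muscles = NULL, envelope = NULL) {
  if (is.null(muscles)) {
    muscles <- intersect(names(thr$h_on)[thr$usable], rec$channel_map)
  }
  missing <- setdiff(muscles, rec$channel_map)
  if (length(missing))
    stop("channel(s) not in recording: ", paste(missing, collapse = ", "))
  missing <- setdiff(muscles, names(thr$h_on))
  if (length(missing))
    stop("no calibrated threshold for channel(s): ",
         paste(missing, collapse = ", "))
  rearm_n <- max(1L, round(thr$refractory * rec$fs))
  ev <- lapply(muscles, function(m) {
    x <- rec$samples[, m]
    if (is.null(envelope)) {
      idx <- st_scan(x, thr$h_on[[m]], rearm_n)
    } else {
      idx <- st_scan_offset_rearm(x, envelope$values[, m], thr$h_on[[m]],
                                  thr$h_off[[m]],
                                  max(1L, round(thr$t_off * rec$fs)))
    }
    if (!length(idx)) return(NULL)
    data.frame(muscle = m, time = rec$t0 + (idx - 1) / rec$fs,
               sample = idx, path = "ST")
  })
  ev <- do.call(rbind, ev)
  if (is.null(ev))
    ev <- data.frame(muscle = character(0), time = numeric(0),
                     sample = integer(0), path = character(0))
  ev[order(ev$time, ev$muscle), , drop = FALSE]
}

# onset scan where the channel stays ACTIVE until a DT offset (envelope below
# h_off for >= dwell_n samples); crossings while ACTIVE are ignored
st_scan_offset_rearm <- function(x, env, h_on, h_off, dwell_n) {
  n <- length(x)
  out <- integer(0)
  i <- 1L
  below <- env < h_off
  while (i <= n) {
    cross <- which(abs(x[i:n]) >= h_on)
    if (!length(cross)) break
    on <- i + cross[1L] - 1L
    out <- c(out, on)
    off <- dwell_start(below, from = on + 1L, dwell_n = dwell_n)
    if (is.na(off)) break
    i <- off + dwell_n  # re-armed once the qualifying dwell completes
  }
  out
}

# first index >= from where `below` stays TRUE for dwell_n consecutive
# samples; NA if none
dwell_start <- function(below, from, dwell_n) {
  n <- length(below)
  if (from > n) return(NA_integer_)
  r <- rle(below[from:n])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= dwell_n)
  if (!length(ok)) return(NA_integer_)
  from + starts[ok[1L]] - 1L
}

#' Detect a contraction offset with the double-threshold (DT) method
#'
#' The offset is the first time after the onset at which the envelope stays
#' below the amplitude threshold `h_off` continuously for at least `t_off`
#' seconds. Combining an amplitude and a time threshold trades latency for
#' robustness against transient dips, which is why it is used for offset
#' (end of contraction) rather than onset detection.
#'
#' @param env an `envelope` from [compute_envelope()].
#' @param thr a [threshold_set()].
#' @param onset a single onset event: list/row with `muscle` and `time`.
#' @return one-row data frame (`muscle`, `time` = start of the qualifying
#'   dwell, `dwell` = seconds actually spent below threshold), or `NULL` when
#'   no qualifying dwell exists before the end of the envelope.
#' @export
detect_offset_dt <- function(env, thr, onset) {
  m <- as.character(onset$muscle)
  v <- env$values[, m]
  fs <- env$fs
  start <- round((onset$time - env$t0) * fs) + 2L  # strictly after the onset
  if (start > length(v)) stop("onset lies at or beyond the end of the envelope")
  dwell_n <- max(1L, round(thr$t_off * fs))
  below <- v < thr$h_off[[m]]
  s <- dwell_start(below, from = start, dwell_n = dwell_n)
  if (is.na(s)) return(NULL)
  # dwell = full length of that sub-threshold run
  run_end <- s
  while (run_end <= length(v) && below[run_end]) run_end <- run_end + 1L
  data.frame(muscle = m, time = env$t0 + (s - 1) / fs,
             dwell = (run_end - s) / fs)
}

#' Calibrate detection thresholds from a passive walk
#'
#' Reproduces the tuning procedure run before EMG-triggered walking: the user
#' walks at least two steps per side with the exoskeleton passive; baseline
#' noise is characterized over a quiet-standing window; per-muscle thresholds
#' are derived (`h_on = k_on * baseline RMS`;
#' `h_off = envelope baseline mean + k_off * envelope baseline SD`); and a
#' validation pass flags as unusable any monitored channel that produces no
#' ST onset during the calibration walk (a channel carrying only baseline
#' noise never crosses its own calibrated threshold).
#'
#' @param passive_walk an [emg_recording()] of the passive calibration walk.
#' @param events a [gait_events()] covering the walk; its `baseline_window`
#'   (or the `baseline_window` argument) marks quiet standing.
#' @param k_on,k_off,t_off,refractory detector constants, see
#'   [analysis_config()].
#' @param muscles channels to calibrate (default: the four trigger muscles
#'   present in the recording, else all channels).
#' @param baseline_window optional `c(start, end)` seconds; overrides the one
#'   in `events`.
#' @return a [threshold_set()] with per-channel `usable` flags.
#' @export
calibrate <- function(passive_walk, events, k_on = 6, k_off = 2,
                      t_off = 0.05, refractory = 0.4, muscles = NULL,
                      baseline_window = NULL) {
  if (length(events$left) < 2 || length(events$right) < 2)
    stop("calibration needs at least 2 steps (contact onsets) per side")
  win <- if (!is.null(baseline_window)) baseline_window
         else events$baseline_window
  if (is.null(win))
    stop("no baseline window available (set events$baseline_window)")
  if (is.null(muscles)) {
    trig <- intersect(c("R-Sol", "L-Sol", "R-ReFe", "L-ReFe"),
                      passive_walk$channel_map)
    muscles <- if (length(trig) == 4) trig else passive_walk$channel_map
  }
  base <- estimate_baseline(passive_walk, win)
  keep <- match(muscles, base$channel_map)
  h_on <- st_threshold(base, k_on)[muscles]
  h_off <- stats::setNames(base$env_mean[keep] + k_off * base$env_sd[keep],
                           muscles)
  thr <- threshold_set(h_on, h_off, t_off = t_off, refractory = refractory,
                       meta = list(k_on = k_on, k_off = k_off,
                                   baseline_window = as.numeric(win)))
  # validation pass: walk-time detections decide usability
  walk_start <- min(events$left[1], events$right[1])
  ons <- detect_onset_st(passive_walk, thr, muscles = muscles)
  ons <- ons[ons$time >= walk_start, , drop = FALSE]
  usable <- stats::setNames(muscles %in% ons$muscle, muscles)
  if (!any(usable))
    stop("calibration failed: no channel produced any onset during the walk")
  map <- muscle_step_map()
  if (all(unlist(map[c("R", "L")]) %in% muscles)) {
    for (s in c("R", "L")) {
      if (!any(usable[map[[s]]]))
        stop("calibration failed: both trigger muscles of the ", s,
             " step are unusable")
    }
  }
  if (!all(usable))
    message("channel(s) flagged unusable (no onset detected): ",
            paste(muscles[!usable], collapse = ", "))
  thr$usable <- usable
  thr
}
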