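#' @keywords internal
"_PACKAGE"

# Canonical muscle abbreviations (lower-limb surface EMG montage)
MUSCLES <- c("Sol", "TiAn", "ReFe", "VaLa", "GaMe", "BiFe")
SIDES <- c("L", "R")

#' Canonical muscle labels
#'
#' Labels are `"<side>-<muscle>"` with side `L`/`R` and muscle one of
#' `Sol` (soleus), `TiAn` (tibialis anterior), `ReFe` (rectus femoris),
#' `VaLa` (vastus lateralis), `GaMe` (gastrocnemius medialis),
#' `BiFe` (biceps femoris, long head).
#'
#' @param sides character vector of sides to include.
#' @return character vector of valid labels.
#' @export
muscle_labels <- function(sides = SIDES) {
  as.vector(t(outer(sides, MUSCLES, paste, sep = "-")))
}

is_muscle_label <- function(x) {
  grepl("^[LR]-", x) & sub("^[LR]-", "", x) %in% MUSCLES
}

#' Multichannel surface EMG recording
#'
#' Container for raw multichannel EMG: a numeric sample matrix, the sampling
#' rate, and a channel-to-muscle map. All downstream onset detection and
#' envelope extraction operate on this object.
#'
#' @param samples numeric matrix, `n_samples x n_channels`, amplitude units.
#' @param fs sampling rate in Hz (surface EMG is typically recorded at
#'   2000 Hz).
#' @param channel_map character vector of muscle labels (see
#'   [muscle_labels()]), one per column, no duplicates.
#' @param t0 recording start time in seconds (default 0; all event and
#'   statistic outputs share this clock).
#' @return an object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs, channel_map, t0 = 0) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (length(channel_map) != ncol(samples))
    stop("channel_map length (", length(channel_map),
         ") != number of channels (", ncol(samples), ")")
  bad <- channel_map[!is_muscle_label(channel_map)]
  if (length(bad))
    stop("invalid muscle label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(channel_map))
    stop("duplicate muscle labels in channel_map")
  if (!all(is.finite(samples)))
    stop("samples contain non-finite values")
  colnames(samples) <- channel_map
  structure(
    list(samples = samples, fs = fs, channel_map = as.character(channel_map),
         t0 = t0),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d samples x %d channels @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              nrow(x$samples) / x$fs))
  cat("  channels:", paste(x$channel_map, collapse = ", "), "\n")
  invisible(x)
}

n_samples <- function(rec) nrow(rec$samples)

#' Recording sample times
#' @param rec an [emg_recording()] (or any object with `fs`, `t0` and a
#'   `samples`/`angles` matrix).
#' @return numeric vector of sample times in seconds.
#' @export
sample_times <- function(rec) {
  n <- if (!is.null(rec$samples)) nrow(rec$samples) else nrow(rec$angles)
  rec$t0 + (seq_len(n) - 1) / rec$fs
}

#' Foot-ground contact event series
#'
#' Ordered per-side foot-contact onset times; consecutive same-side contacts
#' delimit gait cycles.
#'
#' @param left,right numeric vectors of contact onset times (s), each strictly
#'   increasing and non-negative.
#' @param source_fs sampling rate (Hz) of the instrument the events came from
#'   (exoskeleton kinematics run at 100 Hz).
#' @param baseline_window optional `c(start, end)` in seconds flagging a
#'   quiet-standing segment usable for baseline-noise estimation.
#' @return object of class `gait_events`.
#' @export
gait_events <- function(left, right, source_fs = 100, baseline_window = NULL) {
  chk <- function(x, nm) {
    x <- as.numeric(x)
    if (any(x < 0)) stop(nm, " contact times must be non-negative")
    if (is.unsorted(x, strictly = TRUE))
      stop(nm, " contact times must be strictly increasing")
    x
  }
  structure(
    list(left = chk(left, "left"), right = chk(right, "right"),
         source_fs = source_fs, baseline_window = baseline_window),
    class = "gait_events"
  )
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d left / %d right contact onsets\n",
              length(x$left), length(x$right)))
  invisible(x)
}

#' Joint-angle trajectory set
#'
#' @param angles numeric matrix `n_samples x n_joints`, degrees.
#' @param fs sampling rate in Hz.
#' @param joint_map character vector `"<side>-<joint>"`, joint one of
#'   hip/knee/ankle, one entry per column.
#' @param positive_flexion if `TRUE` (default) positive values mean knee
#'   flexion, hip flexion and ankle dorsiflexion.
#' @param t0 start time (s).
#' @return object of class `joint_trajectories`.
#' @export
joint_trajectories <- function(angles, fs, joint_map, positive_flexion = TRUE,
                               t0 = 0) {
  angles <- as.matrix(angles)
  storage.mode(angles) <- "double"
  if (fs <= 0) stop("fs must be positive")
  if (length(joint_map) != ncol(angles))
    stop("joint_map must cover all columns")
  ok <- grepl("^[LR]-(hip|knee|ankle)$", joint_map)
  if (!all(ok))
    stop("invalid joint label(s): ", paste(joint_map[!ok], collapse = ", "))
  colnames(angles) <- joint_map
  structure(
    list(angles = angles, fs = fs, joint_map = as.character(joint_map),
         positive_flexion = isTRUE(positive_flexion), t0 = t0),
    class = "joint_trajectories"
  )
}

#' @export
print.joint_trajectories <- function(x, ...) {
  cat(sprintf("<joint_trajectories> %d samples x %d joints @ %g Hz\n",
              nrow(x$angles), ncol(x$angles), x$fs))
  cat("  joints:", paste(x$joint_map, collapse = ", "), "\n")
  invisible(x)
}

#' Walking-condition metadata
#'
#' Identifies the exoskeleton control condition a trial was recorded under:
#' `TC` (trajectory control), `AC` (admittance control) or `OC` (EMG-onset
#' control). `alpha` is the admittance controller's allowed tracking-error
#' fraction; it is carried as metadata only.
#'
#' @param condition one of `"TC"`, `"AC"`, `"OC"`.
#' @param alpha allowed tracking-error fraction in `[0, 1]` (default 0.30).
#' @export
condition_config <- function(condition = c("TC", "AC", "OC"), alpha = 0.30) {
  condition <- match.arg(condition)
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  structure(list(condition = condition, alpha = alpha),
            class = "condition_config")
}

#' Analysis configuration
#'
#' Collects the tunable parameters of the offline pipeline with their
#' defaults: 6 Hz second-order Butterworth envelope, 100-point cycle grid,
#' 4 synergies, and the onset/offset detector constants.
#'
#' @param envelope_cutoff low-pass cutoff for the EMG envelope, Hz.
#' @param filter_order Butterworth order.
#' @param cycle_grid points per normalized gait cycle (0-100%).
#' @param n_synergies number of synergies extracted by NMF.
#' @param nmf_restarts random restarts for NMF.
#' @param nmf_seed RNG seed used for NMF initializations.
#' @param k_on single-threshold onset multiplier: onset threshold is
#'   `k_on * sqrt(baseline mean power)`.
#' @param k_off double-threshold offset amplitude multiplier: offset
#'   threshold is envelope baseline mean + `k_off` envelope baseline SDs.
#' @param t_off double-threshold dwell duration, s.
#' @param refractory trigger refractory period, s.
#' @param map_convention muscle-to-step pairing convention, see
#'   [muscle_step_map()].
#' @param alpha_significance significance level for condition comparisons.
#' @export
analysis_config <- function(envelope_cutoff = 6, filter_order = 2,
                            cycle_grid = 100, n_synergies = 4,
                            nmf_restarts = 20, nmf_seed = 1,
                            k_on = 6, k_off = 2, t_off = 0.05,
                            refractory = 0.4,
                            map_convention = "table2",
                            alpha_significance = 0.05) {
  cfg <- list(envelope_cutoff = envelope_cutoff, filter_order = filter_order,
              cycle_grid = cycle_grid, n_synergies = n_synergies,
              nmf_restarts = nmf_restarts, nmf_seed = nmf_seed,
              k_on = k_on, k_off = k_off, t_off = t_off,
              refractory = refractory, map_convention = map_convention,
              alpha_significance = alpha_significance)
  num <- cfg[!(names(cfg) %in% "map_convention")]
  if (any(unlist(num) <= 0))
    stop("all numeric analysis_config parameters must be positive")
  if (cycle_grid < 2) stop("cycle_grid must be >= 2")
  structure(cfg, class = "analysis_config")
}
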