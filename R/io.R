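# Delimited-text readers/writers. Dialect: comma-separated, "." decimal,
# UTF-8, one header row. Numbers are written with 15 significant digits so a
# write/read round trip preserves >= 12 significant digits.

fmt_num <- function(x) sprintf("%.15g", x)

# read a numeric CSV body, reporting the first bad cell by row and column name
read_numeric_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  mat <- suppressWarnings(
    vapply(raw, as.numeric, numeric(nrow(raw)))
  )
  if (nrow(raw) == 1L) mat <- matrix(mat, nrow = 1L,
                                     dimnames = list(NULL, names(raw)))
  bad <- which(!is.finite(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or non-finite value at row %d, column '%s'",
                 bad[1, 1], colnames(mat)[bad[1, 2]]))
  }
  mat
}

#' Read a multichannel EMG recording from CSV
#'
#' The file must have one header row of channel names and a numeric body, one
#' column per channel.
#'
#' @param path CSV file path.
#' @param channel_map channel-to-muscle map. Either `NULL` (header names are
#'   taken as muscle labels, file column order kept) or a character vector of
#'   muscle labels naming a subset/reordering of the header columns.
#' @param fs sampling rate in Hz.
#' @param t0 start time (s).
#' @return an [emg_recording()].
#' @export
read_emg <- function(path, channel_map = NULL, fs = 2000, t0 = 0) {
  if (fs <= 0) stop("fs must be positive")
  mat <- read_numeric_csv(path)
  if (is.null(channel_map)) {
    channel_map <- colnames(mat)
  } else {
    missing <- setdiff(channel_map, colnames(mat))
    if (length(missing))
      stop("channel(s) in map absent from file header: ",
           paste(missing, collapse = ", "))
    mat <- mat[, channel_map, drop = FALSE]
  }
  emg_recording(mat, fs = fs, channel_map = channel_map, t0 = t0)
}

#' Write an EMG recording to CSV
#' @param rec an [emg_recording()].
#' @param path output file path.
#' @export
write_emg <- function(rec, path) {
  write_matrix_csv(rec$samples, path)
}

write_matrix_csv <- function(mat, path) {
  con <- file(path, open = "wb")  # binary: fixed "\n" endings on all platforms
  on.exit(close(con))
  writeLines(paste(colnames(mat), collapse = ","), con)
  body <- apply(mat, 1L, function(r) paste(fmt_num(r), collapse = ","))
  writeLines(body, con)
  invisible(path)
}

#' Read foot-contact events from CSV
#'
#' Expected columns: `side` (`L`/`R`) and `time` (seconds), times sorted
#' (strictly increasing) within each side.
#'
#' @param path CSV file path.
#' @param source_fs sampling rate of the event source, Hz.
#' @return a [gait_events()].
#' @export
read_events <- function(path, source_fs = 100) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (!all(c("side", "time") %in% names(df)))
    stop("events file needs 'side' and 'time' columns")
  if (!all(df$side %in% c("L", "R")))
    stop("side column must contain only 'L' or 'R'")
  tm <- suppressWarnings(as.numeric(df$time))
  if (any(!is.finite(tm)))
    stop("non-numeric time at row ", which(!is.finite(tm))[1])
  gait_events(left = tm[df$side == "L"], right = tm[df$side == "R"],
              source_fs = source_fs)
}

#' Write foot-contact events to CSV
#' @param events a [gait_events()].
#' @param path output file path.
#' @export
write_events <- function(events, path) {
  df <- rbind(
    data.frame(side = rep("L", length(events$left)), time = events$left),
    data.frame(side = rep("R", length(events$right)), time = events$right)
  )
  df <- df[order(df$time, df$side), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("side,time", con)
  if (nrow(df))
    writeLines(paste(df$side, fmt_num(df$time), sep = ","), con)
  invisible(path)
}

#' Read joint-angle trajectories from CSV
#' @param path CSV file path (header = joint labels, numeric body in degrees).
#' @param joint_map optional subset/reorder of header columns.
#' @param fs sampling rate in Hz (exoskeleton kinematics: 100 Hz).
#' @param t0 start time (s).
#' @return a [joint_trajectories()].
#' @export
read_angles <- function(path, joint_map = NULL, fs = 100, t0 = 0) {
  mat <- read_numeric_csv(path)
  if (is.null(joint_map)) {
    joint_map <- colnames(mat)
  } else {
    missing <- setdiff(joint_map, colnames(mat))
    if (length(missing))
      stop("joint(s) in map absent from file header: ",
           paste(missing, collapse = ", "))
    mat <- mat[, joint_map, drop = FALSE]
  }
  joint_trajectories(mat, fs = fs, joint_map = joint_map, t0 = t0)
}

#' Write joint-angle trajectories to CSV
#' @param traj a [joint_trajectories()].
#' @param path output file path.
#' @export
write_angles <- function(traj, path) {
  write_matrix_csv(traj$angles, path)
}

#' Read/write a threshold set as JSON
#'
#' @param path JSON file path.
#' @return [read_thresholds()] returns a [threshold_set()].
#' @export
read_thresholds <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  threshold_set(h_on = unlist(x$h_on), h_off = unlist(x$h_off),
                t_off = x$t_off, refractory = x$refractory,
                usable = if (is.null(x$usable)) NULL else unlist(x$usable),
                meta = x$meta)
}

#' @rdname read_thresholds
#' @param thr a [threshold_set()].
#' @export
write_thresholds <- function(thr, path) {
  x <- unclass(thr)
  # named vectors must serialize as JSON objects, not bare arrays
  for (f in c("h_on", "h_off", "usable")) x[[f]] <- as.list(x[[f]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
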