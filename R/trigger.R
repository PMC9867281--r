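# Step-trigger state machine over redundant muscle pairs, onset-timing
# (% gait cycle) statistics and per-muscle detection shares.

#' Muscle-to-step trigger mapping
#'
#' Each step side is triggered by the first onset in either of two redundant
#' muscles. Two pairing conventions are in circulation for this controller
#' and they disagree, so the convention is explicit:
#' \describe{
#'   \item{`"table2"` (default)}{a side's step is triggered by the
#'     ipsilateral rectus femoris or the contralateral soleus: right step
#'     from \{R-ReFe, L-Sol\}, left step from \{L-ReFe, R-Sol\}.}
#'   \item{`"sec233"`}{the opposite pairing: right step from
#'     \{R-Sol, L-ReFe\}, left step from \{L-Sol, R-ReFe\}.}
#' }
#'
#' @param convention `"table2"` or `"sec233"`.
#' @return object of class `muscle_step_map`: list with character vectors
#'   `R` and `L` of trigger muscles per step side.
#' @export
muscle_step_map <- function(convention = c("table2", "sec233")) {
  convention <- match.arg(convention)
  map <- if (convention == "table2") {
    list(R = c("R-ReFe", "L-Sol"), L = c("L-ReFe", "R-Sol"))
  } else {
    list(R = c("R-Sol", "L-ReFe"), L = c("L-Sol", "R-ReFe"))
  }
  structure(c(map, convention = convention), class = "muscle_step_map")
}

#' @export
print.muscle_step_map <- function(x, ...) {
  cat(sprintf("<muscle_step_map> (%s)\n  right step: %s\n  left step:  %s\n",
              x$convention, paste(x$R, collapse = " | "),
              paste(x$L, collapse = " | ")))
  invisible(x)
}

#' Run the step-trigger state machine
#'
#' Finite-state machine implementing the EMG-onset step controller: while
#' awaiting a step on one side, the first ST onset from either of that side's
#' two trigger muscles emits a step command; the controller then holds a
#' refractory period and switches to awaiting the opposite side. Onsets from
#' non-pending muscles or during the refractory period are recorded but
#' ignored — the exoskeleton executes strictly alternating steps. The
#' two-muscle redundancy keeps the controller live when one channel is
#' unusable.
#'
#' @param rec an [emg_recording()] containing the four trigger muscles.
#' @param thr a calibrated [threshold_set()]; unusable channels are skipped.
#' @param map a [muscle_step_map()].
#' @param start_side side awaited first (`"R"` or `"L"`).
#' @return object of class `trigger_run`: `commands` (data frame `side`,
#'   `time`, `muscle`, `sample`), `ignored` (same columns plus `reason`), the
#'   map and threshold metadata.
#' @export
run_trigger <- function(rec, thr, map = muscle_step_map(), start_side = "R") {
  stopifnot(inherits(map, "muscle_step_map"), start_side %in% c("R", "L"))
  usable <- names(thr$usable)[thr$usable]
  for (s in c("R", "L")) {
    if (!any(map[[s]] %in% usable))
      stop("both trigger muscles for the ", s,
           " step are unusable; controller cannot run")
  }
  monitored <- intersect(unlist(map[c("R", "L")]), usable)
  onsets <- detect_onset_st(rec, thr, muscles = monitored)
  pending <- start_side
  refr_end <- -Inf
  acc <- ign <- list()
  for (i in seq_len(nrow(onsets))) {
    o <- onsets[i, ]
    if (o$time < refr_end) {
      ign[[length(ign) + 1L]] <- cbind(o, reason = "refractory")
    } else if (o$muscle %in% map[[pending]]) {
      acc[[length(acc) + 1L]] <- data.frame(side = pending, time = o$time,
                                            muscle = o$muscle,
                                            sample = o$sample)
      refr_end <- o$time + thr$refractory
      pending <- if (pending == "R") "L" else "R"
    } else {
      ign[[length(ign) + 1L]] <- cbind(o, reason = "wrong_side")
    }
  }
  empty_cmd <- data.frame(side = character(0), time = numeric(0),
                          muscle = character(0), sample = integer(0))
  structure(list(
    commands = if (length(acc)) do.call(rbind, acc) else empty_cmd,
    ignored = if (length(ign)) do.call(rbind, ign)
              else data.frame(muscle = character(0), time = numeric(0),
                              sample = integer(0), path = character(0),
                              reason = character(0)),
    map = map, start_side = start_side,
    refractory = thr$refractory, usable = thr$usable
  ), class = "trigger_run")
}

#' @export
print.trigger_run <- function(x, ...) {
  cat(sprintf("<trigger_run> %d step commands (%d onsets ignored)\n",
              nrow(x$commands), nrow(x$ignored)))
  if (nrow(x$commands)) {
    sh <- detection_shares(x)
    print(sh)
  }
  invisible(x)
}

#' Onset timing as % of the gait cycle
#'
#' Maps each accepted trigger onset to its phase within the containing
#' reference-side gait cycle, `100 * (t - start) / (end - start)`, and
#' summarizes mean and SD per muscle.
#'
#' @param run a `trigger_run` (or a data frame with `muscle` and `time`).
#' @param bounds cycle bounds from [segment_cycles()] (reference side).
#' @return object of class `trigger_stats`: data frame `onsets` with a
#'   `phase` column, and `summary` per muscle (`n`, `mean_phase`, `sd_phase`).
#' @export
onset_cycle_stats <- function(run, bounds) {
  ev <- if (inherits(run, "trigger_run")) run$commands else run
  if (nrow(bounds) < 1) stop("need at least one gait cycle")
  idx <- findInterval(ev$time, bounds[, 1])
  inside <- idx >= 1 & idx <= nrow(bounds) &
    ev$time < bounds[pmax(pmin(idx, nrow(bounds)), 1L), 2]
  if (any(!inside))
    warning(sum(!inside), " onset(s) outside all cycles excluded")
  ev <- ev[inside, , drop = FALSE]
  idx <- idx[inside]
  ev$cycle <- idx
  ev$phase <- 100 * (ev$time - bounds[idx, 1]) /
    (bounds[idx, 2] - bounds[idx, 1])
  agg <- do.call(rbind, lapply(split(ev$phase, ev$muscle), function(p) {
    data.frame(n = length(p), mean_phase = mean(p),
               sd_phase = if (length(p) > 1) stats::sd(p) else NA_real_)
  }))
  agg <- cbind(muscle = rownames(agg), agg)
  rownames(agg) <- NULL
  structure(list(onsets = ev, summary = agg), class = "trigger_stats")
}

#' @export
print.trigger_stats <- function(x, ...) {
  cat("<trigger_stats> onset phase (% gait cycle)\n")
  print(transform(x$summary, mean_phase = round(mean_phase, 2),
                  sd_phase = round(sd_phase, 2)))
  invisible(x)
}

#' Per-muscle detection shares
#'
#' Share of all accepted trigger onsets attributed to each monitored muscle:
#' `share(m) = 100 * accepted onsets from m / total accepted onsets`. A
#' channel flagged unusable contributes no onsets, hence a 0.00% share.
#'
#' @param run a `trigger_run`, or a data frame of accepted onsets with a
#'   `muscle` column.
#' @param muscles muscles to report (default: the trigger map's four muscles
#'   when `run` is a `trigger_run`, else the muscles present).
#' @return data frame `muscle`, `n`, `share` (percent; shares sum to 100).
#' @export
detection_shares <- function(run, muscles = NULL) {
  if (inherits(run, "trigger_run")) {
    ev <- run$commands
    if (is.null(muscles)) muscles <- unlist(run$map[c("R", "L")])
  } else {
    ev <- run
    if (is.null(muscles)) muscles <- sort(unique(ev$muscle))
  }
  if (nrow(ev) == 0) stop("no accepted onsets; shares are undefined")
  counts <- table(factor(ev$muscle, levels = muscles))
  data.frame(muscle = muscles, n = as.integer(counts),
             share = 100 * as.integer(counts) / nrow(ev),
             row.names = NULL)
}
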