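# Per-cycle joint-angle summaries (max/min/ROM) and nonparametric condition
# comparison (Friedman + post-hoc Wilcoxon signed-rank with Bonferroni).

#' Per-cycle joint-angle extrema and range of motion
#'
#' For each gait cycle and joint: maximum and minimum angle (degrees) and
#' range of motion `ROM = max - min`, plus aggregates across cycles (mean,
#' SD, median, max, min) per joint.
#'
#' @param cm a `cycle_matrix` of joint angles (from [normalize_cycles()] on a
#'   [joint_trajectories()]).
#' @return object of class `cycle_summary`: `per_cycle` data frame (`cycle`,
#'   `joint`, `max`, `min`, `rom`) and `aggregate` data frame (`joint`,
#'   `variable`, mean/sd/median/max/min columns).
#' @export
joint_cycle_stats <- function(cm) {
  d <- dim(cm$data)
  if (d[1] < 1) stop("need at least one cycle")
  per <- do.call(rbind, lapply(seq_len(d[3]), function(j) {
    mx <- apply(cm$data[, , j, drop = FALSE], 1, max)
    mn <- apply(cm$data[, , j, drop = FALSE], 1, min)
    data.frame(cycle = seq_len(d[1]), joint = cm$channel_map[j],
               max = mx, min = mn, rom = mx - mn)
  }))
  rownames(per) <- NULL
  agg <- do.call(rbind, lapply(split(per, per$joint), function(g) {
    do.call(rbind, lapply(c("max", "min", "rom"), function(v) {
      x <- g[[v]]
      data.frame(joint = g$joint[1], variable = v, mean = mean(x),
                 sd = stats::sd(x), median = stats::median(x),
                 max = max(x), min = min(x))
    }))
  }))
  rownames(agg) <- NULL
  structure(list(per_cycle = per, aggregate = agg), class = "cycle_summary")
}

#' @export
print.cycle_summary <- function(x, ...) {
  cat(sprintf("<cycle_summary> %d cycles x %d joints\n",
              max(x$per_cycle$cycle), length(unique(x$per_cycle$joint))))
  print(transform(x$aggregate, mean = round(mean, 2), sd = round(sd, 2),
                  median = round(median, 2), max = round(max, 2),
                  min = round(min, 2)))
  invisible(x)
}

#' Compare walking conditions with the Friedman / Wilcoxon / Bonferroni chain
#'
#' Repeated-measures nonparametric comparison: a Friedman test across
#' conditions, followed by all pairwise Wilcoxon signed-rank tests with
#' Bonferroni correction (`p_adj = min(1, p_raw * n_pairs)`). With the
#' protected (default) convention, pairwise flags are only raised when the
#' Friedman test itself rejects at `alpha`; the unprotected convention flags
#' on the adjusted pairwise p-values alone. Exact signed-rank distributions
#' are used for n <= 25 subjects (mid-rank handling of ties via the normal
#' approximation, as usual).
#'
#' @param values numeric matrix or data frame, subjects x conditions (named
#'   columns). Subjects with any missing condition are excluded listwise.
#' @param alpha significance level (default 0.05).
#' @param protected gate the post-hoc flags on the Friedman rejection
#'   (default `TRUE`).
#' @param variable optional label carried into the result.
#' @return object of class `comparison_result`: Friedman statistic/p, data
#'   frame `pairwise` (`a`, `b`, `p_raw`, `p_adj`, `significant`), `alpha`,
#'   `protected`, `n_subjects`.
#' @export
compare_conditions <- function(values, alpha = 0.05, protected = TRUE,
                               variable = NA_character_) {
  values <- as.matrix(values)
  if (ncol(values) < 2) stop("need at least 2 conditions")
  complete <- stats::complete.cases(values)
  if (any(!complete)) {
    message(sum(!complete), " subject(s) with missing conditions excluded")
    values <- values[complete, , drop = FALSE]
  }
  if (nrow(values) < 2) stop("need at least 2 complete subjects")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("cond", seq_len(ncol(values)))
  fr <- stats::friedman.test(values)
  if (!is.finite(fr$statistic)) {
    # fully tied ranks: no evidence of any difference
    fr$statistic[] <- 0
    fr$p.value <- 1
  }
  pairs <- utils::combn(colnames(values), 2)
  n <- nrow(values)
  p_raw <- apply(pairs, 2, function(pr) {
    d <- values[, pr[1]] - values[, pr[2]]
    if (all(d == 0)) return(1)  # identical samples carry no signal
    suppressWarnings(
      stats::wilcox.test(values[, pr[1]], values[, pr[2]], paired = TRUE,
                         exact = n <= 25)$p.value)
  })
  p_adj <- stats::p.adjust(p_raw, method = "bonferroni")
  gate <- if (protected) fr$p.value < alpha else TRUE
  structure(list(
    variable = variable,
    friedman_stat = unname(fr$statistic), friedman_p = fr$p.value,
    pairwise = data.frame(a = pairs[1, ], b = pairs[2, ], p_raw = p_raw,
                          p_adj = p_adj,
                          significant = gate & (p_adj < alpha)),
    alpha = alpha, protected = protected, n_subjects = n
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result>%s Friedman chi-sq = %.3f, p = %.4g (n = %d)\n",
              if (is.na(x$variable)) "" else paste0(" [", x$variable, "]"),
              x$friedman_stat, x$friedman_p, x$n_subjects))
  cat(sprintf("  post-hoc Wilcoxon signed-rank, Bonferroni-adjusted (%s)\n",
              if (x$protected) "protected" else "unprotected"))
  print(transform(x$pairwise, p_raw = signif(p_raw, 3),
                  p_adj = signif(p_adj, 3)))
  invisible(x)
}
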