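# Merged JSON report of the analysis outputs.

#' Write a merged analysis report as JSON
#'
#' Collects any of the pipeline's result objects — trigger statistics,
#' detection shares, synergy pattern statistics, joint-cycle summaries,
#' condition comparisons — into one JSON document.
#'
#' @param path output JSON path.
#' @param trigger_stats a `trigger_stats` from [onset_cycle_stats()].
#' @param shares a detection-share data frame from [detection_shares()].
#' @param synergies a `synergy_fit`; its VAF, W and pattern stats are stored.
#' @param kinematics a `cycle_summary` from [joint_cycle_stats()].
#' @param comparisons a list of `comparison_result` objects.
#' @param extra named list of extra fields to merge in.
#' @return the path, invisibly.
#' @export
write_report <- function(path, trigger_stats = NULL, shares = NULL,
                         synergies = NULL, kinematics = NULL,
                         comparisons = NULL, extra = list()) {
  rep <- list()
  if (!is.null(trigger_stats))
    rep$onset_phase <- trigger_stats$summary
  if (!is.null(shares))
    rep$detection_shares <- shares
  if (!is.null(synergies))
    rep$synergies <- list(vaf = synergies$vaf, n_syn = synergies$n_syn,
                          W = synergies$W,
                          pattern_stats = pattern_stats(synergies))
  if (!is.null(kinematics))
    rep$kinematics <- kinematics$aggregate
  if (!is.null(comparisons)) {
    if (inherits(comparisons, "comparison_result"))
      comparisons <- list(comparisons)
    rep$comparisons <- lapply(comparisons, function(cc) {
      list(variable = cc$variable, friedman_stat = cc$friedman_stat,
           friedman_p = cc$friedman_p, pairwise = cc$pairwise,
           alpha = cc$alpha, protected = cc$protected)
    })
  }
  rep <- c(rep, extra)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
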