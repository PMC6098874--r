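#' Run the full model for one or more strategies
#'
#' Convenience wrapper: builds the strategy catalog, runs the cohort for
#' each requested strategy and summarises lifetime outcomes.
#'
#' @param p An `endocea_params` object.
#' @param lt A [life_table()].
#' @param strategies Character vector of strategy names (subset of
#'   `"tamoxifen"`, `"ai_5yr"`, `"ai_switch"`).
#' @return Named list of `endocea_outcomes`, one per strategy.
#' @examples
#' lt <- synth_life_table()
#' res <- run_model(default_params(), lt, strategies = "tamoxifen")
#' res$tamoxifen
#' @export
run_model <- function(p = default_params(), lt,
                      strategies = c("tamoxifen", "ai_5yr", "ai_switch")) {
  cat_all <- strategy_catalog(p)
  bad <- setdiff(strategies, names(cat_all))
  if (length(bad))
    stop(sprintf("unknown strategy: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  stats::setNames(lapply(strategies, function(nm)
    summarize(run_cohort(cat_all[[nm]], p, lt))), strategies)
}

#' Base-case comparison table
#'
#' Runs all three strategies and returns the pairwise incremental
#' comparisons of each letrozole strategy against tamoxifen and of the
#' 5-year letrozole strategy against the switch strategy.
#'
#' @inheritParams run_model
#' @return List with elements `outcomes` (per-strategy) and `comparisons`
#'   (named list of `endocea_comparison`).
#' @export
base_case <- function(p = default_params(), lt) {
  out <- run_model(p, lt)
  cmp <- list(
    ai_5yr_vs_tamoxifen  = compare(out$ai_5yr, out$tamoxifen),
    ai_switch_vs_tamoxifen = compare(out$ai_switch, out$tamoxifen),
    ai_5yr_vs_ai_switch  = compare(out$ai_5yr, out$ai_switch))
  list(outcomes = out, comparisons = cmp)
}
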