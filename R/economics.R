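# Costing, utilities, discounting, lifetime outcomes and ICERs ---------------

#' Per-cycle discount factor
#'
#' Continuous-compounding-free annual discounting applied at monthly
#' resolution: `(1 + annual_rate)^(-cycle/12)`.
#'
#' @param cycle Cycle index in months (vectorised), `>= 0`.
#' @param annual_rate Annual discount rate in `[0, 1)`.
#' @return Discount factor(s) in `(0, 1]`.
#' @examples
#' discount_factor(12, 0.05)  # one year out: 1/1.05
#' @export
discount_factor <- function(cycle, annual_rate) {
  if (any(cycle < 0)) stop("'cycle' must be non-negative", call. = FALSE)
  if (annual_rate < 0 || annual_rate >= 1)
    stop("'annual_rate' must lie in [0, 1)", call. = FALSE)
  (1 + annual_rate)^(-cycle / 12)
}

#' Joint utility of two co-occurring conditions
#'
#' Combines the utilities of two simultaneous health conditions (here:
#' disease-free survival and a prior bone fracture). The default model is
#' the anchored form
#' \deqn{U_{ij} = U_{min} - U_{min}(1 - U_i)(1 - U_j)}
#' with \eqn{U_{min} = \min(U_i, U_j)}; it is symmetric, never exceeds the
#' worse of the two utilities, and reduces to \eqn{U_i} when the partner
#' utility is 1. The conventional multiplicative model \eqn{U_i U_j} is
#' available as an alternative for sensitivity analysis.
#'
#' @param u_i,u_j Utilities in `[0, 1]`.
#' @param model `"anchored"` (default) or `"multiplicative"`.
#' @return The joint utility.
#' @examples
#' joint_utility(0.94, 0.70)
#' @export
joint_utility <- function(u_i, u_j, model = c("anchored", "multiplicative")) {
  model <- match.arg(model)
  if (any(u_i < 0 | u_i > 1 | u_j < 0 | u_j > 1))
    stop("utilities must lie in [0, 1]", call. = FALSE)
  if (model == "multiplicative") return(u_i * u_j)
  u_min <- pmin(u_i, u_j)
  u_min - u_min * (1 - u_i) * (1 - u_j)
}

#' Utility weight of a health state for one cycle
#'
#' @param state Health state name (see [transition_row()]).
#' @param on_therapy Logical; whether adjuvant endocrine therapy is being
#'   taken this cycle (its disutility applies only in the disease-free
#'   states, where therapy continues).
#' @param p An `endocea_params` object.
#' @return Utility in `[0, 1]` (0 for the dead state).
#' @export
cycle_utility <- function(state, on_therapy, p) {
  stopifnot(inherits(p, "endocea_params"))
  u <- p$utilities
  base <- switch(state,
    disease_free = u$u_dfs,
    disease_free_fracture = joint_utility(u$u_dfs, u$u_fracture,
                                          p$options$joint_utility_model),
    local_recurrence = ,
    contralateral_recurrence = u$u_regional,
    distant_recurrence = u$u_distant,
    endometrial_cancer = u$u_endometrial,
    dead = 0,
    stop(sprintf("unknown health state '%s'", state), call. = FALSE))
  if (on_therapy && state %in% c("disease_free", "disease_free_fracture"))
    base <- max(0, base - u$disutility_endocrine)
  base
}

#' Cost of occupying a health state for one cycle
#'
#' Drug acquisition cost (daily price times days per month) accrues while
#' the strategy's schedule is active and the woman is disease-free. The
#' recurrence states cost their monthly management value; under the
#' `recurrence_entry_cost = "first_month"` model option the separately
#' tabulated first-month management value is charged in the entry month
#' instead (the default, `"monthly"`, charges the monthly value throughout
#' and reproduces the published lifetime cost totals). One-time event costs
#' (fracture, endometrial cancer) are handled separately at incidence by
#' [summarize()].
#'
#' @param state Health state name.
#' @param months_in_state Months since entering the state (0 = entry month).
#' @param s An `endocea_strategy`.
#' @param cycle Model month.
#' @param p An `endocea_params` object.
#' @return Cost in CNY for the cycle.
#' @export
cycle_cost <- function(state, months_in_state, s, cycle, p) {
  stopifnot(inherits(s, "endocea_strategy"), inherits(p, "endocea_params"))
  co <- p$costs
  switch(state,
    disease_free = ,
    disease_free_fracture = {
      drug <- .drug_at(s, cycle)
      if (is.na(drug)) 0
      else p$econ$days_per_month *
        switch(drug, tamoxifen = co$daily_tamoxifen,
               letrozole = co$daily_letrozole)
    },
    local_recurrence = ,
    contralateral_recurrence =
      if (months_in_state == 0 &&
          identical(p$options$recurrence_entry_cost, "first_month"))
        co$locoregional_first_month
      else co$locoregional_subsequent,
    distant_recurrence =
      if (months_in_state == 0 &&
          identical(p$options$recurrence_entry_cost, "first_month"))
        co$distant_first_month
      else co$distant_subsequent,
    endometrial_cancer = 0,  # costed once per patient at incidence
    dead = 0,
    stop(sprintf("unknown health state '%s'", state), call. = FALSE))
}

#' Lifetime outcomes of a cohort trace
#'
#' Aggregates a [run_cohort()] trace into lifetime outcomes: discounted
#' cost, discounted QALYs, undiscounted life-years (and progression-free
#' life-years), and the lifetime cumulative event probabilities. Costs and
#' QALYs are discounted per cycle at the annual rate; one-time event costs
#' are discounted at their incidence cycle. With
#' `p$options$half_cycle_correction` the state-membership accruals use the
#' mean of successive trace rows.
#'
#' @param trace A `cohort_trace`.
#' @param s The `endocea_strategy` that produced it (defaults to the one
#'   attached to the trace).
#' @param p The `endocea_params` used (defaults to those attached).
#' @return An object of class `endocea_outcomes`: list with
#'   `discounted_cost`, `discounted_qalys`, `life_years`,
#'   `pf_life_years`, `discounted_life_years`, `event_cumulatives` and
#'   `strategy`.
#' @export
summarize <- function(trace, s = attr(trace, "strategy"),
                      p = attr(trace, "params")) {
  stopifnot(inherits(trace, "cohort_trace"),
            inherits(s, "endocea_strategy"), inherits(p, "endocea_params"))
  n <- nrow(trace) - 1L            # accrual rows: cycles 0 .. n-1
  t_idx <- trace$cycle[seq_len(n)]
  disc <- discount_factor(t_idx, p$econ$annual_discount)

  occ <- trace[, c("disease_free", "disease_free_fracture", "local",
                   "local_entry", "contralateral", "contralateral_entry",
                   "distant", "distant_entry", "endometrial")]
  m <- as.matrix(occ)
  if (isTRUE(p$options$half_cycle_correction))
    m <- (m[seq_len(n), , drop = FALSE] +
            m[seq_len(n) + 1L, , drop = FALSE]) / 2
  else
    m <- m[seq_len(n), , drop = FALSE]

  # drug cost while disease-free and on schedule
  drug_daily <- vapply(t_idx, function(t) {
    d <- .drug_at(s, t)
    if (is.na(d)) 0
    else switch(d, tamoxifen = p$costs$daily_tamoxifen,
                letrozole = p$costs$daily_letrozole)
  }, numeric(1))
  dfs_occ <- m[, "disease_free"] + m[, "disease_free_fracture"]
  cost_drug <- dfs_occ * drug_daily * p$econ$days_per_month
  loco_entry <- if (identical(p$options$recurrence_entry_cost, "first_month"))
    p$costs$locoregional_first_month else p$costs$locoregional_subsequent
  dist_entry_cost <- if (identical(p$options$recurrence_entry_cost, "first_month"))
    p$costs$distant_first_month else p$costs$distant_subsequent
  cost_states <-
    (m[, "local_entry"] + m[, "contralateral_entry"]) * loco_entry +
    (m[, "local"] - m[, "local_entry"] +
       m[, "contralateral"] - m[, "contralateral_entry"]) *
      p$costs$locoregional_subsequent +
    m[, "distant_entry"] * dist_entry_cost +
    (m[, "distant"] - m[, "distant_entry"]) * p$costs$distant_subsequent
  cost_events <- trace$inc_fracture[seq_len(n)] * p$costs$fracture_per_event +
    trace$inc_endometrial[seq_len(n)] * p$costs$endometrial_per_patient
  discounted_cost <- sum(disc * (cost_drug + cost_states + cost_events))

  # utilities per cycle
  on_therapy <- vapply(t_idx, function(t) !is.na(.drug_at(s, t)), logical(1))
  u_dfs_t <- ifelse(on_therapy,
                    pmax(0, p$utilities$u_dfs - p$utilities$disutility_endocrine),
                    p$utilities$u_dfs)
  u_fx <- joint_utility(p$utilities$u_dfs, p$utilities$u_fracture,
                        p$options$joint_utility_model)
  u_fx_t <- ifelse(on_therapy,
                   pmax(0, u_fx - p$utilities$disutility_endocrine), u_fx)
  util <- m[, "disease_free"] * u_dfs_t +
    m[, "disease_free_fracture"] * u_fx_t +
    (m[, "local"] + m[, "contralateral"]) * p$utilities$u_regional +
    m[, "distant"] * p$utilities$u_distant +
    m[, "endometrial"] * p$utilities$u_endometrial
  discounted_qalys <- sum(disc * util) / 12

  alive <- rowSums(m[, c("disease_free", "disease_free_fracture", "local",
                         "contralateral", "distant", "endometrial")])
  out <- structure(list(
    discounted_cost = discounted_cost,
    discounted_qalys = discounted_qalys,
    life_years = sum(alive) / 12,
    pf_life_years = sum(dfs_occ) / 12,
    discounted_life_years = sum(disc * alive) / 12,
    event_cumulatives = event_cumulatives(trace),
    strategy = s$name), class = "endocea_outcomes")
  out
}

#' @export
print.endocea_outcomes <- function(x, ...) {
  cat(sprintf("<endocea_outcomes> %s\n", x$strategy))
  cat(sprintf("  cost  %10.0f CNY (discounted)\n", x$discounted_cost))
  cat(sprintf("  QALYs %10.2f (discounted)\n", x$discounted_qalys))
  cat(sprintf("  LYs   %10.2f (undiscounted; %.2f progression-free)\n",
              x$life_years, x$pf_life_years))
  cat(sprintf("  recurrence %.2f%%, endometrial cancer %.2f%%\n",
              100 * x$event_cumulatives[["recurrence"]],
              100 * x$event_cumulatives[["endometrial"]]))
  invisible(x)
}

#' Incremental comparison of two strategies
#'
#' @param a Outcomes of the (usually more effective) strategy.
#' @param b Outcomes of the comparator.
#' @return An object of class `endocea_comparison`: `delta_cost`,
#'   `delta_qalys`, and `icer` — the incremental cost-effectiveness ratio in
#'   CNY/QALY when `delta_qalys != 0`, or a dominance label: `"dominant"`
#'   (cheaper and more effective), `"dominated"` (costlier and less
#'   effective), `"undefined"` (equal QALYs).
#' @examples
#' \dontrun{compare(summarize(tr_ai5), summarize(tr_tam))}
#' @export
compare <- function(a, b) {
  stopifnot(inherits(a, "endocea_outcomes"), inherits(b, "endocea_outcomes"))
  dc <- a$discounted_cost - b$discounted_cost
  dq <- a$discounted_qalys - b$discounted_qalys
  icer <- if (dq == 0) "undefined"
  else if (dq > 0 && dc <= 0) "dominant"
  else if (dq < 0 && dc >= 0) "dominated"
  else dc / dq
  structure(list(strategy = a$strategy, comparator = b$strategy,
                 delta_cost = dc, delta_qalys = dq, icer = icer),
            class = "endocea_comparison")
}

#' @export
print.endocea_comparison <- function(x, ...) {
  lab <- if (is.character(x$icer)) x$icer
  else sprintf("%.0f CNY/QALY", x$icer)
  cat(sprintf("<endocea_comparison> %s vs %s: dCost %.0f, dQALY %.3f, ICER %s\n",
              x$strategy, x$comparator, x$delta_cost, x$delta_qalys, lab))
  invisible(x)
}

# numeric ICER or +/-Inf for dominance labels (internal, for sweeps)
.icer_value <- function(cmp) {
  if (is.numeric(cmp$icer)) return(cmp$icer)
  switch(cmp$icer, dominant = -Inf, dominated = Inf, undefined = NaN)
}
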