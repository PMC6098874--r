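# Markov cohort engine -------------------------------------------------------
#
# Six exclusive health states: disease-free (split by a prior-fracture flag),
# local recurrence, contralateral recurrence, distant recurrence, endometrial
# cancer, dead (split by cause for bookkeeping). Bone fracture is a temporary
# event: it moves disease-free women into the flagged disease-free substate
# and triggers a one-time cost; at most one fracture per woman.
#
# Recurrence hazards run on the model clock (months since therapy start);
# progression hazards after local/contralateral recurrence run on the
# state-entry clock, so occupancy of those states is partitioned by months
# since entry (exact tunnel accounting, not an approximation).

#' Strategy definitions
#'
#' Builds the three adjuvant endocrine strategies compared by the model:
#' \describe{
#'   \item{tamoxifen}{tamoxifen for the full therapy period (months 0-60);
#'     all risk ratios 1 (baseline).}
#'   \item{ai_5yr}{letrozole for the full therapy period; recurrence and
#'     side-effect risk ratios from the "AI 5-years versus tamoxifen"
#'     inputs, applied from month 0.}
#'   \item{ai_switch}{tamoxifen to the switch month (default 30, the
#'     midpoint of the 2-3 year switch window) then letrozole to month 60;
#'     recurrence risk ratios from the "AI switch versus tamoxifen" inputs
#'     applied from month 0 (they are trial-level contrasts measured from
#'     randomisation); side-effect risk ratios apply from the switch month,
#'     when aromatase-inhibitor exposure begins.}
#' }
#' Recurrence risk ratios are maintained over the lifetime. Side-effect risk
#' ratios (endometrial cancer, fracture) also persist for life by default;
#' with `options$side_effect_duration == "treatment"` they apply only while
#' letrozole is actually being taken.
#'
#' @param p An `endocea_params` object.
#' @return Named list of three `endocea_strategy` objects
#'   (`tamoxifen`, `ai_5yr`, `ai_switch`).
#' @export
strategy_catalog <- function(p = default_params()) {
  stopifnot(inherits(p, "endocea_params"))
  tm <- p$econ$therapy_months
  sw <- p$econ$switch_month
  rr1 <- list(rr_distant = 1, rr_local = 1, rr_contralateral = 1,
              rr_endometrial = 1, rr_fracture = 1)
  mk <- function(name, schedule, rr, ai_start) {
    structure(list(name = name, schedule = schedule, rr = rr,
                   ai_start = ai_start), class = "endocea_strategy")
  }
  list(
    tamoxifen = mk("tamoxifen",
                   data.frame(drug = "tamoxifen", start = 0, end = tm),
                   rr1, ai_start = Inf),
    ai_5yr    = mk("ai_5yr",
                   data.frame(drug = "letrozole", start = 0, end = tm),
                   p$clinical$rr_ai5, ai_start = 0),
    ai_switch = mk("ai_switch",
                   data.frame(drug = c("tamoxifen", "letrozole"),
                              start = c(0, sw), end = c(sw, tm)),
                   p$clinical$rr_switch, ai_start = sw)
  )
}

#' @export
print.endocea_strategy <- function(x, ...) {
  sch <- paste(sprintf("%s m%g-%g", x$schedule$drug, x$schedule$start,
                       x$schedule$end), collapse = ", ")
  cat(sprintf("<endocea_strategy> %s [%s]\n", x$name, sch))
  invisible(x)
}

# Drug active at month t (or NA_character_ if none).
.drug_at <- function(s, t) {
  hit <- s$schedule$start <= t & t < s$schedule$end
  if (any(hit)) s$schedule$drug[which(hit)[1L]] else NA_character_
}

# Side-effect RR (endometrial / fracture) in force at month t.
.side_rr_at <- function(s, t, rr, p) {
  on <- if (identical(p$options$side_effect_duration, "treatment"))
    t >= s$ai_start & t < p$econ$therapy_months
  else
    t >= s$ai_start
  ifelse(on, rr, 1)
}

# Background mortality as a rate-convertible probability: a terminal life
# table row with qx = 1 is represented by a just-sub-unity monthly
# probability so the competing-risk rate algebra stays finite.
.qm_capped <- function(lt, age) pmin(monthly_mortality(lt, age), 1 - 1e-12)

# Per-cycle competing-risk split: given named exit rates, return the named
# exit probabilities (rates summed, total converted back to a probability,
# apportioned proportionally to the rates) plus the stay probability.
.compete <- function(rates) {
  total <- sum(rates)
  if (total <= 0) return(c(rates * 0, stay = 1))
  p_exit <- rate_to_prob(total)
  c(rates / total * p_exit, stay = 1 - p_exit)
}

#' Single-state transition probabilities
#'
#' Returns the one-cycle destination distribution for a woman in `state` at
#' model month `cycle`, months `months_in_state` after entering it. All
#' competing monthly risks are combined on the rate scale and the total exit
#' probability apportioned proportionally to the rates. Destinations:
#' \itemize{
#'   \item `disease_free` (no prior fracture): distant/local/contralateral
#'     recurrence (baseline cycle probability adjusted by the strategy risk
#'     ratio), endometrial cancer, fracture (to `disease_free_fracture`),
#'     other-cause death.
#'   \item `disease_free_fracture`: as above without a second fracture.
#'   \item `local_recurrence` / `contralateral_recurrence`: progression to
#'     distant recurrence on the state-entry clock, other-cause death.
#'   \item `distant_recurrence`: breast-cancer death, other-cause death.
#'   \item `endometrial_cancer`: endometrial-cancer death, other-cause death.
#'   \item `dead`: absorbing.
#' }
#'
#' @param state One of `"disease_free"`, `"disease_free_fracture"`,
#'   `"local_recurrence"`, `"contralateral_recurrence"`,
#'   `"distant_recurrence"`, `"endometrial_cancer"`, `"dead"`.
#' @param cycle Model month (0-based).
#' @param s An `endocea_strategy` from [strategy_catalog()].
#' @param p An `endocea_params` object.
#' @param lt A [life_table()] for background mortality.
#' @param months_in_state Months since entering the current state (used by
#'   the recurrence states' progression clocks).
#' @return Named numeric vector of destination probabilities summing to 1.
#' @export
transition_row <- function(state, cycle, s, p, lt, months_in_state = 0) {
  stopifnot(inherits(s, "endocea_strategy"), inherits(p, "endocea_params"))
  if (cycle < 0 || months_in_state < 0)
    stop("'cycle' and 'months_in_state' must be non-negative", call. = FALSE)
  cl <- p$clinical
  age <- p$econ$start_age + cycle / 12
  r_bg <- prob_to_rate(.qm_capped(lt, age))
  out <- switch(state,
    disease_free = ,
    disease_free_fracture = {
      rates <- c(
        distant_recurrence =
          s$rr$rr_distant * prob_to_rate(cycle_prob(cl$dist_distant, cycle)),
        local_recurrence =
          s$rr$rr_local * prob_to_rate(cycle_prob(cl$dist_local, cycle)),
        contralateral_recurrence =
          s$rr$rr_contralateral *
            prob_to_rate(cycle_prob(cl$dist_contralateral, cycle)),
        endometrial_cancer =
          .side_rr_at(s, cycle, s$rr$rr_endometrial, p) *
            prob_to_rate(cl$p_endometrial),
        dead = r_bg)
      if (state == "disease_free")  # a second fracture cannot occur
        rates <- c(rates, disease_free_fracture =
                     .side_rr_at(s, cycle, s$rr$rr_fracture, p) *
                       prob_to_rate(cl$p_fracture))
      pr <- .compete(rates)
      names(pr)[names(pr) == "stay"] <- state
      pr
    },
    local_recurrence = ,
    contralateral_recurrence = {
      pfs <- if (state == "local_recurrence") cl$pfs_after_local
             else cl$pfs_after_contralateral
      rates <- c(
        distant_recurrence = prob_to_rate(cycle_prob(pfs, months_in_state)),
        dead = r_bg)
      pr <- .compete(rates)
      names(pr)[names(pr) == "stay"] <- state
      pr
    },
    distant_recurrence = {
      rates <- c(dead_breast_cancer = prob_to_rate(cl$p_death_distant),
                 dead = r_bg)
      pr <- .compete(rates)
      names(pr)[names(pr) == "stay"] <- state
      pr
    },
    endometrial_cancer = {
      rates <- c(dead_endometrial_cancer = prob_to_rate(cl$p_death_endometrial),
                 dead = r_bg)
      pr <- .compete(rates)
      names(pr)[names(pr) == "stay"] <- state
      pr
    },
    dead = c(dead = 1),
    stop(sprintf("unknown health state '%s'", state), call. = FALSE)
  )
  out
}

#' Run the cohort model for one strategy
#'
#' Propagates a cohort starting disease-free at the configured start age
#' through monthly cycles until the horizon age, tracking occupancy of every
#' (sub)state and per-cycle incident events. Occupancy of the local and
#' contralateral recurrence states is partitioned by months since state
#' entry so that the Weibull progression hazards run on the correct clock.
#'
#' @param s An `endocea_strategy` from [strategy_catalog()].
#' @param p An `endocea_params` object.
#' @param lt A [life_table()].
#' @return A `cohort_trace`: a data.frame with one row per cycle (cycle 0 to
#'   the horizon). Occupancy columns: `disease_free`,
#'   `disease_free_fracture`, `local`, `local_entry`, `contralateral`,
#'   `contralateral_entry`, `distant`, `distant_entry`, `endometrial`,
#'   `dead_bc`, `dead_endometrial`, `dead_other` (the `_entry` columns are
#'   the occupancy currently in its first month of the state, used for
#'   first-month costing). Incident-event columns (events during the cycle
#'   beginning at that row): `inc_local`, `inc_contralateral`,
#'   `inc_distant`, `inc_first_recurrence`, `inc_endometrial`,
#'   `inc_fracture`, `inc_death_bc`, `inc_death_endometrial`,
#'   `inc_death_other`. The strategy and parameters are attached as
#'   attributes.
#' @export
run_cohort <- function(s, p, lt) {
  stopifnot(inherits(s, "endocea_strategy"), inherits(p, "endocea_params"),
            inherits(lt, "life_table"))
  cl <- p$clinical
  n_cyc <- ceiling((p$econ$max_age - p$econ$start_age) * 12)
  t_idx <- 0:(n_cyc - 1L)

  # per-cycle exit rates on the model clock
  qm <- .qm_capped(lt, p$econ$start_age + t_idx / 12)
  r_bg   <- prob_to_rate(qm)
  r_dist <- s$rr$rr_distant * prob_to_rate(cycle_prob(cl$dist_distant, t_idx))
  r_loc  <- s$rr$rr_local * prob_to_rate(cycle_prob(cl$dist_local, t_idx))
  r_con  <- s$rr$rr_contralateral *
    prob_to_rate(cycle_prob(cl$dist_contralateral, t_idx))
  r_endo <- .side_rr_at(s, t_idx, s$rr$rr_endometrial, p) *
    prob_to_rate(cl$p_endometrial)
  r_frac <- .side_rr_at(s, t_idx, s$rr$rr_fracture, p) *
    prob_to_rate(cl$p_fracture)
  # progression rates on the state-entry clock (duration d = 0, 1, ...)
  r_prog_loc <- prob_to_rate(cycle_prob(cl$pfs_after_local, t_idx))
  r_prog_con <- prob_to_rate(cycle_prob(cl$pfs_after_contralateral, t_idx))
  r_death_distant <- prob_to_rate(cl$p_death_distant)
  r_death_endo    <- prob_to_rate(cl$p_death_endometrial)

  # state occupancy
  dfs0 <- 1; dfsfx <- 0
  loc <- numeric(n_cyc + 1L)   # indexed by duration d + 1
  con <- numeric(n_cyc + 1L)
  dist <- 0; dist_entry <- 0; endo <- 0
  dead_bc <- 0; dead_endo <- 0; dead_oth <- 0

  occ_names <- c("disease_free", "disease_free_fracture", "local",
                 "local_entry", "contralateral", "contralateral_entry",
                 "distant", "distant_entry", "endometrial", "dead_bc",
                 "dead_endometrial", "dead_other")
  inc_names <- c("inc_local", "inc_contralateral", "inc_distant",
                 "inc_first_recurrence", "inc_endometrial", "inc_fracture",
                 "inc_death_bc", "inc_death_endometrial", "inc_death_other")
  occ <- matrix(0, n_cyc + 1L, length(occ_names),
                dimnames = list(NULL, occ_names))
  inc <- matrix(0, n_cyc + 1L, length(inc_names),
                dimnames = list(NULL, inc_names))

  for (i in seq_len(n_cyc)) {
    occ[i, ] <- c(dfs0, dfsfx, sum(loc), loc[1L], sum(con), con[1L],
                  dist, dist_entry, endo, dead_bc, dead_endo, dead_oth)

    # disease-free without prior fracture: six competing exits
    R0 <- r_dist[i] + r_loc[i] + r_con[i] + r_endo[i] + r_frac[i] + r_bg[i]
    if (R0 > 0) {
      ex0 <- dfs0 * rate_to_prob(R0) / R0
      f0 <- c(d = ex0 * r_dist[i], l = ex0 * r_loc[i], c = ex0 * r_con[i],
              e = ex0 * r_endo[i], fx = ex0 * r_frac[i], bg = ex0 * r_bg[i])
    } else f0 <- c(d = 0, l = 0, c = 0, e = 0, fx = 0, bg = 0)

    # disease-free with prior fracture: same exits minus a second fracture
    Rf <- r_dist[i] + r_loc[i] + r_con[i] + r_endo[i] + r_bg[i]
    if (Rf > 0) {
      exf <- dfsfx * rate_to_prob(Rf) / Rf
      ff <- c(d = exf * r_dist[i], l = exf * r_loc[i], c = exf * r_con[i],
              e = exf * r_endo[i], bg = exf * r_bg[i])
    } else ff <- c(d = 0, l = 0, c = 0, e = 0, bg = 0)

    # recurrence tunnels: progression rate depends on duration, death on age
    d_max <- i  # durations 0 .. i-1 can be occupied
    sl <- seq_len(d_max)
    Rl <- r_prog_loc[sl] + r_bg[i]
    exl <- ifelse(Rl > 0, rate_to_prob(Rl) / Rl, 0) * loc[sl]
    loc_to_dist <- exl * r_prog_loc[sl]
    loc_to_dead <- exl * r_bg[i]
    Rc <- r_prog_con[sl] + r_bg[i]
    exc <- ifelse(Rc > 0, rate_to_prob(Rc) / Rc, 0) * con[sl]
    con_to_dist <- exc * r_prog_con[sl]
    con_to_dead <- exc * r_bg[i]

    # distant recurrence and endometrial cancer
    Rd <- r_death_distant + r_bg[i]
    exd <- if (Rd > 0) dist * rate_to_prob(Rd) / Rd else 0
    dist_to_bc <- exd * r_death_distant
    dist_to_oth <- exd * r_bg[i]
    Re <- r_death_endo + r_bg[i]
    exe <- if (Re > 0) endo * rate_to_prob(Re) / Re else 0
    endo_to_ec <- exe * r_death_endo
    endo_to_oth <- exe * r_bg[i]

    inc_dist_total <- f0[["d"]] + ff[["d"]] + sum(loc_to_dist) +
      sum(con_to_dist)
    inc[i, ] <- c(f0[["l"]] + ff[["l"]], f0[["c"]] + ff[["c"]],
                  inc_dist_total,
                  f0[["d"]] + ff[["d"]] + f0[["l"]] + ff[["l"]] +
                    f0[["c"]] + ff[["c"]],
                  f0[["e"]] + ff[["e"]], f0[["fx"]],
                  dist_to_bc, endo_to_ec,
                  f0[["bg"]] + ff[["bg"]] + sum(loc_to_dead) +
                    sum(con_to_dead) + dist_to_oth + endo_to_oth)

    # advance occupancy
    dfs0_new <- dfs0 - sum(f0)
    dfsfx_new <- dfsfx - sum(ff) + f0[["fx"]]
    loc_stay <- loc[sl] - loc_to_dist - loc_to_dead
    con_stay <- con[sl] - con_to_dist - con_to_dead
    loc[sl + 1L] <- loc_stay; loc[1L] <- f0[["l"]] + ff[["l"]]
    con[sl + 1L] <- con_stay; con[1L] <- f0[["c"]] + ff[["c"]]
    dist_entry <- inc_dist_total
    dist <- dist - dist_to_bc - dist_to_oth + inc_dist_total
    endo <- endo - endo_to_ec - endo_to_oth + f0[["e"]] + ff[["e"]]
    dead_bc <- dead_bc + dist_to_bc
    dead_endo <- dead_endo + endo_to_ec
    dead_oth <- dead_oth + inc[i, "inc_death_other"]
    dfs0 <- dfs0_new; dfsfx <- dfsfx_new
  }
  occ[n_cyc + 1L, ] <- c(dfs0, dfsfx, sum(loc), loc[1L], sum(con), con[1L],
                         dist, dist_entry, endo, dead_bc, dead_endo,
                         dead_oth)

  trace <- data.frame(cycle = 0:n_cyc,
                      age = p$econ$start_age + (0:n_cyc) / 12,
                      occ, inc)
  class(trace) <- c("cohort_trace", "data.frame")
  attr(trace, "strategy") <- s
  attr(trace, "params") <- p
  trace
}

# Alive occupancy per trace row.
.alive <- function(trace) {
  with(trace, disease_free + disease_free_fracture + local + contralateral +
         distant + endometrial)
}

#' Lifetime cumulative probabilities of clinical events
#'
#' Sums the per-cycle incident-event columns of a trace. Because no pathway
#' returns to the disease-free state, the sum of exits from disease-free to
#' any recurrence state is exactly the per-woman probability of a first
#' breast-cancer recurrence of any type.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @return Named numeric vector of lifetime cumulative probabilities:
#'   `recurrence` (first recurrence of any type), `local`, `contralateral`,
#'   `distant` (entries to the distant state, including progressions),
#'   `endometrial`, `fracture`, `death_breast_cancer`, `death_endometrial`,
#'   `death_other`.
#' @export
event_cumulatives <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  c(recurrence        = sum(trace$inc_first_recurrence),
    local             = sum(trace$inc_local),
    contralateral     = sum(trace$inc_contralateral),
    distant           = sum(trace$inc_distant),
    endometrial       = sum(trace$inc_endometrial),
    fracture          = sum(trace$inc_fracture),
    death_breast_cancer = sum(trace$inc_death_bc),
    death_endometrial = sum(trace$inc_death_endometrial),
    death_other       = sum(trace$inc_death_other))
}
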