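# Parameter registry ---------------------------------------------------------
#
# Every scalar model input is addressable by a flat key. The registry drives
# default_params(), the config reader/writer, validate(), the one-way
# sensitivity analysis and the PSA, so the input list is defined exactly once.
#
# kind:  rate      positive survival scale (lognormal in PSA)
#        rr        positive risk ratio (lognormal in PSA)
#        prob      monthly probability in [0,1] (beta in PSA)
#        utility   preference weight in [0,1] (beta in PSA)
#        cost      non-negative CNY amount (lognormal in PSA)
#        econ      structural/economic setting (never sampled; OWSA only
#                  where a range is defined)
.param_registry_cache <- new.env(parent = emptyenv())

.param_registry <- function() {
  if (!is.null(.param_registry_cache$reg)) return(.param_registry_cache$reg)
  reg <- list(
    # clinical: baseline survival scales (monthly), tamoxifen strategy
    list("lam_distant",          "rate", 0.001524, 0.001423, 0.001625),
    list("lam_local",            "rate", 0.000292, 0.00029,  0.000294),
    list("lam_contralateral",    "rate", 0.000017, 0.000013, 0.000021),
    list("gamma_contralateral",  "rate", 1.6165,   NA,       NA),
    list("lam_pfs_local",        "rate", 0.0458,   0.004498, 0.023713),
    list("gamma_pfs_local",      "rate", 0.782,    NA,       NA),
    list("lam_pfs_contralateral","rate", 0.0487,   0.044114, 0.053286),
    list("gamma_pfs_contralateral","rate", 0.742,  NA,       NA),
    # recurrence risk ratios vs the tamoxifen strategy
    list("rr_ai5_distant",       "rr",   0.830,    0.74,     0.93),
    list("rr_ai5_local",         "rr",   0.7200,   0.57,     0.92),
    list("rr_ai5_contralateral", "rr",   0.6500,   0.52,     0.81),
    list("rr_switch_distant",    "rr",   0.90,     0.80,     1.01),
    list("rr_switch_local",      "rr",   0.84,     0.68,     1.03),
    list("rr_switch_contralateral","rr", 0.63,     0.51,     0.80),
    # adverse events (baseline monthly probabilities; RRs under AI therapy)
    list("p_endometrial",        "prob", 0.00010,  0.000084, 0.000117),
    list("p_fracture",           "prob", 0.00047,  0.000375, 0.000551),
    list("rr_ai_endometrial",    "rr",   0.33,     0.21,     0.51),
    list("rr_ai_fracture",       "rr",   1.42,     1.28,     1.57),
    # monthly death probabilities
    list("p_death_distant",      "prob", 0.0290,   0.023,    0.041),
    list("p_death_endometrial",  "prob", 0.0098,   0.0091,   0.0105),
    # utilities
    list("u_dfs",                "utility", 0.94,  0.92,     0.97),
    list("disutility_endocrine", "utility", 0.01,  0.01,     0.01),
    list("u_fracture",           "utility", 0.70,  0.64,     0.96),
    list("u_regional",           "utility", 0.78,  0.77,     0.79),
    list("u_distant",            "utility", 0.53,  0.42,     0.64),
    list("u_endometrial",        "utility", 0.83,  0.68,     0.95),
    # costs (2016 CNY)
    list("cost_tamoxifen_day",   "cost", 1.4,      0.98,     1.67),
    list("cost_letrozole_day",   "cost", 11.9,     11.08,    12.9),
    list("cost_locoregional_first", "cost", 75421, 44364,    106478),
    list("cost_locoregional_month", "cost", 865,   509,      1221),
    list("cost_distant_first",   "cost", 83008,    34876,    131140),
    list("cost_distant_month",   "cost", 888,      373,      1403),
    list("cost_endometrial",     "cost", 17138,    14499,    19776),
    list("cost_fracture",        "cost", 25552,    21440,    30622),
    # economic / structural settings
    list("annual_discount",      "econ", 0.05,     0.00,     0.08),
    list("wtp_threshold",        "econ", 171000,   NA,       NA),
    list("per_capita_gdp",       "econ", 57000,    NA,       NA),
    list("cycle_length",         "econ", 1,        NA,       NA),
    list("start_age",            "econ", 57.3,     27,       79),
    list("max_age",              "econ", 100,      NA,       NA),
    list("therapy_months",       "econ", 60,       NA,       NA),
    list("switch_month",         "econ", 30,       NA,       NA),
    list("days_per_month",       "econ", 30.4375,  NA,       NA)
  )
  out <- do.call(rbind, lapply(reg, function(r)
    data.frame(key = r[[1]], kind = r[[2]], base = r[[3]],
               low = r[[4]], high = r[[5]], stringsAsFactors = FALSE)))
  .param_registry_cache$reg <- out
  out
}

.model_option_defaults <- function() {
  list(
    side_effect_duration = "lifetime",   # or "treatment"
    joint_utility_model  = "anchored",   # or "multiplicative"
    # Cost attribution in the recurrence states. "monthly" charges the
    # monthly management cost in every month including the entry month and
    # reproduces the published lifetime cost totals; "first_month" charges
    # the separately tabulated first-month management cost at state entry.
    recurrence_entry_cost = "monthly",
    half_cycle_correction = FALSE
  )
}

#' Default model parameters
#'
#' Returns the full base-case parameter set: baseline monthly recurrence
#' hazards for the tamoxifen strategy (exponential for local and distant
#' recurrence, Weibull for contralateral recurrence), post-recurrence
#' progression-free-survival laws, risk ratios for the two letrozole
#' strategies, monthly adverse-event and death probabilities, 2016 CNY unit
#' costs, preference weights, and economic settings (5% annual discounting,
#' willingness-to-pay threshold of CNY 171,000 per QALY, one-month cycles,
#' cohort start age 57.3 years, horizon at age 100).
#'
#' @return An object of class `endocea_params`: a list with elements
#'   `clinical`, `costs`, `utilities`, `econ`, `options` and `ranges` (a
#'   named list of `c(low, high)` ranges used by the sensitivity analyses).
#' @examples
#' p <- default_params()
#' p$costs$daily_letrozole
#' @export
default_params <- function() {
  reg <- .param_registry()
  v <- stats::setNames(reg$base, reg$key)
  params_from_values(v, .model_option_defaults(), registry = reg)
}

# Assemble the nested parameter object from a named vector of scalar values.
params_from_values <- function(v, options, registry = .param_registry()) {
  clinical <- list(
    dist_distant        = survdist("exponential", v[["lam_distant"]]),
    dist_local          = survdist("exponential", v[["lam_local"]]),
    dist_contralateral  = survdist("weibull", v[["lam_contralateral"]],
                                   v[["gamma_contralateral"]]),
    pfs_after_local     = survdist("weibull", v[["lam_pfs_local"]],
                                   v[["gamma_pfs_local"]]),
    pfs_after_contralateral = survdist("weibull",
                                       v[["lam_pfs_contralateral"]],
                                       v[["gamma_pfs_contralateral"]]),
    p_death_distant     = v[["p_death_distant"]],
    p_endometrial       = v[["p_endometrial"]],
    p_fracture          = v[["p_fracture"]],
    p_death_endometrial = v[["p_death_endometrial"]],
    rr_ai5 = list(rr_distant        = v[["rr_ai5_distant"]],
                  rr_local          = v[["rr_ai5_local"]],
                  rr_contralateral  = v[["rr_ai5_contralateral"]],
                  rr_endometrial    = v[["rr_ai_endometrial"]],
                  rr_fracture       = v[["rr_ai_fracture"]]),
    rr_switch = list(rr_distant       = v[["rr_switch_distant"]],
                     rr_local         = v[["rr_switch_local"]],
                     rr_contralateral = v[["rr_switch_contralateral"]],
                     rr_endometrial   = v[["rr_ai_endometrial"]],
                     rr_fracture      = v[["rr_ai_fracture"]])
  )
  costs <- list(
    daily_tamoxifen         = v[["cost_tamoxifen_day"]],
    daily_letrozole         = v[["cost_letrozole_day"]],
    locoregional_first_month = v[["cost_locoregional_first"]],
    locoregional_subsequent = v[["cost_locoregional_month"]],
    distant_first_month     = v[["cost_distant_first"]],
    distant_subsequent      = v[["cost_distant_month"]],
    endometrial_per_patient = v[["cost_endometrial"]],
    fracture_per_event      = v[["cost_fracture"]]
  )
  utilities <- list(
    u_dfs = v[["u_dfs"]], u_regional = v[["u_regional"]],
    u_distant = v[["u_distant"]], u_endometrial = v[["u_endometrial"]],
    u_fracture = v[["u_fracture"]],
    disutility_endocrine = v[["disutility_endocrine"]]
  )
  econ <- list(
    annual_discount = v[["annual_discount"]],
    wtp_threshold   = v[["wtp_threshold"]],
    per_capita_gdp  = v[["per_capita_gdp"]],
    cycle_length    = v[["cycle_length"]],
    start_age       = v[["start_age"]],
    max_age         = v[["max_age"]],
    therapy_months  = v[["therapy_months"]],
    switch_month    = v[["switch_month"]],
    days_per_month  = v[["days_per_month"]]
  )
  ranged <- registry[!is.na(registry$low), ]
  ranges <- stats::setNames(
    lapply(seq_len(nrow(ranged)),
           function(i) c(low = ranged$low[i], high = ranged$high[i])),
    ranged$key)
  structure(list(clinical = clinical, costs = costs, utilities = utilities,
                 econ = econ, options = options, ranges = ranges,
                 values = v),
            class = "endocea_params")
}

#' Flat scalar view of a parameter set
#'
#' @param p An `endocea_params` object.
#' @return Named numeric vector of every scalar input, keyed by the flat
#'   config-file key.
#' @export
param_values <- function(p) {
  stopifnot(inherits(p, "endocea_params"))
  p$values
}

#' Replace one scalar parameter by flat key
#'
#' Rebuilds the nested parameter object with one value replaced; used by the
#' sensitivity analyses and the config reader.
#'
#' @param p An `endocea_params` object.
#' @param key Flat parameter key (see [param_values()] for the names).
#' @param value New numeric value.
#' @return A new `endocea_params` object.
#' @export
set_param <- function(p, key, value) {
  stopifnot(inherits(p, "endocea_params"))
  v <- p$values
  if (!key %in% names(v))
    stop(sprintf("unknown parameter key '%s'", key), call. = FALSE)
  v[[key]] <- value
  params_from_values(v, p$options)
}

#' @export
print.endocea_params <- function(x, ...) {
  cat("<endocea_params>", length(x$values), "scalar inputs;",
      length(x$ranges), "with sensitivity ranges\n")
  cat(sprintf("  start age %.1f y, horizon %g y, discount %.1f%%/yr, WTP %s CNY/QALY\n",
              x$econ$start_age, x$econ$max_age,
              100 * x$econ$annual_discount,
              format(x$econ$wtp_threshold, big.mark = ",")))
  invisible(x)
}

#' Load a parameter configuration file
#'
#' The config dialect is a flat YAML mapping of parameter keys to numbers
#' (the keys of [param_values()]), plus the optional structural keys
#' `side_effect_duration` (`"lifetime"` or `"treatment"`),
#' `joint_utility_model` (`"anchored"` or `"multiplicative"`) and
#' `half_cycle_correction` (logical). Keys absent from the file keep their
#' defaults; an empty file reproduces [default_params()] exactly.
#'
#' @param path Path to a YAML file.
#' @return A validated `endocea_params` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg))
    stop(sprintf("config file '%s' must be a YAML mapping", path),
         call. = FALSE)
  reg <- .param_registry()
  v <- stats::setNames(reg$base, reg$key)
  opts <- .model_option_defaults()
  for (key in names(cfg)) {
    if (key %in% names(opts)) {
      opts[[key]] <- cfg[[key]]
    } else if (key %in% names(v)) {
      val <- cfg[[key]]
      if (!is.numeric(val) || length(val) != 1L || is.na(val))
        stop(sprintf("config key '%s' must be a single number", key),
             call. = FALSE)
      v[[key]] <- as.numeric(val)
    } else {
      stop(sprintf("unknown config key '%s'", key), call. = FALSE)
    }
  }
  viol <- .scalar_violations(v)
  if (length(viol))
    stop(paste(c("invalid parameter configuration:",
                 paste0("  - ", viol)), collapse = "\n"), call. = FALSE)
  p <- params_from_values(v, opts, registry = reg)
  viol <- validate(p)
  if (length(viol))
    stop(paste(c("invalid parameter configuration:",
                 paste0("  - ", viol)), collapse = "\n"), call. = FALSE)
  p
}

#' Write a parameter set to a config file
#'
#' Serialises every scalar value and structural option to the flat YAML
#' dialect read by [load_config()]; the round trip is value-identical.
#'
#' @param p An `endocea_params` object.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_config <- function(p, path) {
  stopifnot(inherits(p, "endocea_params"))
  out <- as.list(p$values)
  out <- c(out, p$options)
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

# Per-scalar invariant checks on the flat value vector; shared by
# validate() and by load_config(), which must report violations by key
# before the nested objects are constructed.
.scalar_violations <- function(v) {
  reg <- .param_registry()
  bad <- character()
  add <- function(msg) bad <<- c(bad, msg)
  for (i in seq_len(nrow(reg))) {
    key <- reg$key[i]; val <- v[[key]]
    if (!is.finite(val)) { add(sprintf("%s: not a finite number", key)); next }
    switch(reg$kind[i],
      rate = if (val < 0 || (grepl("^gamma", key) && val <= 0))
               add(sprintf("%s: survival parameter must be positive (got %g)",
                           key, val)),
      rr   = if (val <= 0)
               add(sprintf("%s: risk ratio must be positive (got %g)", key, val)),
      prob = if (val < 0 || val > 1)
               add(sprintf("%s: probability must lie in [0, 1] (got %g)",
                           key, val)),
      utility = if (key == "disutility_endocrine") {
                  if (val < 0)
                    add(sprintf("%s: disutility must be >= 0 (got %g)", key, val))
                } else if (val < 0 || val > 1)
                  add(sprintf("%s: utility must lie in [0, 1] (got %g)", key, val)),
      cost = if (val < 0)
               add(sprintf("%s: cost must be >= 0 (got %g)", key, val)),
      econ = NULL)
  }
  bad
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the model inputs and returns the
#' violations as a character vector (empty when the set is valid):
#' survival scales and risk ratios positive, probabilities and utilities in
#' `[0, 1]`, costs non-negative, discount in `[0, 1)`, start age below the
#' horizon age, and each sensitivity range internally ordered (`low <=
#' high`). Values lying outside their published tested range are allowed:
#' scenario overrides and probabilistic draws leave the range by design.
#'
#' @param p An `endocea_params` object.
#' @return Character vector of human-readable violation descriptions.
#' @export
validate <- function(p) {
  stopifnot(inherits(p, "endocea_params"))
  v <- p$values
  bad <- .scalar_violations(v)
  add <- function(msg) bad <<- c(bad, msg)
  if (v[["annual_discount"]] < 0 || v[["annual_discount"]] >= 1)
    add("annual_discount: must lie in [0, 1)")
  if (v[["start_age"]] >= v[["max_age"]])
    add("start_age: must be below max_age")
  if (v[["switch_month"]] < 0 || v[["switch_month"]] > v[["therapy_months"]])
    add("switch_month: must lie within the therapy period")
  if (!p$options$side_effect_duration %in% c("lifetime", "treatment"))
    add("side_effect_duration: must be 'lifetime' or 'treatment'")
  if (!p$options$joint_utility_model %in% c("anchored", "multiplicative"))
    add("joint_utility_model: must be 'anchored' or 'multiplicative'")
  if (!p$options$recurrence_entry_cost %in% c("monthly", "first_month"))
    add("recurrence_entry_cost: must be 'monthly' or 'first_month'")
  if (!is.logical(p$options$half_cycle_correction))
    add("half_cycle_correction: must be logical")
  # ranges must be ordered; whether the current value sits inside its
  # published tested range is deliberately NOT enforced here (sensitivity
  # overrides and PSA draws legitimately leave the range, and one published
  # range does not bracket its own base value)
  for (key in names(p$ranges)) {
    r <- p$ranges[[key]]
    if (r[["low"]] > r[["high"]])
      add(sprintf("range for %s: low (%g) exceeds high (%g)",
                  key, r[["low"]], r[["high"]]))
  }
  bad
}
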