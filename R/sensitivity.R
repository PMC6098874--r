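# Sensitivity analyses: one-way (tornado), age sweep, probabilistic ----------

# ICER of strategy a vs b under a given parameter set.
.pair_icer <- function(p, lt, pair = c("ai_5yr", "tamoxifen")) {
  out <- run_model(p, lt, strategies = pair)
  .icer_value(compare(out[[pair[1L]]], out[[pair[2L]]]))
}

#' One-way (tornado) sensitivity analysis
#'
#' Recomputes the ICER of one strategy pair with each ranged parameter set
#' in turn to its lower and upper tested limit (all other inputs at base
#' case). Rows are sorted by decreasing bar width `|icer_high - icer_low|`,
#' the tornado-diagram ordering.
#'
#' @param base An `endocea_params` object (base case).
#' @param lt A [life_table()].
#' @param pair Character vector of length 2: strategy and comparator.
#' @param parameters Flat parameter keys to vary; default all keys with a
#'   tested range (including `start_age` and `annual_discount`).
#' @return A data.frame of class `endocea_owsa` with columns `parameter`,
#'   `low`, `high`, `icer_low`, `icer_high`, `width`, plus the base-case
#'   ICER as attribute `base_icer`.
#' @export
owsa <- function(base, lt, pair = c("ai_5yr", "tamoxifen"),
                 parameters = names(base$ranges)) {
  stopifnot(inherits(base, "endocea_params"))
  base_icer <- .pair_icer(base, lt, pair)
  rows <- lapply(parameters, function(key) {
    r <- base$ranges[[key]]
    if (is.null(r))
      stop(sprintf("no tested range for parameter '%s'", key), call. = FALSE)
    icer_lo <- .pair_icer(set_param(base, key, r[["low"]]), lt, pair)
    icer_hi <- .pair_icer(set_param(base, key, r[["high"]]), lt, pair)
    data.frame(parameter = key, low = r[["low"]], high = r[["high"]],
               icer_low = icer_lo, icer_high = icer_hi,
               width = abs(icer_hi - icer_lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  class(out) <- c("endocea_owsa", "data.frame")
  attr(out, "base_icer") <- base_icer
  attr(out, "pair") <- pair
  out
}

#' ICER as a function of the age at therapy start
#'
#' @param ages Numeric vector of starting ages (years).
#' @param p An `endocea_params` object.
#' @param lt A [life_table()].
#' @return Data.frame with columns `age`, `icer_ai5_vs_tamoxifen`,
#'   `icer_switch_vs_tamoxifen`.
#' @export
age_sweep <- function(ages, p, lt) {
  stopifnot(inherits(p, "endocea_params"))
  rows <- lapply(ages, function(a) {
    pa <- set_param(p, "start_age", a)
    out <- run_model(pa, lt)
    data.frame(age = a,
               icer_ai5_vs_tamoxifen =
                 .icer_value(compare(out$ai_5yr, out$tamoxifen)),
               icer_switch_vs_tamoxifen =
                 .icer_value(compare(out$ai_switch, out$tamoxifen)))
  })
  do.call(rbind, rows)
}

# PSA distribution hyperparameters for one parameter (NULL if degenerate).
.psa_spec <- function(key, kind, base, low, high) {
  if (!is.na(low) && !is.na(high) && low == high) return(NULL)
  if (kind %in% c("prob", "utility")) {
    m <- base; s <- (high - low) / (2 * stats::qnorm(0.975))
    if (s <= 0) return(NULL)
    if (m <= 0 || m >= 1 || s^2 >= m * (1 - m))
      stop(sprintf("infeasible beta hyperparameters for '%s'", key),
           call. = FALSE)
    nu <- m * (1 - m) / s^2 - 1
    list(dist = "beta", shape1 = m * nu, shape2 = (1 - m) * nu)
  } else {  # cost, rr, rate: lognormal anchored at median = base
    if (base <= 0 || low <= 0)
      stop(sprintf("infeasible lognormal hyperparameters for '%s'", key),
           call. = FALSE)
    sdlog <- (log(high) - log(low)) / (2 * stats::qnorm(0.975))
    if (sdlog <= 0) return(NULL)
    list(dist = "lnorm", meanlog = log(base), sdlog = sdlog)
  }
}

#' Draw one probabilistic-sensitivity-analysis parameter set
#'
#' Samples every uncertain parameter jointly: beta distributions for
#' probabilities and utilities (method of moments with mean = base value
#' and sd = range width / 3.92, the tested range being read as a 95%
#' interval), lognormal for costs, risk ratios and survival scale
#' parameters (median = base, 95% interval width from the tested range).
#' Structural settings (`start_age`, `annual_discount`) are never sampled.
#' Parameters whose tested range is degenerate (e.g. the endocrine-therapy
#' disutility) stay at their base value, so shrinking all ranges to zero
#' collapses every draw to the base case.
#'
#' @param base An `endocea_params` object.
#' @return A new `endocea_params` object with sampled values (consumes the
#'   current R random-number stream; seed via [set.seed()] or [run_psa()]).
#' @export
draw_psa <- function(base) {
  stopifnot(inherits(base, "endocea_params"))
  reg <- .param_registry()
  v <- base$values
  for (key in names(base$ranges)) {
    i <- match(key, reg$key)
    kind <- reg$kind[i]
    if (kind == "econ") next  # structural: OWSA only
    r <- base$ranges[[key]]
    spec <- .psa_spec(key, kind, v[[key]], r[["low"]], r[["high"]])
    if (is.null(spec)) next
    v[[key]] <- if (spec$dist == "beta")
      stats::rbeta(1, spec$shape1, spec$shape2)
    else
      stats::rlnorm(1, spec$meanlog, spec$sdlog)
  }
  params_from_values(v, base$options, registry = reg)
}

#' Probabilistic sensitivity analysis
#'
#' Runs `n` second-order Monte Carlo draws of the full parameter set and
#' evaluates every requested strategy on each draw with common random
#' numbers (the same sampled parameters are shared by all strategies within
#' a draw, so incremental contrasts reflect parameter uncertainty only).
#'
#' @param n Number of draws (the reference analysis uses 1,000).
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @param p An `endocea_params` object (base case).
#' @param lt A [life_table()].
#' @param strategies Strategy names to evaluate.
#' @return A data.frame of class `endocea_psa`, one row per draw and
#'   strategy: `draw`, `strategy`, `cost`, `qalys`, `life_years`.
#' @export
run_psa <- function(n, seed, p, lt,
                    strategies = c("tamoxifen", "ai_5yr", "ai_switch")) {
  stopifnot(n >= 1)
  set.seed(seed)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pi <- draw_psa(p)
    out <- run_model(pi, lt, strategies = strategies)
    rows[[i]] <- data.frame(
      draw = i, strategy = strategies,
      cost = vapply(out, `[[`, numeric(1), "discounted_cost"),
      qalys = vapply(out, `[[`, numeric(1), "discounted_qalys"),
      life_years = vapply(out, `[[`, numeric(1), "life_years"),
      row.names = NULL)
  }
  res <- do.call(rbind, rows)
  class(res) <- c("endocea_psa", "data.frame")
  attr(res, "seed") <- seed
  res
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the proportion of PSA draws in which
#' the strategy has higher net monetary benefit (WTP x QALYs - cost) than
#' its comparator. At WTP = 0 this is the fraction of draws where the
#' strategy is cheaper; as WTP grows it converges to the fraction of draws
#' with a QALY gain.
#'
#' @param samples An `endocea_psa` data.frame from [run_psa()].
#' @param wtp_grid Numeric vector of willingness-to-pay values (CNY/QALY).
#' @param strategy,comparator Strategy names present in `samples`.
#' @return Data.frame with columns `wtp` and `prob_ce`.
#' @export
ceac <- function(samples, wtp_grid = seq(0, 400000, by = 5000),
                 strategy = "ai_5yr", comparator = "tamoxifen") {
  stopifnot(inherits(samples, "data.frame"))
  a <- samples[samples$strategy == strategy, ]
  b <- samples[samples$strategy == comparator, ]
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("requested strategies not present in the PSA samples", call. = FALSE)
  a <- a[order(a$draw), ]; b <- b[order(b$draw), ]
  if (!identical(a$draw, b$draw))
    stop("PSA samples must contain the same draws for both strategies",
         call. = FALSE)
  prob <- vapply(wtp_grid, function(w)
    mean(w * a$qalys - a$cost > w * b$qalys - b$cost), numeric(1))
  data.frame(wtp = wtp_grid, prob_ce = prob)
}

#' Probability that each strategy is optimal (multiway CEAC)
#'
#' @param samples An `endocea_psa` data.frame covering all strategies.
#' @param wtp_grid Willingness-to-pay values.
#' @return Data.frame with one row per WTP value and one probability column
#'   per strategy; the columns sum to 1 at every WTP.
#' @export
ceac_multiway <- function(samples, wtp_grid = seq(0, 400000, by = 5000)) {
  strategies <- unique(samples$strategy)
  wide_q <- stats::reshape(samples[, c("draw", "strategy", "qalys")],
                           idvar = "draw", timevar = "strategy",
                           direction = "wide")
  wide_c <- stats::reshape(samples[, c("draw", "strategy", "cost")],
                           idvar = "draw", timevar = "strategy",
                           direction = "wide")
  qm <- as.matrix(wide_q[, paste0("qalys.", strategies)])
  cm <- as.matrix(wide_c[, paste0("cost.", strategies)])
  rows <- lapply(wtp_grid, function(w) {
    nmb <- w * qm - cm
    best <- strategies[max.col(nmb, ties.method = "first")]
    cbind(data.frame(wtp = w),
          as.data.frame(as.list(stats::setNames(
            vapply(strategies, function(s) mean(best == s), numeric(1)),
            strategies))))
  })
  do.call(rbind, rows)
}
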