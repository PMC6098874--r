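test_that("the strategy catalog encodes the three regimens", {
  cats <- strategy_catalog(fx_params())
  expect_named(cats, c("tamoxifen", "ai_5yr", "ai_switch"))
  expect_true(all(unlist(cats$tamoxifen$rr) == 1))
  expect_equal(cats$ai_5yr$rr$rr_distant, 0.830)
  expect_equal(cats$ai_switch$rr$rr_contralateral, 0.63)
  expect_equal(cats$ai_switch$schedule$drug, c("tamoxifen", "letrozole"))
  expect_equal(cats$ai_switch$schedule$start, c(0, 30))
  expect_equal(cats$ai_5yr$schedule$end, 60)
  # schedules tile the therapy period without overlap
  for (s in cats) {
    sch <- s$schedule[order(s$schedule$start), ]
    if (nrow(sch) > 1)
      expect_true(all(sch$end[-nrow(sch)] <= sch$start[-1]))
  }
})

test_that("transition rows are proper distributions with correct structure", {
  p <- fx_params(); lt <- fx_lt()
  s <- strategy_catalog(p)$ai_5yr
  states <- c("disease_free", "disease_free_fracture", "local_recurrence",
              "contralateral_recurrence", "distant_recurrence",
              "endometrial_cancer", "dead")
  for (st in states) {
    for (cyc in c(0, 30, 200)) {
      tr <- transition_row(st, cyc, s, p, lt, months_in_state = 3)
      expect_equal(sum(tr), 1, tolerance = 1e-12)
      expect_true(all(tr >= 0))
    }
  }
  expect_identical(transition_row("dead", 10, s, p, lt), c(dead = 1))
  expect_error(transition_row("limbo", 0, s, p, lt), "unknown health state")
  # a fracture event is possible from disease-free but not a second one
  # from the flagged substate (whose only fracture-named entry is the stay)
  tr_dfs <- transition_row("disease_free", 5, s, p, lt)
  tr_fx <- transition_row("disease_free_fracture", 5, s, p, lt)
  expect_gt(tr_dfs[["disease_free_fracture"]], 0)
  expect_equal(sum(names(tr_fx) == "disease_free_fracture"), 1L)
  expect_false(anyDuplicated(names(tr_fx)) > 0)
})

test_that("distant-recurrence death matches its input with no background", {
  p <- fx_params()
  s <- strategy_catalog(p)$tamoxifen
  tr <- transition_row("distant_recurrence", 12, s, p, fx_zero_lt())
  expect_equal(tr[["dead_breast_cancer"]], 0.0290)
  tr <- transition_row("endometrial_cancer", 12, s, p, fx_zero_lt())
  expect_equal(tr[["dead_endometrial_cancer"]], 0.0098)
})

test_that("zeroed hazards leave the cohort disease-free forever", {
  p <- fx_zero_hazard_params()
  s <- strategy_catalog(p)$tamoxifen
  tr0 <- transition_row("disease_free", 0, s, p, fx_zero_lt())
  expect_equal(tr0[["disease_free"]], 1)
  trace <- run_cohort(s, p, fx_zero_lt())
  expect_true(all(trace$disease_free == 1))
})

test_that("certain annual death empties the cohort within a year", {
  p <- fx_params()
  lt <- life_table(0:100, rep(1, 101))
  trace <- run_cohort(strategy_catalog(p)$tamoxifen, p, lt)
  dead <- with(trace, dead_bc + dead_endometrial + dead_other)
  expect_gt(dead[13], 1 - 1e-6)
})

test_that("every trace row conserves mass across all strategies", {
  for (trace in fx_traces()) {
    totals <- rowSums(trace[, occupancy_cols])
    expect_lt(max(abs(totals - 1)), 1e-10)
    dead <- with(trace, dead_bc + dead_endometrial + dead_other)
    expect_true(all(diff(dead) >= -1e-14))      # death is absorbing
    expect_true(all(as.matrix(trace[, occupancy_cols]) >= 0))
  }
})

test_that("with no excess hazards life-years equal table life expectancy", {
  p <- fx_zero_hazard_params()
  trace <- run_cohort(strategy_catalog(p)$tamoxifen, p, fx_lt())
  out <- summarize(trace)
  le <- life_expectancy(fx_lt(), p$econ$start_age, p$econ$max_age)
  expect_lt(abs(out$life_years - le), 1 / 24)
  expect_equal(out$life_years, out$pf_life_years)
})

test_that("event cumulatives sum incident events and respect bounds", {
  p <- fx_zero_hazard_params()
  trace <- run_cohort(strategy_catalog(p)$tamoxifen, p, fx_zero_lt())
  ev <- event_cumulatives(trace)
  expect_true(all(ev == 0))

  trace <- fx_traces()$tamoxifen
  ev <- event_cumulatives(trace)
  expect_true(all(ev >= 0 & ev <= 1))
  # first-recurrence decomposition: exits from disease-free to the three
  # recurrence destinations
  n <- nrow(trace) - 1L
  direct_distant <- sum(trace$inc_first_recurrence) -
    sum(trace$inc_local) - sum(trace$inc_contralateral)
  expect_lte(direct_distant, ev[["distant"]])
  # endometrial incidence cannot exceed hazard x disease-free exposure
  dfs_exposure <- sum(trace$disease_free[seq_len(n)] +
                        trace$disease_free_fracture[seq_len(n)])
  expect_lte(ev[["endometrial"]],
             prob_to_rate(fx_params()$clinical$p_endometrial) * dfs_exposure)
})

test_that("switch-strategy side-effect risk ratios start at the switch", {
  p <- fx_params(); lt <- fx_lt()
  cats <- strategy_catalog(p)
  # before month 30 the switch arm behaves like tamoxifen for endometrial
  # cancer; afterwards like the AI arm
  # the underlying endometrial rates are equal; the destination
  # probabilities differ only through the competing-risk normalisation
  # (order 1e-4 relative at these monthly magnitudes)
  tr_pre <- transition_row("disease_free", 10, cats$ai_switch, p, lt)
  tr_tam <- transition_row("disease_free", 10, cats$tamoxifen, p, lt)
  expect_equal(tr_pre[["endometrial_cancer"]], tr_tam[["endometrial_cancer"]],
               tolerance = 1e-3)
  tr_post <- transition_row("disease_free", 40, cats$ai_switch, p, lt)
  tr_ai <- transition_row("disease_free", 40, cats$ai_5yr, p, lt)
  expect_equal(tr_post[["endometrial_cancer"]], tr_ai[["endometrial_cancer"]],
               tolerance = 1e-3)
  # cumulative endometrial risk is ordered tamoxifen > switch > AI 5-year
  ev <- vapply(fx_traces(), function(tr)
    event_cumulatives(tr)[["endometrial"]], numeric(1))
  expect_gt(ev[["tamoxifen"]], ev[["ai_switch"]])
  expect_gt(ev[["ai_switch"]], ev[["ai_5yr"]])
})

test_that("treatment-limited side-effect option reverts risks after therapy", {
  p <- fx_params()
  p$options$side_effect_duration <- "treatment"
  lt <- fx_lt()
  s <- strategy_catalog(p)$ai_5yr
  tr_on <- transition_row("disease_free", 30, s, p, lt)
  tr_off <- transition_row("disease_free", 90, s, p, lt)
  s_tam <- strategy_catalog(p)$tamoxifen
  tr_tam <- transition_row("disease_free", 90, s_tam, p, lt)
  expect_lt(tr_on[["endometrial_cancer"]], tr_off[["endometrial_cancer"]])
  expect_equal(tr_off[["endometrial_cancer"]], tr_tam[["endometrial_cancer"]],
               tolerance = 1e-3)
})

test_that("uniformly favourable risk ratios dominate on QALYs", {
  p <- set_param(fx_params(), "rr_ai_fracture", 1)
  # all remaining AI risk ratios are <= 1, so the letrozole arm can only
  # gain health relative to tamoxifen
  expect_true(all(unlist(strategy_catalog(p)$ai_5yr$rr) <= 1))
  out <- run_model(p, fx_lt(), strategies = c("tamoxifen", "ai_5yr"))
  expect_gte(out$ai_5yr$discounted_qalys, out$tamoxifen$discounted_qalys)
  expect_gte(out$ai_5yr$life_years, out$tamoxifen$life_years)
})
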