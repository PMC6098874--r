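test_that("discount factors follow annual compounding at monthly resolution", {
  expect_equal(discount_factor(0, 0.05), 1)
  expect_equal(discount_factor(12, 0.05), 1 / 1.05)
  expect_equal(discount_factor(c(0, 60, 240), 0), rep(1, 3))
  expect_equal(discount_factor(30, 0.05), 1.05^(-2.5))
  expect_error(discount_factor(-1, 0.05), "non-negative")
})

test_that("joint utility matches the anchored formula and its bounds", {
  expect_equal(joint_utility(0.94, 0.70), 0.70 - 0.70 * 0.06 * 0.30)
  expect_equal(joint_utility(0.94, 0.70), 0.6874)
  expect_equal(joint_utility(1, 1), 1)
  for (u in c(0, 0.3, 0.77, 1)) {
    expect_equal(joint_utility(u, 1), u)   # perfect-health partner
    expect_equal(joint_utility(1, u), u)
  }
  set.seed(105)
  ui <- stats::runif(50); uj <- stats::runif(50)
  expect_equal(joint_utility(ui, uj), joint_utility(uj, ui))  # symmetric
  expect_true(all(joint_utility(ui, uj) <= pmin(ui, uj) + 1e-15))
  expect_true(all(joint_utility(ui, uj) >= 0))
  expect_equal(joint_utility(0.9, 0.8, model = "multiplicative"), 0.72)
})

test_that("state utilities include therapy disutility and fracture joint", {
  p <- fx_params()
  expect_equal(cycle_utility("disease_free", TRUE, p), 0.93)
  expect_equal(cycle_utility("disease_free", FALSE, p), 0.94)
  expect_equal(cycle_utility("disease_free_fracture", FALSE, p), 0.6874)
  expect_equal(cycle_utility("local_recurrence", FALSE, p), 0.78)
  expect_equal(cycle_utility("contralateral_recurrence", FALSE, p), 0.78)
  expect_equal(cycle_utility("distant_recurrence", FALSE, p), 0.53)
  # therapy has stopped in the recurrence states: no disutility there
  expect_equal(cycle_utility("distant_recurrence", TRUE, p), 0.53)
  expect_equal(cycle_utility("endometrial_cancer", FALSE, p), 0.83)
  expect_equal(cycle_utility("dead", FALSE, p), 0)
})

test_that("cycle costs follow the schedule and the costing convention", {
  p <- fx_params()
  cats <- strategy_catalog(p)
  expect_equal(cycle_cost("disease_free", 0, cats$ai_5yr, 10, p),
               11.9 * 30.4375)
  expect_equal(cycle_cost("disease_free", 0, cats$tamoxifen, 10, p),
               1.4 * 30.4375)
  # switch arm: tamoxifen price before month 30, letrozole after
  expect_equal(cycle_cost("disease_free", 0, cats$ai_switch, 10, p),
               1.4 * 30.4375)
  expect_equal(cycle_cost("disease_free", 0, cats$ai_switch, 45, p),
               11.9 * 30.4375)
  # off schedule: no drug cost
  expect_equal(cycle_cost("disease_free", 0, cats$ai_5yr, 61, p), 0)
  expect_equal(cycle_cost("dead", 0, cats$ai_5yr, 10, p), 0)
  # default costing: monthly management value throughout
  expect_equal(cycle_cost("distant_recurrence", 0, cats$tamoxifen, 80, p), 888)
  expect_equal(cycle_cost("distant_recurrence", 7, cats$tamoxifen, 80, p), 888)
  expect_equal(cycle_cost("local_recurrence", 3, cats$tamoxifen, 80, p), 865)
  # tabulated first-month premium under the alternative attribution
  pf <- fx_params(); pf$options$recurrence_entry_cost <- "first_month"
  expect_equal(cycle_cost("distant_recurrence", 0, cats$tamoxifen, 80, pf),
               83008)
  expect_equal(cycle_cost("distant_recurrence", 1, cats$tamoxifen, 80, pf),
               888)
  expect_equal(cycle_cost("local_recurrence", 0, cats$tamoxifen, 80, pf),
               75421)
  expect_equal(cycle_cost("contralateral_recurrence", 0, cats$tamoxifen,
                          80, pf), 75421)
})

test_that("summarize degenerates correctly at zero cost and zero discount", {
  p <- fx_zero_hazard_params()
  for (key in c("cost_tamoxifen_day", "cost_letrozole_day"))
    p <- set_param(p, key, 0)
  trace <- run_cohort(strategy_catalog(p)$tamoxifen, p, fx_zero_lt())
  out <- summarize(trace)
  expect_equal(out$discounted_cost, 0)

  # all utilities 1, no disutility, no discount: QALYs == life-years
  p2 <- fx_params()
  for (key in c("u_dfs", "u_regional", "u_distant", "u_endometrial",
                "u_fracture"))
    p2 <- set_param(p2, key, 1)
  p2 <- set_param(p2, "disutility_endocrine", 0)
  p2 <- set_param(p2, "annual_discount", 0)
  trace <- run_cohort(strategy_catalog(p2)$tamoxifen, p2, fx_lt())
  out <- summarize(trace)
  expect_equal(out$discounted_qalys, out$life_years, tolerance = 1e-12)
})

test_that("discounting shrinks totals and utilities cap QALYs", {
  for (out in fx_outcomes()) {
    expect_lte(out$discounted_life_years, out$life_years)
    expect_lte(out$discounted_qalys,
               fx_params()$utilities$u_dfs * out$discounted_life_years)
    expect_lte(out$pf_life_years, out$life_years)
    expect_gte(out$discounted_cost, 0)
  }
})

test_that("comparisons compute ICERs and dominance labels", {
  mk <- function(cost, qalys)
    structure(list(discounted_cost = cost, discounted_qalys = qalys,
                   strategy = "x"), class = "endocea_outcomes")
  cmp <- compare(mk(28797, 10.84), mk(13613, 10.44))
  expect_equal(cmp$icer, (28797 - 13613) / (10.84 - 10.44))
  expect_equal(cmp$icer, 37960, tolerance = 1e-4)
  cmp <- compare(mk(100, 5), mk(100, 5))
  expect_identical(cmp$icer, "undefined")
  expect_identical(compare(mk(90, 6), mk(100, 5))$icer, "dominant")
  expect_identical(compare(mk(110, 4), mk(100, 5))$icer, "dominated")
})

test_that("the AI 5-year ICER rises strictly with the letrozole price", {
  lt <- fx_lt()
  prices <- c(5, 11.9, 20, 35, 47.3)
  icers <- vapply(prices, function(px) {
    p <- set_param(fx_params(), "cost_letrozole_day", px)
    out <- run_model(p, lt, strategies = c("tamoxifen", "ai_5yr"))
    cmp <- compare(out$ai_5yr, out$tamoxifen)
    if (is.numeric(cmp$icer)) cmp$icer else -Inf
  }, numeric(1))
  expect_true(all(diff(icers) > 0))
})

test_that("half-cycle correction changes accruals only marginally", {
  p <- fx_params()
  p$options$half_cycle_correction <- TRUE
  trace <- run_cohort(strategy_catalog(p)$tamoxifen, p, fx_lt())
  out_hc <- summarize(trace)
  out <- fx_outcomes()$tamoxifen
  expect_lt(abs(out_hc$discounted_qalys - out$discounted_qalys), 0.02)
  expect_lt(abs(out_hc$life_years - out$life_years), 0.1)
  expect_false(out_hc$discounted_qalys == out$discounted_qalys)
})
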