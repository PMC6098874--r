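# Shared fixtures, computed lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

fx_params <- function() fixture("params", default_params)
fx_lt <- function() fixture("lt", synth_life_table)

# base-case traces and outcomes for the three strategies (one cohort run
# each; reused by the markov, economics and acceptance tests)
fx_traces <- function() fixture("traces", function() {
  cats <- strategy_catalog(fx_params())
  lapply(cats, run_cohort, p = fx_params(), lt = fx_lt())
})
fx_outcomes <- function() fixture("outcomes", function()
  lapply(fx_traces(), summarize))

# a parameter set with every hazard, adverse event and background death
# switched off (immortal disease-free cohort)
fx_zero_hazard_params <- function() fixture("zero_hazard", function() {
  p <- fx_params()
  for (key in c("lam_distant", "lam_local", "lam_contralateral",
                "p_endometrial", "p_fracture"))
    p <- set_param(p, key, 0)
  p
})

fx_zero_lt <- function() fixture("zero_lt", function()
  life_table(0:100, rep(0, 101)))

occupancy_cols <- c("disease_free", "disease_free_fracture", "local",
                    "contralateral", "distant", "endometrial", "dead_bc",
                    "dead_endometrial", "dead_other")

# relative difference helper for reproduction-tier checks
rel_err <- function(x, ref) abs(x - ref) / abs(ref)
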