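Package: endocea
Title: Markov Cohort Cost-Effectiveness Model of Adjuvant Endocrine Therapy
    in Early Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lifetime Markov state-transition model comparing three adjuvant
    endocrine strategies (five years of tamoxifen, five years of letrozole,
    and a tamoxifen-then-letrozole switch) for postmenopausal women with
    estrogen receptor positive early breast cancer, from the Chinese
    health-care payer perspective. Implements parametric survival
    extrapolation (exponential and Weibull) of recurrence risks, competing
    background mortality from an age-specific life table (file-based or a
    synthetic Gompertz-Makeham generator), discounted cost and
    quality-adjusted life-year projection, incremental cost-effectiveness
    ratios, one-way (tornado) and age sensitivity analyses, and
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
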