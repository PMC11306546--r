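Package: chwpay
Title: Break-Even Medicaid Payment Thresholds for Community Health Worker Programs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Microsimulation of the minimum Medicaid fee-for-service rate
    (per 30-minute visit, billing code 98960) and capitated per-member-per-month
    rate required to cover the full cost of employing a community health worker,
    across geographies. Composes labor, ratio-allocated supervision, and
    five-component overhead into a per-CHW monthly cost, converts it to
    break-even payment rates given visit capacity and panel size, propagates
    input uncertainty by Monte Carlo resampling to percentile credible
    intervals, and runs supervisor-substitution and panel-size sensitivity
    analyses. Includes a synthetic geography-table generator emulating the
    statistical structure of BLS OEWS wage data and survey-based overhead.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
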