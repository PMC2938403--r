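Package: dppcea
Title: Markov Cohort Cost-Effectiveness Model of a Community Diabetes
    Prevention Program
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A six-state Markov cohort model comparing a community-based,
    group-format modified Diabetes Prevention Program (mDPP) lifestyle
    intervention against usual care over a three-year horizon with monthly
    cycles. Computes discounted costs and quality-adjusted life-years
    (QALYs), incremental cost-effectiveness ratios (ICERs), one-way
    (tornado) sensitivity analyses, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and named scenario analyses.
    Includes an individual-level microsimulation used as an independent
    validation oracle for the cohort engine, a synthetic life-table
    generator, and a YAML parameter-file interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
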