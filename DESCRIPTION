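Package: waitcea
Title: Cost-Utility Modelling of Reduced Waiting Times for Elective Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An adaptable cost-utility framework for valuing reductions in
    elective-surgery waiting times. Incremental quality-adjusted life years
    (QALYs) are computed from a segment model comparing an early-surgery arm
    against a delayed, missed, or fatal counterfactual; discounted incremental
    costs are decomposed into direct medical and indirect (patient and
    caregiver productivity) components. The package reports incremental
    cost-effectiveness ratios from societal and payer perspectives, a
    benefit-cost ratio, catastrophic-health-expenditure exposure under the
    budget-share method, and deterministic (tornado) and probabilistic
    (Monte Carlo) sensitivity analyses. Model runs are driven entirely by
    declarative YAML parameter files, and a fixture generator produces
    illustrative and calibrated parameter sets so the pipeline is usable
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
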