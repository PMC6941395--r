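Package: qwtsim
Title: Monte Carlo Scenario Simulation of Alcohol Withdrawal Treatment Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cohort-level outcomes of inpatient alcohol withdrawal
    treatment under alternative treatment-allocation scenarios. Per-patient
    hospitalisation counts and hospital days are modelled as overdispersed
    negative binomial variables (dispersion derived from published means and
    standard deviations by the method of moments), abstinence and mortality as
    binomial variables. For each scenario the package draws replicate cohort
    totals, summarises them with means and percentile confidence intervals,
    and compares scenarios to baseline by paired per-replicate differences.
    Includes a synthetic admissions-register generator for end-to-end testing
    and parameter-recovery checks without real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
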