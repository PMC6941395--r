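# Published per-arm outcome parameters used across the suite:
# count outcomes over 5 years (per-patient mean, SD), binary outcomes over
# 28 months (events / denominator).
table1_params <- function() {
  study_parameter_set(
    hospitalisations = list(
      qwt = count_outcome_params(3.5, 4.4, horizon = "5 years"),
      swt = count_outcome_params(7.3, 11.3, horizon = "5 years")),
    hospital_days = list(
      qwt = count_outcome_params(55.7, 75.4, horizon = "5 years"),
      swt = count_outcome_params(135.8, 167.3, horizon = "5 years")),
    abstinence = list(
      qwt = binary_outcome_params(29, 92, horizon = "28 months"),
      swt = binary_outcome_params(13, 90, horizon = "28 months")),
    death = list(
      qwt = binary_outcome_params(7, 92, horizon = "28 months"),
      swt = binary_outcome_params(13, 90, horizon = "28 months"))
  )
}

table1_scenarios <- function(total_n = 2051) {
  list(
    baseline = structure(
      allocate_scenario(total_n, label = "baseline", qwt_n = 170),
      baseline = TRUE),
    qwt25 = allocate_scenario(total_n, 0.25, "qwt25"),
    qwt50 = allocate_scenario(total_n, 0.50, "qwt50")
  )
}

# analytic SD of a simulated cohort total under an allocation
analytic_total_sd <- function(allocation, entry) {
  arm_var <- function(p, n) {
    if (inherits(p, "count_params")) n * (p$mean + p$mean^2 / p$dispersion)
    else n * p$probability * (1 - p$probability)
  }
  sqrt(arm_var(entry$qwt, allocation$n_qwt) +
         arm_var(entry$swt, allocation$n_swt))
}
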