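# qwtsim

Monte Carlo scenario simulation of inpatient alcohol-withdrawal treatment
outcomes.

## What it is for

People with severe alcohol use disorder who seek inpatient withdrawal
treatment can receive either a short somatic detoxification (SWT, 3–5 days
of pharmacological support) or a "qualified" withdrawal treatment (QWT, an
extended programme of three weeks or more that adds psychosocial
interventions). Prospective follow-up studies found QWT superior on
rehospitalisation, abstinence and survival, yet few inpatients receive it.
`qwtsim` is for health-services researchers who want to quantify the
what-if: for a fixed cohort of treatment-seeking inpatients, how would
5-year hospitalisation burden and 28-month abstinence and mortality change
if a larger share of the cohort received QWT instead of SWT?

## The model

For a scenario that allocates $n_Q$ patients to QWT and $n_S = N - n_Q$ to
SWT:

* per-patient **counts** (hospitalisations, hospital days) are negative
  binomial, NB($\mu$, $k$), with the size parameter recovered from
  published moments by $k = \mu^2/(\sigma^2 - \mu)$, so the NB variance
  $\mu + \mu^2/k$ round-trips $\sigma^2$ exactly; the arm total of $n$
  patients is drawn as NB($n\mu$, $nk$), exactly the distribution of the
  per-patient sum;
* per-patient **binaries** (abstinent, dead) are Bernoulli($p$) with the
  published event fractions; arm totals are Binomial($n$, $p$);
* a cohort total is the sum of the two arm totals; 10,000 replicate totals
  per scenario × outcome give the mean and the empirical 2.5–97.5
  percentile interval;
* scenarios are compared to baseline pairwise by replicate:
  $d_i = s_i - b_i$ and $r_i = 100\,d_i/b_i$, summarised the same way.

The bundled default configuration encodes a register of 2051 inpatients
(170 observed QWT), per-arm parameters from two prospective studies, and
the three scenarios: baseline (8% QWT), 25% QWT (513/1538) and 50% QWT
(1026/1025).

## Worked example

```r
library(qwtsim)
cfg <- load_config(default_config_path())
sim <- run_simulation(build_parameter_set(cfg), build_scenarios(cfg),
                      replicates = 10000, master_seed = 20162017)
rt  <- build_results_table(sim, total_n = 2051)
print(rt)
```

```
hospitalisations:
  baseline   (QWT  170 / SWT 1881): 14,335 (13,379 to 15,312)
  qwt25      (QWT  513 / SWT 1538): 13,025 (12,141 to 13,941)    vs baseline: -9% (-17 to 0%)
  qwt50      (QWT 1026 / SWT 1025): 11,077 (10,345 to 11,864)    vs baseline: -23% (-30 to -15%)
hospital_days:
  baseline   (QWT  170 / SWT 1881): 264,885 (250,529 to 279,561)
  qwt25      (QWT  513 / SWT 1538): 237,533 (224,320 to 251,086) vs baseline: -10% (-17 to -3%)
  qwt50      (QWT 1026 / SWT 1025): 196,335 (185,001 to 207,926) vs baseline: -26% (-32 to -20%)
abstinence:
  baseline   (QWT  170 / SWT 1881): 16% (14 to 17%)
  qwt25      (QWT  513 / SWT 1538): 19% (17 to 20%)              vs baseline: +18% (3 to 35%)
  qwt50      (QWT 1026 / SWT 1025): 23% (21 to 25%)              vs baseline: +45% (28 to 65%)
death:
  baseline   (QWT  170 / SWT 1881): 14% (12 to 15%)
  qwt25      (QWT  513 / SWT 1538): 13% (11 to 14%)              vs baseline: -8% (-21 to 7%)
  qwt50      (QWT 1026 / SWT 1025): 11% (10 to 12%)              vs baseline: -20% (-33 to -7%)
```

Reading it: under the observed allocation the cohort accumulates about
14,300 hospitalisations and 265,000 hospital days over five years, with
16% of patients abstinent and 14% dead within 28 months. Moving half the
cohort into QWT cuts expected hospitalisations by 23% and hospital days by
26%, raises the number abstinent by 45%, and lowers deaths by 20%;
brackets are percentile intervals over the 10,000 replicates.

The same pipeline is scriptable from a shell via the thin wrapper in
`inst/scripts/qwtsim.R` (`simulate`, `synth` and `check` subcommands), and
`cmd_synth()` generates a synthetic admissions register plus patient-level
outcome table for end-to-end testing — no real patient data are used or
needed anywhere.

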