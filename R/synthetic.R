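#' Generate a synthetic admissions register
#'
#' Emulates a two-hospital inpatient admissions register for alcohol
#' withdrawal treatment: one row per patient with an ICD-10 F10.x main
#' diagnosis, sex, treatment arm (QWT or SWT) and admission year. Arm counts
#' match [allocate_scenario()] exactly (the arm labels are a random
#' permutation with fixed counts); diagnosis and sex are drawn i.i.d. from
#' the supplied mixes. The default mixes reproduce the observed register
#' composition: 53.5% withdrawal state (F10.3), 38.6% dependence syndrome
#' (F10.2), 5.5% acute intoxication (F10.0), 2.3% harmful use (F10.1), and
#' 26.2% female.
#'
#' @param total_n positive integer register size.
#' @param qwt_share share of patients in the QWT arm, in `[0, 1]`.
#' @param diagnosis_mix named probability vector over F10 codes; must sum
#'   to 1 (tolerance 1e-9).
#' @param female_share probability a patient is female, in `[0, 1]`.
#' @param seed integer seed; the register is deterministic given the seed.
#' @param years integer vector of admission years to draw from uniformly.
#' @return a `data.frame` of class `admissions_register` with columns
#'   `patient_id`, `main_diagnosis`, `sex`, `arm`, `admission_year`.
#' @export
generate_admissions_register <- function(total_n, qwt_share,
                                         diagnosis_mix = c("F10.3" = 0.535,
                                                           "F10.2" = 0.386,
                                                           "F10.0" = 0.055,
                                                           "F10.1" = 0.023),
                                         female_share = 0.262,
                                         seed = 1,
                                         years = c(2016L, 2017L)) {
  # published diagnosis percentages sum to 99.9% after rounding; accept a
  # mix within rounding slack of 1 and renormalise, reject anything worse
  if (abs(sum(diagnosis_mix) - 1) > 5e-3 || any(diagnosis_mix < 0)) {
    abort("qwtsim_config_error", "diagnosis_mix must be non-negative and sum to 1")
  }
  diagnosis_mix <- diagnosis_mix / sum(diagnosis_mix)
  if (is.null(names(diagnosis_mix)) || any(names(diagnosis_mix) == "")) {
    abort("qwtsim_config_error", "diagnosis_mix must name its ICD-10 codes")
  }
  if (female_share < 0 || female_share > 1) {
    abort("qwtsim_share_error", "female_share must lie in [0, 1]")
  }
  alloc <- allocate_scenario(total_n, qwt_share, label = "register")
  reg <- with_seed(seed, {
    arm <- sample(c(rep("QWT", alloc$n_qwt), rep("SWT", alloc$n_swt)))
    data.frame(
      patient_id = sprintf("P%06d", seq_len(total_n)),
      main_diagnosis = sample(names(diagnosis_mix), total_n, replace = TRUE,
                              prob = diagnosis_mix),
      sex = sample(c("female", "male"), total_n, replace = TRUE,
                   prob = c(female_share, 1 - female_share)),
      arm = arm,
      admission_year = sample(as.integer(years), total_n, replace = TRUE)
    )
  })
  class(reg) <- c("admissions_register", "data.frame")
  reg
}

#' Derive the baseline scenario allocation from a register
#'
#' Counts the QWT and SWT rows, mirroring how an observed baseline scenario
#' is read off hospital records.
#'
#' @param register an `admissions_register` (or any data.frame with an
#'   `arm` column of "QWT"/"SWT" values).
#' @param label label for the resulting scenario, default `"baseline"`.
#' @return a [allocate_scenario()] object.
#' @export
register_to_allocation <- function(register, label = "baseline") {
  if (nrow(register) == 0) {
    abort("qwtsim_config_error", "register is empty")
  }
  n_qwt <- sum(register$arm == "QWT")
  allocate_scenario(nrow(register), label = label, qwt_n = n_qwt)
}

#' Generate patient-level outcomes for an allocated cohort
#'
#' Realises the outcome model at patient level: each patient draws their
#' arm's negative-binomial counts (hospitalisations, hospital days) and
#' Bernoulli flags (abstinent, dead), independently across outcomes and
#' patients. Column sums of the result are distributed like the aggregate
#' totals drawn by [simulate_scenario_outcome()].
#'
#' @param allocation a [allocate_scenario()] object (QWT rows come first).
#' @param params a [study_parameter_set()].
#' @param seed integer seed; deterministic given the seed.
#' @return a `data.frame` of class `patient_outcomes`: `patient_id`, `arm`,
#'   plus one integer column per count outcome and one logical column per
#'   binary outcome, named after the parameter-set outcomes.
#' @export
generate_patient_outcomes <- function(allocation, params, seed = 1) {
  if (!inherits(allocation, "scenario_allocation")) {
    abort("qwtsim_type_error", "allocation must be a scenario_allocation")
  }
  if (!inherits(params, "parameter_set")) {
    abort("qwtsim_type_error", "params must be a parameter_set")
  }
  n <- allocation$total_n
  arm <- c(rep("QWT", allocation$n_qwt), rep("SWT", allocation$n_swt))
  tab <- data.frame(patient_id = sprintf("P%06d", seq_len(n)), arm = arm)
  for (nm in names(params)) {
    e <- params[[nm]]
    col <- with_seed(stream_seed(seed, "patient", nm), {
      draw_arm <- function(p, size) {
        if (size == 0) return(numeric(0))
        if (inherits(p, "count_params")) {
          stats::rnbinom(size, size = p$dispersion, mu = p$mean)
        } else {
          stats::rbinom(size, 1, p$probability)
        }
      }
      c(draw_arm(e$qwt, allocation$n_qwt), draw_arm(e$swt, allocation$n_swt))
    })
    tab[[nm]] <- if (inherits(e$qwt, "binary_params")) as.logical(col)
                 else as.integer(col)
  }
  class(tab) <- c("patient_outcomes", "data.frame")
  tab
}

#' Estimate outcome parameters from a patient-level table
#'
#' Recovers the per-arm summaries a follow-up study would publish: sample
#' mean and SD (denominator n - 1) with the moment dispersion via
#' [derive_dispersion()] for count columns; event counts, denominators and
#' proportions for logical columns. An arm whose sample variance does not
#' exceed its mean has no valid negative-binomial dispersion; it is reported
#' with `dispersion = NA` and `dispersion_estimable = FALSE` rather than
#' failing.
#'
#' @param table a `patient_outcomes` data.frame (needs `arm` plus outcome
#'   columns).
#' @return a `data.frame` with one row per outcome x arm: columns `outcome`,
#'   `arm`, `type`, `n`, `mean`, `sd`, `dispersion`, `dispersion_estimable`,
#'   `events`, `denominator`, `probability`.
#' @export
estimate_outcome_params <- function(table) {
  outcome_cols <- setdiff(names(table), c("patient_id", "arm"))
  if (length(outcome_cols) == 0) {
    abort("qwtsim_config_error", "table has no outcome columns")
  }
  rows <- list()
  for (nm in outcome_cols) {
    for (arm in c("QWT", "SWT")) {
      v <- table[[nm]][table$arm == arm]
      if (length(v) == 0) {
        abort("qwtsim_samples_error",
              "arm %s is empty; cannot estimate outcome '%s'", arm, nm)
      }
      if (is.logical(v)) {
        rows[[length(rows) + 1]] <- data.frame(
          outcome = nm, arm = arm, type = "binary", n = length(v),
          mean = NA_real_, sd = NA_real_, dispersion = NA_real_,
          dispersion_estimable = NA,
          events = sum(v), denominator = length(v),
          probability = mean(v))
      } else {
        m <- mean(v); s <- stats::sd(v)
        estimable <- is.finite(s) && s^2 > m && m > 0
        rows[[length(rows) + 1]] <- data.frame(
          outcome = nm, arm = arm, type = "count", n = length(v),
          mean = m, sd = s,
          dispersion = if (estimable) derive_dispersion(m, s) else NA_real_,
          dispersion_estimable = estimable,
          events = NA_integer_, denominator = NA_integer_,
          probability = NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read the register and outcome tables as CSV
#'
#' UTF-8, header row, RFC 4180 quoting. Reading restores the column classes
#' so that a write/read round trip is exact (ids and codes as character,
#' flags as logical, counts as integer).
#'
#' @param x the table to write.
#' @param path CSV path.
#' @return `write_*`: the path, invisibly; `read_*`: the restored table.
#' @export
write_register <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_register
#' @export
read_register <- function(path) {
  reg <- utils::read.csv(path, colClasses = c(
    patient_id = "character", main_diagnosis = "character",
    sex = "character", arm = "character", admission_year = "integer"),
    fileEncoding = "UTF-8")
  class(reg) <- c("admissions_register", "data.frame")
  reg
}

#' @rdname write_register
#' @export
write_outcomes <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_register
#' @export
read_outcomes <- function(path) {
  head <- utils::read.csv(path, nrows = 1, fileEncoding = "UTF-8")
  classes <- vapply(names(head), function(nm) {
    if (nm %in% c("patient_id", "arm")) "character"
    else if (is.logical(head[[nm]])) "logical" else "integer"
  }, character(1))
  tab <- utils::read.csv(path, colClasses = classes, fileEncoding = "UTF-8")
  class(tab) <- c("patient_outcomes", "data.frame")
  tab
}
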