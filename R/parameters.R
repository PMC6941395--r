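#' Negative-binomial dispersion from published mean and SD
#'
#' Method-of-moments estimate of the negative-binomial size parameter k from
#' a published per-patient mean and standard deviation:
#' \deqn{k = \mu^2 / (\sigma^2 - \mu)}
#' Under this parameterisation the NB variance is \eqn{\mu + \mu^2/k}, so the
#' derived k reproduces the input variance exactly (round trip). Smaller k
#' means stronger overdispersion.
#'
#' @param mean positive per-patient mean (events or days over the horizon).
#' @param sd positive per-patient standard deviation, same units.
#' @return positive dispersion (size) parameter.
#'
#' A negative binomial requires overdispersion: if `sd^2 <= mean` the
#' distribution is undefined and an error of class
#' `qwtsim_overdispersion_error` is signalled — callers must not silently
#' fall back to a Poisson model.
#' @export
#' @examples
#' derive_dispersion(7.3, 11.3)    # 0.443 to 3 dp
#' derive_dispersion(55.7, 75.4)   # 0.551 to 3 dp
derive_dispersion <- function(mean, sd) {
  if (!is.numeric(mean) || !is.numeric(sd)) {
    abort("qwtsim_type_error", "mean and sd must be numeric")
  }
  if (any(mean <= 0)) {
    abort("qwtsim_overdispersion_error", "mean must be positive (got %s)",
          paste(mean[mean <= 0], collapse = ", "))
  }
  v <- sd^2
  if (any(v <= mean)) {
    abort("qwtsim_overdispersion_error",
          "variance (%s) must exceed mean (%s): negative binomial undefined without overdispersion",
          paste(signif(v[v <= mean], 6), collapse = ", "),
          paste(signif(mean[v <= mean], 6), collapse = ", "))
  }
  mean^2 / (v - mean)
}

#' Event probability from printed counts
#'
#' @param events non-negative integer count of events.
#' @param denominator positive integer group size.
#' @return `events / denominator`, a probability in `[0, 1]`.
#' @export
#' @examples
#' probability_from_counts(29, 92)  # 0.315..., prints as 31.5%
probability_from_counts <- function(events, denominator) {
  if (any(denominator < 1)) {
    abort("qwtsim_counts_error", "denominator must be a positive integer")
  }
  if (any(events < 0) || any(events > denominator)) {
    abort("qwtsim_counts_error",
          "events (%s) must lie in [0, denominator = %s]", events, denominator)
  }
  events / denominator
}

#' Parameters of a count outcome for one treatment arm
#'
#' Bundles the per-patient mean, SD and negative-binomial dispersion for a
#' count outcome (hospitalisations, hospital days) over a stated horizon.
#' If `dispersion` is `NULL` it is derived from the moments via
#' [derive_dispersion()]; an explicit value (e.g. one printed in a source
#' table) may be supplied instead and is validated for positivity only.
#'
#' @param mean positive per-patient mean.
#' @param sd positive per-patient SD; must satisfy `sd^2 > mean`.
#' @param dispersion optional positive size parameter override.
#' @param horizon label for the outcome horizon, e.g. `"5 years"`.
#' @return an object of class `count_params`.
#' @export
count_outcome_params <- function(mean, sd, dispersion = NULL, horizon = "") {
  derived <- derive_dispersion(mean, sd)  # also validates overdispersion
  if (is.null(dispersion)) {
    dispersion <- derived
  } else if (!is.numeric(dispersion) || dispersion <= 0) {
    abort("qwtsim_type_error", "dispersion must be a positive number")
  }
  structure(
    list(mean = mean, sd = sd, dispersion = dispersion, horizon = horizon),
    class = "count_params"
  )
}

#' Parameters of a binary outcome for one treatment arm
#'
#' @param events non-negative integer numerator (e.g. patients abstinent).
#' @param denominator positive integer group size.
#' @param horizon label for the outcome horizon, e.g. `"28 months"`.
#' @return an object of class `binary_params` with the derived `probability`.
#' @export
binary_outcome_params <- function(events, denominator, horizon = "") {
  p <- probability_from_counts(events, denominator)
  structure(
    list(events = events, denominator = denominator, probability = p,
         horizon = horizon),
    class = "binary_params"
  )
}

#' Assemble the full study parameter set
#'
#' One entry per outcome; each entry holds a QWT (qualified, i.e. extended,
#' withdrawal treatment) and an SWT (somatic withdrawal treatment) arm of the
#' same parameter type.
#'
#' @param ... named outcome entries, each a list `list(qwt = , swt = )` of
#'   two `count_params` or two `binary_params` objects.
#' @return an object of class `parameter_set`.
#' @export
study_parameter_set <- function(...) {
  outcomes <- list(...)
  if (length(outcomes) == 0 || is.null(names(outcomes)) ||
      any(names(outcomes) == "")) {
    abort("qwtsim_config_error", "every outcome must be named")
  }
  for (nm in names(outcomes)) {
    entry <- outcomes[[nm]]
    if (!all(c("qwt", "swt") %in% names(entry))) {
      abort("qwtsim_config_error", "outcome '%s' must have both qwt and swt arms", nm)
    }
    cls_q <- class(entry$qwt)[1]
    cls_s <- class(entry$swt)[1]
    if (!cls_q %in% c("count_params", "binary_params") || cls_q != cls_s) {
      abort("qwtsim_config_error",
            "outcome '%s': arms must both be count_params or both binary_params", nm)
    }
  }
  structure(outcomes, class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Study parameter set:", length(x), "outcomes\n")
  for (nm in names(x)) {
    e <- x[[nm]]
    if (inherits(e$qwt, "count_params")) {
      cat(sprintf(
        "  %s [count, %s]: QWT mean %.1f (SD %.1f, k %.3f); SWT mean %.1f (SD %.1f, k %.3f)\n",
        nm, e$qwt$horizon, e$qwt$mean, e$qwt$sd, e$qwt$dispersion,
        e$swt$mean, e$swt$sd, e$swt$dispersion))
    } else {
      cat(sprintf(
        "  %s [binary, %s]: QWT %.1f%% (%d/%d); SWT %.1f%% (%d/%d)\n",
        nm, e$qwt$horizon, 100 * e$qwt$probability, e$qwt$events,
        e$qwt$denominator, 100 * e$swt$probability, e$swt$events,
        e$swt$denominator))
    }
  }
  invisible(x)
}

#' Split a cohort between the two treatment arms
#'
#' Defines a scenario: a hypothetical split of a fixed cohort between QWT and
#' SWT, holding the total constant. The QWT count is either given explicitly
#' (`qwt_n`, e.g. the observed 170 of 2051) or computed from a share as
#' `round_half_up(total_n * qwt_share)`; SWT takes the remainder. Half-up
#' rounding reproduces the conventional splits 2051 x 0.25 -> 513/1538 and
#' 2051 x 0.50 -> 1026/1025.
#'
#' @param total_n positive integer cohort size.
#' @param qwt_share share of the cohort allocated to QWT, in `[0, 1]`.
#' @param label scenario label, e.g. `"baseline"`, `"qwt25"`.
#' @param qwt_n explicit QWT count; overrides `qwt_share` when given.
#' @return an object of class `scenario_allocation` with fields `label`,
#'   `total_n`, `n_qwt`, `n_swt`.
#' @export
#' @examples
#' allocate_scenario(2051, 0.25, "qwt25")  # 513 QWT / 1538 SWT
#' allocate_scenario(2051, label = "baseline", qwt_n = 170)
allocate_scenario <- function(total_n, qwt_share = NULL, label = "scenario",
                              qwt_n = NULL) {
  if (length(total_n) != 1 || !is.numeric(total_n) || total_n < 1 ||
      total_n != floor(total_n)) {
    abort("qwtsim_allocation_error", "total_n must be a positive integer")
  }
  if (is.null(qwt_n)) {
    if (is.null(qwt_share) || !is.numeric(qwt_share) ||
        qwt_share < 0 || qwt_share > 1) {
      abort("qwtsim_share_error", "qwt_share must lie in [0, 1]")
    }
    qwt_n <- round_half_up(total_n * qwt_share)
  }
  if (qwt_n < 0 || qwt_n > total_n || qwt_n != floor(qwt_n)) {
    abort("qwtsim_allocation_error", "qwt_n must be an integer in [0, total_n]")
  }
  structure(
    list(label = label, total_n = as.integer(total_n),
         n_qwt = as.integer(qwt_n), n_swt = as.integer(total_n - qwt_n)),
    class = "scenario_allocation"
  )
}

#' @export
print.scenario_allocation <- function(x, ...) {
  cat(sprintf("Scenario '%s': N = %d (QWT %d, SWT %d)\n",
              x$label, x$total_n, x$n_qwt, x$n_swt))
  invisible(x)
}
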