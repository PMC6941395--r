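#' Summarise a replicate vector by mean and percentile CI
#'
#' The point estimate is the arithmetic mean of the replicates; the interval
#' is the empirical percentile interval at `(1 - ci_level)/2` and
#' `1 - (1 - ci_level)/2` (quantile type 7, linear interpolation between
#' order statistics).
#'
#' @param samples numeric vector of Monte Carlo replicates (non-empty).
#' @param ci_level confidence level in (0, 1), default 0.95.
#' @return an object of class `summary_stat`: list with `mean`, `ci_low`,
#'   `ci_high`, `ci_level`.
#' @export
summarize_samples <- function(samples, ci_level = 0.95) {
  if (length(samples) == 0) {
    abort("qwtsim_samples_error", "cannot summarise an empty replicate vector")
  }
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1) {
    abort("qwtsim_samples_error", "ci_level must lie strictly in (0, 1)")
  }
  alpha <- (1 - ci_level) / 2
  qs <- stats::quantile(as.numeric(samples), probs = c(alpha, 1 - alpha),
                        names = FALSE, type = 7)
  structure(
    list(mean = mean(samples), ci_low = qs[1], ci_high = qs[2],
         ci_level = ci_level),
    class = "summary_stat"
  )
}

#' @export
print.summary_stat <- function(x, ...) {
  cat(sprintf("%.2f (%.0f%% CI %.2f to %.2f)\n", x$mean, 100 * x$ci_level,
              x$ci_low, x$ci_high))
  invisible(x)
}

#' Convert binary-outcome totals to cohort proportions
#'
#' Divides each replicate total by the full cohort size, so that e.g. the
#' number abstinent becomes the proportion of all patients abstinent.
#'
#' @param samples a [total_samples()] vector of event counts.
#' @param total_n positive integer cohort size.
#' @return a `total_samples` vector of fractions, order preserved.
#' @export
to_proportion <- function(samples, total_n) {
  if (length(total_n) != 1 || !is.numeric(total_n) || total_n < 1) {
    abort("qwtsim_samples_error", "total_n must be a positive integer")
  }
  total_samples(as.numeric(samples) / total_n,
                scenario = attr(samples, "scenario") %||% "",
                outcome = attr(samples, "outcome") %||% "")
}

#' Paired comparison of a scenario against baseline
#'
#' Replicate i of the scenario is paired with replicate i of baseline.
#' The absolute difference is `d_i = scenario_i - baseline_i` (outcome
#' units); the relative difference is `r_i = 100 * d_i / baseline_i` (% of
#' baseline). Replicates with a zero baseline are excluded from the relative
#' summary and counted in `n_zero_baseline`. Both difference vectors are
#' summarised with [summarize_samples()].
#'
#' @param baseline,scenario replicate vectors of equal length for the same
#'   outcome.
#' @param ci_level confidence level for the percentile intervals.
#' @return an object of class `comparison_stat`: list with `absolute` and
#'   `relative` (`summary_stat`s) and `n_zero_baseline`.
#' @export
compare_paired <- function(baseline, scenario, ci_level = 0.95) {
  if (length(baseline) != length(scenario)) {
    abort("qwtsim_alignment_error",
          "baseline (%d) and scenario (%d) replicate vectors differ in length",
          length(baseline), length(scenario))
  }
  b <- as.numeric(baseline)
  s <- as.numeric(scenario)
  d <- s - b
  nz <- b != 0
  rel <- 100 * d[nz] / b[nz]
  if (!any(nz)) {
    abort("qwtsim_samples_error",
          "all baseline replicates are zero; relative change undefined")
  }
  structure(
    list(absolute = summarize_samples(d, ci_level),
         relative = summarize_samples(rel, ci_level),
         n_zero_baseline = sum(!nz)),
    class = "comparison_stat"
  )
}

#' @export
print.comparison_stat <- function(x, ...) {
  cat(sprintf("absolute: %+.1f (%.1f to %.1f); relative: %+.1f%% (%.1f to %.1f%%)",
              x$absolute$mean, x$absolute$ci_low, x$absolute$ci_high,
              x$relative$mean, x$relative$ci_low, x$relative$ci_high))
  if (x$n_zero_baseline > 0) {
    cat(sprintf("  [%d zero-baseline replicates excluded from relative]",
                x$n_zero_baseline))
  }
  cat("\n")
  invisible(x)
}

#' Assemble the per-outcome, per-scenario results table
#'
#' One row per outcome x scenario. Count outcomes are summarised as cohort
#' totals; binary outcomes as proportions of the full cohort (`mean`,
#' `ci_low`, `ci_high` are then fractions of `total_n`). Scenario-versus-
#' baseline comparisons (absolute difference in outcome units — for binary
#' outcomes, in patients — and relative difference in % of baseline) are
#' paired by replicate index and reported for every non-baseline scenario.
#'
#' @param sim a `simulation_result` from [run_simulation()].
#' @param total_n positive integer cohort size (proportion denominator).
#' @param ci_level confidence level, default 0.95.
#' @param baseline label of the baseline scenario; defaults to the scenario
#'   flagged baseline in `sim$scenarios`, else the first scenario.
#' @return a `data.frame` of class `qwtsim_results` with columns `outcome`,
#'   `scenario`, `type`, `n_qwt`, `n_swt`, `scale`, `mean`, `ci_low`,
#'   `ci_high`, `abs_diff`, `abs_ci_low`, `abs_ci_high`, `rel_diff_pct`,
#'   `rel_ci_low_pct`, `rel_ci_high_pct` (comparison columns `NA` for the
#'   baseline rows).
#' @export
build_results_table <- function(sim, total_n, ci_level = 0.95,
                                baseline = NULL) {
  if (is.null(baseline)) {
    flagged <- names(sim$scenarios)[vapply(
      sim$scenarios, function(a) isTRUE(attr(a, "baseline")), logical(1))]
    baseline <- if (length(flagged) == 1) flagged else names(sim$samples)[1]
  }
  if (!baseline %in% names(sim$samples)) {
    abort("qwtsim_config_error", "baseline scenario '%s' not in simulation",
          baseline)
  }
  rows <- list()
  for (nm in names(sim$samples[[baseline]])) {
    base_raw <- sim$samples[[baseline]][[nm]]
    is_binary <- identical(sim$outcome_types[[nm]], "binary")
    for (sc in names(sim$samples)) {
      raw <- sim$samples[[sc]][[nm]]
      summ <- if (is_binary) {
        summarize_samples(to_proportion(raw, total_n), ci_level)
      } else {
        summarize_samples(raw, ci_level)
      }
      cmp <- if (sc != baseline) compare_paired(base_raw, raw, ci_level) else NULL
      alloc <- sim$scenarios[[sc]]
      rows[[length(rows) + 1]] <- data.frame(
        outcome = nm, scenario = sc,
        type = if (is_binary) "binary" else "count",
        n_qwt = alloc$n_qwt, n_swt = alloc$n_swt,
        scale = if (is_binary) "proportion_of_cohort" else "total",
        mean = summ$mean, ci_low = summ$ci_low, ci_high = summ$ci_high,
        abs_diff = if (is.null(cmp)) NA_real_ else cmp$absolute$mean,
        abs_ci_low = if (is.null(cmp)) NA_real_ else cmp$absolute$ci_low,
        abs_ci_high = if (is.null(cmp)) NA_real_ else cmp$absolute$ci_high,
        rel_diff_pct = if (is.null(cmp)) NA_real_ else cmp$relative$mean,
        rel_ci_low_pct = if (is.null(cmp)) NA_real_ else cmp$relative$ci_low,
        rel_ci_high_pct = if (is.null(cmp)) NA_real_ else cmp$relative$ci_high
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "baseline") <- baseline
  attr(out, "total_n") <- total_n
  attr(out, "ci_level") <- ci_level
  class(out) <- c("qwtsim_results", "data.frame")
  out
}

#' Proportional-change table
#'
#' Extracts the relative scenario-versus-baseline changes (the numbers one
#' would plot as a bar chart of proportional change per outcome).
#'
#' @param results a `qwtsim_results` table from [build_results_table()].
#' @return a `data.frame` with columns `outcome`, `scenario`,
#'   `rel_diff_pct`, `rel_ci_low_pct`, `rel_ci_high_pct`.
#' @export
proportional_change_table <- function(results) {
  keep <- !is.na(results$rel_diff_pct)
  out <- results[keep, c("outcome", "scenario", "rel_diff_pct",
                         "rel_ci_low_pct", "rel_ci_high_pct")]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Format the results table for reading
#'
#' Human-readable aligned text: count totals rounded to integers, binary
#' proportions as integer percentages, relative changes as integer
#' percentages, all with half-up rounding; percentile intervals in brackets.
#'
#' @param results a `qwtsim_results` table.
#' @return a character vector of lines, invisibly printed by
#'   `print.qwtsim_results`.
#' @export
format_results_table <- function(results) {
  fmt_est <- function(r) {
    if (r$scale == "proportion_of_cohort") {
      sprintf("%d%% (%d to %d%%)", round_half_up(100 * r$mean),
              round_half_up(100 * r$ci_low), round_half_up(100 * r$ci_high))
    } else {
      sprintf("%s (%s to %s)",
              format(round_half_up(r$mean), big.mark = ","),
              format(round_half_up(r$ci_low), big.mark = ","),
              format(round_half_up(r$ci_high), big.mark = ","))
    }
  }
  fmt_cmp <- function(r) {
    if (is.na(r$rel_diff_pct)) return("")
    sprintf("%+d%% (%d to %d%%)", round_half_up(r$rel_diff_pct),
            round_half_up(r$rel_ci_low_pct), round_half_up(r$rel_ci_high_pct))
  }
  lines <- character(0)
  for (nm in unique(results$outcome)) {
    lines <- c(lines, sprintf("%s:", nm))
    sub <- results[results$outcome == nm, ]
    for (i in seq_len(nrow(sub))) {
      r <- sub[i, ]
      cmp <- fmt_cmp(r)
      lines <- c(lines, sprintf(
        "  %-10s (QWT %4d / SWT %4d): %-28s %s",
        r$scenario, r$n_qwt, r$n_swt, fmt_est(r),
        if (nzchar(cmp)) paste("vs baseline:", cmp) else ""))
    }
  }
  lines
}

#' @export
print.qwtsim_results <- function(x, ...) {
  cat(format_results_table(x), sep = "\n")
  invisible(x)
}

#' Closed-form expected cohort total
#'
#' The analytic expectation `n_qwt * mu_QWT + n_swt * mu_SWT` (count
#' outcomes) or `n_qwt * p_QWT + n_swt * p_SWT` (binary outcomes), against
#' which simulated means converge. Useful as an independent no-sampling
#' check of simulation output.
#'
#' @param allocation a [allocate_scenario()] object.
#' @param entry one outcome entry of a [study_parameter_set()] (list with
#'   `qwt` and `swt` arm parameters).
#' @return the expected cohort total, a single number.
#' @export
expected_total <- function(allocation, entry) {
  per_patient <- function(p) {
    if (inherits(p, "count_params")) p$mean else p$probability
  }
  allocation$n_qwt * per_patient(entry$qwt) +
    allocation$n_swt * per_patient(entry$swt)
}
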