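#' Write a run manifest
#'
#' Every output directory gets a `manifest.json` recording what produced
#' it: an MD5 digest of the resolved configuration, the master seed,
#' replicate count, CI level, package version and a timestamp. Re-running
#' with the same config, seed and replicates reproduces the outputs
#' exactly; the manifest makes a run self-describing.
#'
#' @param output_dir directory the manifest accompanies.
#' @param config the resolved configuration list (digested via YAML dump).
#' @param seed,replicates,ci_level the effective simulation settings.
#' @param extra optional named list of additional fields.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(output_dir, config, seed, replicates,
                           ci_level = 0.95, extra = list()) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  manifest <- c(list(
    config_digest = unname(tools::md5sum(tmp)),
    master_seed = seed,
    replicates = replicates,
    ci_level = ci_level,
    package_version = as.character(utils::packageVersion("qwtsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

resolve_config <- function(config_path, replicates = NULL, seed = NULL) {
  config <- load_config(config_path)
  if (!is.null(replicates)) config$simulation$replicates <- replicates
  if (!is.null(seed)) config$simulation$seed <- seed
  config$simulation$replicates <- config$simulation$replicates %||% 10000
  config$simulation$seed <- config$simulation$seed %||% 1
  config$simulation$ci_level <- config$simulation$ci_level %||% 0.95
  config
}

#' Validate a configuration and print the derived parameters
#'
#' Validation-only pass: builds the parameter set (reporting derived
#' dispersions) and the scenario allocations without simulating. Errors
#' carry the offending config entry path.
#'
#' @param config_path path to the YAML config.
#' @return the parameter set, invisibly.
#' @export
cmd_check <- function(config_path = default_config_path()) {
  config <- resolve_config(config_path)
  params <- build_parameter_set(config)
  scenarios <- build_scenarios(config)
  message("config OK: ", config_path)
  print(params)
  for (nm in names(params)) {
    e <- params[[nm]]
    if (inherits(e$qwt, "count_params")) {
      cat(sprintf("  derived dispersion %s: QWT %.3f, SWT %.3f\n", nm,
                  derive_dispersion(e$qwt$mean, e$qwt$sd),
                  derive_dispersion(e$swt$mean, e$swt$sd)))
    }
  }
  for (a in scenarios) print(a)
  invisible(params)
}

#' Run the full pipeline and write result files
#'
#' Loads and validates the config, runs the Monte Carlo simulation, and
#' writes to `output_dir`: `results.csv` (full precision, one row per
#' outcome x scenario), `results.txt` (formatted, rounded like a published
#' summary table), `proportional_change.csv` (relative-change values per
#' outcome and non-baseline scenario) and `manifest.json`. The run is
#' deterministic given the config and seed; identical invocations write
#' byte-identical CSVs.
#'
#' @param config_path path to the YAML config.
#' @param replicates optional override of `simulation.replicates`.
#' @param seed optional override of `simulation.seed`.
#' @param output_dir output directory, created if needed.
#' @return the results table, invisibly.
#' @export
cmd_simulate <- function(config_path = default_config_path(),
                         replicates = NULL, seed = NULL,
                         output_dir = ".") {
  config <- resolve_config(config_path, replicates, seed)
  params <- build_parameter_set(config)
  scenarios <- build_scenarios(config)
  simset <- config$simulation
  message(sprintf("simulating %d scenarios x %d outcomes, %d replicates, seed %d",
                  length(scenarios), length(params),
                  simset$replicates, simset$seed))
  message("dispersion source: ", config$dispersion_source %||% "derived",
          "; SWT mortality denominator: ",
          config$outcomes$death$swt$denominator %||% NA)
  sim <- run_simulation(params, scenarios, simset$replicates, simset$seed)
  results <- build_results_table(sim, req(config, c("cohort", "total_n")),
                                 simset$ci_level)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  utils::write.csv(as.data.frame(results),
                   file.path(output_dir, "results.csv"), row.names = FALSE)
  writeLines(format_results_table(results),
             file.path(output_dir, "results.txt"))
  utils::write.csv(proportional_change_table(results),
                   file.path(output_dir, "proportional_change.csv"),
                   row.names = FALSE)
  write_manifest(output_dir, config, simset$seed, simset$replicates,
                 simset$ci_level)
  message("results written to ", output_dir)
  invisible(results)
}

#' Generate and write a synthetic register and outcome table
#'
#' Writes `register.csv`, `patient_outcomes.csv` and `manifest.json` to
#' `output_dir`. Outcome parameters come from the bundled default config
#' unless another is supplied.
#'
#' @param total_n register size.
#' @param qwt_share share of patients receiving QWT.
#' @param seed integer seed.
#' @param output_dir output directory, created if needed.
#' @param config_path config supplying outcome parameters and register
#'   composition.
#' @return invisible list with the register and outcomes tables.
#' @export
cmd_synth <- function(total_n = 2051, qwt_share = 170 / 2051, seed = 1,
                      output_dir = ".",
                      config_path = default_config_path()) {
  config <- resolve_config(config_path)
  params <- build_parameter_set(config)
  mix <- unlist(config$register$diagnosis_mix %||%
                  list("F10.3" = 0.535, "F10.2" = 0.386,
                       "F10.0" = 0.055, "F10.1" = 0.023))
  reg <- generate_admissions_register(
    total_n, qwt_share, diagnosis_mix = mix,
    female_share = config$register$female_share %||% 0.262,
    seed = stream_seed(seed, "register"),
    years = unlist(config$register$years %||% list(2016L, 2017L)))
  alloc <- register_to_allocation(reg)
  outcomes <- generate_patient_outcomes(alloc, params,
                                        seed = stream_seed(seed, "outcomes"))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  write_register(reg, file.path(output_dir, "register.csv"))
  write_outcomes(outcomes, file.path(output_dir, "patient_outcomes.csv"))
  write_manifest(output_dir, config, seed, replicates = NA,
                 extra = list(total_n = total_n, qwt_share = qwt_share,
                              command = "synth"))
  message(sprintf("synthetic register (%d rows, %d QWT) written to %s",
                  nrow(reg), alloc$n_qwt, output_dir))
  invisible(list(register = reg, outcomes = outcomes, allocation = alloc))
}

#' Bar chart of proportional changes versus baseline
#'
#' Plots the relative scenario-versus-baseline change per outcome with its
#' percentile interval as error bars. Requires ggplot2.
#'
#' @param results a `qwtsim_results` table.
#' @return a ggplot object.
#' @export
plot_proportional_change <- function(results) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("qwtsim_config_error", "ggplot2 is required for plotting")
  }
  pc <- proportional_change_table(results)
  pc$outcome <- factor(pc$outcome, levels = unique(pc$outcome))
  ggplot2::ggplot(pc, ggplot2::aes(x = .data[["outcome"]],
                                   y = .data[["rel_diff_pct"]],
                                   fill = .data[["scenario"]])) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data[["rel_ci_low_pct"]],
                   ymax = .data[["rel_ci_high_pct"]]),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::labs(x = NULL, y = "change vs baseline (%)", fill = "scenario") +
    ggplot2::theme_minimal()
}
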