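#' Path to the bundled default configuration
#'
#' The default config encodes the published per-arm outcome parameters
#' (per-patient means/SDs for hospitalisation counts and days, event
#' fractions for abstinence and mortality), the three allocation scenarios
#' (observed baseline 170/1881, 25% QWT, 50% QWT over N = 2051) and the
#' simulation settings (10,000 replicates, 95% CI).
#'
#' @return path to the installed YAML file.
#' @export
default_config_path <- function() {
  system.file("extdata", "bremen.yaml", package = "qwtsim", mustWork = TRUE)
}

#' Load a configuration file
#'
#' @param path path to a YAML config; defaults to the bundled one.
#' @return the parsed configuration list.
#' @export
load_config <- function(path = default_config_path()) {
  if (!file.exists(path)) {
    abort("qwtsim_config_error", "config file not found: %s", path)
  }
  yaml::read_yaml(path)
}

req <- function(config, path_chr) {
  node <- config
  for (k in path_chr) {
    if (is.null(node[[k]])) {
      abort("qwtsim_config_error", "missing config entry: %s",
            paste(path_chr, collapse = "."))
    }
    node <- node[[k]]
  }
  node
}

num_field <- function(entry, field, where) {
  v <- entry[[field]]
  if (is.null(v)) {
    abort("qwtsim_config_error", "%s: missing field '%s'", where, field)
  }
  if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
    abort("qwtsim_config_error", "%s.%s: must be a single finite number", where, field)
  }
  v
}

#' Build a validated parameter set from a configuration
#'
#' Materialises the per-outcome, per-arm parameters from a parsed config.
#' Count-arm dispersions are taken from the config when
#' `dispersion_source: config`, or derived from the mean/SD moments when
#' `dispersion_source: derived` (the default). Validation errors name the
#' offending entry (`outcomes.<name>.<arm>`).
#'
#' @param config a parsed config list, as from [load_config()].
#' @return a [study_parameter_set()] object.
#' @export
build_parameter_set <- function(config) {
  outs <- req(config, "outcomes")
  src <- config$dispersion_source %||% "derived"
  if (!src %in% c("derived", "config")) {
    abort("qwtsim_config_error",
          "dispersion_source must be 'derived' or 'config', got '%s'", src)
  }
  built <- list()
  for (nm in names(outs)) {
    o <- outs[[nm]]
    type <- o$type %||% abort("qwtsim_config_error", "outcomes.%s: missing type", nm)
    horizon <- o$horizon %||% ""
    arms <- list()
    for (arm in c("qwt", "swt")) {
      where <- sprintf("outcomes.%s.%s", nm, arm)
      entry <- o[[arm]]
      if (is.null(entry)) abort("qwtsim_config_error", "%s: missing arm", where)
      arms[[arm]] <- withCallingHandlers(
        if (type == "count") {
          disp <- if (src == "config") {
            num_field(entry, "dispersion", where)
          } else NULL
          count_outcome_params(num_field(entry, "mean", where),
                               num_field(entry, "sd", where),
                               dispersion = disp, horizon = horizon)
        } else if (type == "binary") {
          binary_outcome_params(num_field(entry, "events", where),
                                num_field(entry, "denominator", where),
                                horizon = horizon)
        } else {
          abort("qwtsim_config_error",
                "outcomes.%s: type must be 'count' or 'binary', got '%s'", nm, type)
        },
        qwtsim_error = function(e) {
          if (!inherits(e, "qwtsim_config_error")) {
            abort(class(e)[1], "%s: %s", where, conditionMessage(e))
          }
        }
      )
    }
    built[[nm]] <- list(qwt = arms$qwt, swt = arms$swt)
  }
  do.call(study_parameter_set, built)
}

#' Build scenario allocations from a configuration
#'
#' @param config a parsed config list with `cohort.total_n` and a
#'   `scenarios` list of `{label, qwt_share | qwt_n, [baseline]}` entries.
#' @return a named list of [allocate_scenario()] objects; the baseline
#'   scenario carries attribute `baseline = TRUE`.
#' @export
build_scenarios <- function(config) {
  total_n <- req(config, c("cohort", "total_n"))
  raw <- req(config, "scenarios")
  allocs <- list()
  for (sc in raw) {
    label <- sc$label %||% abort("qwtsim_config_error", "scenarios: missing label")
    a <- allocate_scenario(total_n, qwt_share = sc$qwt_share,
                           label = label, qwt_n = sc$qwt_n)
    attr(a, "baseline") <- isTRUE(sc$baseline)
    allocs[[label]] <- a
  }
  if (sum(vapply(allocs, function(a) isTRUE(attr(a, "baseline")), logical(1))) > 1) {
    abort("qwtsim_config_error", "at most one scenario may be flagged baseline")
  }
  allocs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
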