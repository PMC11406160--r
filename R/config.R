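# Scenario configuration: what to run (synthetic community or trait-table
# paths), the temperature-size rule, the temperature grid, and the
# robustness settings. YAML and JSON are both accepted.

#' Parse a "start:stop:step" temperature grid specification
#'
#' Endpoints are inclusive within a floating tolerance of 1e-9, so
#' `"20:30:0.5"` yields 21 points even when the step does not divide the
#' range exactly in binary.
#'
#' @param spec A string `"start:stop:step"` (step optional, default 1), or
#'   a numeric vector returned unchanged.
#' @return An ascending numeric vector of temperatures (degrees C).
#' @examples
#' parse_t_grid("20:30:0.5")
#' @export
parse_t_grid <- function(spec) {
  if (is.numeric(spec)) return(spec)
  parts <- suppressWarnings(as.numeric(strsplit(spec, ":", fixed = TRUE)[[1]]))
  if (length(parts) < 2 || length(parts) > 3 || any(is.na(parts))) {
    abort_usage(sprintf(
      "cannot parse t_grid spec '%s'; expected 'start:stop:step'", spec
    ))
  }
  start <- parts[1]
  stop_ <- parts[2]
  step <- if (length(parts) == 3) parts[3] else 1
  if (step <= 0 || stop_ < start) {
    abort_usage("t_grid spec needs stop >= start and step > 0")
  }
  n <- floor((stop_ - start) / step + 1e-9)
  start + step * (0:n)
}

#' Assemble a full scenario configuration
#'
#' Exactly one community source must be given: either a
#' [synthetic_config()] or a pair of trait-table paths.
#'
#' @param synthetic A [synthetic_config()], or `NULL` when loading tables.
#' @param consumer_table,resource_table Paths to CSV/TSV trait tables, or
#'   `NULL` when generating synthetically.
#' @param rule A [temp_size_rule()]; defaults to the synthetic config's
#'   `alpha`/`reference_temperature` when available.
#' @param thermal Optional [thermal_performance_model()] recorded with the
#'   scenario.
#' @param t_grid Temperature grid (numeric or `"start:stop:step"`).
#' @param robustness_strategy,robustness_replicates,robustness_seed
#'   Settings for the per-layer robustness analysis.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(synthetic = synthetic_config(),
                            consumer_table = NULL,
                            resource_table = NULL,
                            rule = NULL,
                            thermal = NULL,
                            t_grid = "20:30:0.5",
                            robustness_strategy = "random",
                            robustness_replicates = 100,
                            robustness_seed = 1L) {
  from_tables <- !is.null(consumer_table) || !is.null(resource_table)
  if (from_tables && !is.null(synthetic)) {
    abort_usage("supply either `synthetic` or table paths, not both")
  }
  if (!from_tables && is.null(synthetic)) {
    abort_usage("supply one community source: `synthetic` or table paths")
  }
  if (from_tables && (is.null(consumer_table) || is.null(resource_table))) {
    abort_usage("both consumer_table and resource_table paths are required")
  }
  if (is.null(rule)) {
    rule <- if (!is.null(synthetic)) {
      temp_size_rule(synthetic$alpha, synthetic$reference_temperature)
    } else {
      temp_size_rule(0.9, 20)
    }
  }
  stopifnot(inherits(rule, "temp_size_rule"))
  if (!is.null(thermal)) stopifnot(inherits(thermal, "thermal_performance_model"))
  structure(
    list(
      synthetic = synthetic,
      consumer_table = consumer_table,
      resource_table = resource_table,
      rule = rule,
      thermal = thermal,
      t_grid = parse_t_grid(t_grid),
      robustness_strategy = robustness_strategy,
      robustness_replicates = robustness_replicates,
      robustness_seed = as.integer(robustness_seed)
    ),
    class = "scenario_config"
  )
}

#' Read a scenario configuration from YAML or JSON
#'
#' The file mirrors the arguments of [scenario_config()]: top-level keys
#' `synthetic` (a mapping of [synthetic_config()] fields) or
#' `consumer_table`/`resource_table`, plus optional `rule`
#' (`alpha`, `reference_temperature`), `thermal` (`q10`,
#' `reference_temperature`, `plateau_temperature`), `t_grid`, and
#' `robustness` (`strategy`, `n_replicates`, `seed`).
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  scenario_config_from_list(raw)
}

scenario_config_from_list <- function(raw) {
  synthetic <- if (!is.null(raw$synthetic)) {
    do.call(synthetic_config, raw$synthetic)
  } else {
    NULL
  }
  rule <- if (!is.null(raw$rule)) do.call(temp_size_rule, raw$rule) else NULL
  thermal <- if (!is.null(raw$thermal)) {
    do.call(thermal_performance_model, raw$thermal)
  } else {
    NULL
  }
  rb <- raw$robustness %||% list()
  scenario_config(
    synthetic = synthetic,
    consumer_table = raw$consumer_table,
    resource_table = raw$resource_table,
    rule = rule,
    thermal = thermal,
    t_grid = raw$t_grid %||% "20:30:0.5",
    robustness_strategy = rb$strategy %||% "random",
    robustness_replicates = rb$n_replicates %||% 100,
    robustness_seed = rb$seed %||% 1L
  )
}

# Plain-list form for manifests (round-trips via scenario_config_from_list).
scenario_config_to_list <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  out <- list(
    rule = list(alpha = config$rule$alpha,
                reference_temperature = config$rule$reference_temperature),
    t_grid = config$t_grid,
    robustness = list(
      strategy = config$robustness_strategy,
      n_replicates = config$robustness_replicates,
      seed = config$robustness_seed
    )
  )
  if (!is.null(config$synthetic)) {
    out$synthetic <- unclass(config$synthetic)
  } else {
    out$consumer_table <- config$consumer_table
    out$resource_table <- config$resource_table
  }
  if (!is.null(config$thermal)) out$thermal <- unclass(config$thermal)
  out
}

#' Write a scenario configuration to YAML or JSON
#'
#' @param config A `scenario_config`.
#' @param path Destination `.yaml`/`.yml` or `.json` path.
#' @return Invisibly, `path`.
#' @export
write_scenario_config <- function(config, path) {
  lst <- scenario_config_to_list(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(lst, path, precision = 15)
  }
  invisible(path)
}

# Load or generate the community a scenario describes.
resolve_community <- function(config) {
  if (!is.null(config$synthetic)) {
    comm <- generate_community(config$synthetic)
    list(consumers = comm$consumers, resources = comm$resources)
  } else {
    list(
      consumers = read_consumers(config$consumer_table),
      resources = read_resources(config$resource_table)
    )
  }
}
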