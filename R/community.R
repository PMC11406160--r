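# Consumer/resource trait tables and the synthetic community generator.
#
# Consumers are bite-force-bearing colonies (id, reference mass, allometry);
# resources are plants characterised by the force needed to cut their
# tissue. Both are plain tibbles so the whole pipeline stays pipeable.

#' Build a validated consumer trait table
#'
#' @param id Character vector of consumer (colony) labels; must be unique.
#' @param reference_mass_mg Body mass (mg) at the reference temperature;
#'   positive.
#' @param allometry An [allometric_model()] shared by all consumers, or
#'   `NULL` if `prefactor`/`exponent` are given per row.
#' @param prefactor,exponent Optional per-consumer allometric parameters;
#'   recycled if length 1. Ignored when `allometry` is supplied.
#' @return A tibble with columns `id`, `reference_mass_mg`, `prefactor`,
#'   `exponent`, `baseline_bite_force_mn` (the allometry evaluated at the
#'   reference mass).
#' @export
consumer_table <- function(id, reference_mass_mg, allometry = NULL,
                           prefactor = NULL, exponent = NULL) {
  if (!is.null(allometry)) {
    stopifnot(inherits(allometry, "allometric_model"))
    prefactor <- allometry$prefactor
    exponent <- allometry$exponent
  }
  if (is.null(prefactor) || is.null(exponent)) {
    abort_usage("supply either `allometry` or both `prefactor` and `exponent`")
  }
  out <- tibble::tibble(
    id = as.character(id),
    reference_mass_mg = reference_mass_mg,
    prefactor = prefactor,
    exponent = exponent
  )
  out$baseline_bite_force_mn <- out$prefactor * out$reference_mass_mg^out$exponent
  validate_consumers(out)
}

#' Build a validated resource trait table
#'
#' @param id Character vector of resource (plant) labels; must be unique.
#' @param cutting_force_mn Force (mN) required to cut the resource tissue;
#'   positive.
#' @param abundance Optional relative abundance, non-negative. Carried
#'   through for weighted summaries; never gates edge existence.
#' @return A tibble with columns `id`, `cutting_force_mn` and, if supplied,
#'   `abundance`.
#' @export
resource_table <- function(id, cutting_force_mn, abundance = NULL) {
  out <- tibble::tibble(
    id = as.character(id),
    cutting_force_mn = cutting_force_mn
  )
  if (!is.null(abundance)) out$abundance <- abundance
  validate_resources(out)
}

validate_consumers <- function(consumers) {
  required <- c("id", "reference_mass_mg", "prefactor", "exponent")
  missing_cols <- setdiff(required, names(consumers))
  if (length(missing_cols) > 0) {
    abort_schema(sprintf(
      "consumer table is missing column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyDuplicated(consumers$id)) {
    abort_validation("consumer ids must be unique")
  }
  validate_rows_positive(consumers, c("reference_mass_mg", "prefactor"), "consumer")
  if (any(!is.finite(consumers$exponent))) {
    bad <- which(!is.finite(consumers$exponent))
    abort_validation(sprintf(
      "consumer table: non-finite exponent in row(s) %s",
      paste(bad, collapse = ", ")
    ))
  }
  out <- tibble::as_tibble(consumers)
  out$id <- as.character(out$id)
  if (!"baseline_bite_force_mn" %in% names(out)) {
    out$baseline_bite_force_mn <-
      out$prefactor * out$reference_mass_mg^out$exponent
  }
  out
}

validate_resources <- function(resources) {
  required <- c("id", "cutting_force_mn")
  missing_cols <- setdiff(required, names(resources))
  if (length(missing_cols) > 0) {
    abort_schema(sprintf(
      "resource table is missing column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyDuplicated(resources$id)) {
    abort_validation("resource ids must be unique")
  }
  validate_rows_positive(resources, "cutting_force_mn", "resource")
  if ("abundance" %in% names(resources)) {
    bad <- which(!is.finite(resources$abundance) | resources$abundance < 0)
    if (length(bad) > 0) {
      abort_validation(sprintf(
        "resource table: negative or non-finite abundance in row(s) %s",
        paste(bad, collapse = ", ")
      ))
    }
  }
  out <- tibble::as_tibble(resources)
  out$id <- as.character(out$id)
  out
}

# Row-level positivity check with row indices in the message.
validate_rows_positive <- function(tbl, cols, what) {
  for (col in cols) {
    x <- tbl[[col]]
    if (!is.numeric(x)) {
      abort_validation(sprintf("%s table: column %s must be numeric", what, col))
    }
    bad <- which(!is.finite(x) | x <= 0)
    if (length(bad) > 0) {
      abort_validation(sprintf(
        "%s table: non-positive or non-finite %s in row(s) %s",
        what, col, paste(utils::head(bad, 10), collapse = ", ")
      ))
    }
  }
  invisible(tbl)
}

#' Configuration for the synthetic community generator
#'
#' Defaults describe a small leaf-cutter-ant-style study system: three
#' colonies of one species whose body masses vary log-normally around
#' 30 mg, a shared area-like bite-force allometry (10 * mass^(2/3) mN), a
#' plant community whose required cutting forces are log-normal around
#' 90 mN (right-skewed, spanning the colonies' force range so the baseline
#' network has intermediate connectance), and a 10% body-mass shrink per
#' degree of warming (`alpha = 0.9`). All defaults are synthetic stand-ins,
#' not measurements.
#'
#' @param n_consumers,n_resources Community sizes (counts >= 1).
#' @param consumer_mass_median Median body mass (mg) of consumers.
#' @param consumer_mass_sigma Log-scale standard deviation of masses (>= 0).
#' @param allometry_prefactor,allometry_exponent Shared bite-force
#'   allometry, as in [allometric_model()].
#' @param cutting_force_median Median required cutting force (mN) of
#'   resources.
#' @param cutting_force_sigma Log-scale standard deviation of cutting
#'   forces (>= 0).
#' @param alpha Per-degree-Celsius multiplicative body-size factor.
#' @param reference_temperature Temperature (degrees C) at which reference
#'   masses are defined.
#' @param seed Integer RNG seed; identical seed + config reproduce the
#'   community exactly.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_consumers = 3,
                             n_resources = 50,
                             consumer_mass_median = 30,
                             consumer_mass_sigma = 0.4,
                             allometry_prefactor = 10,
                             allometry_exponent = 2 / 3,
                             cutting_force_median = 90,
                             cutting_force_sigma = 0.6,
                             alpha = 0.9,
                             reference_temperature = 20,
                             seed = 1L) {
  cfg <- list(
    n_consumers = n_consumers, n_resources = n_resources,
    consumer_mass_median = consumer_mass_median,
    consumer_mass_sigma = consumer_mass_sigma,
    allometry_prefactor = allometry_prefactor,
    allometry_exponent = allometry_exponent,
    cutting_force_median = cutting_force_median,
    cutting_force_sigma = cutting_force_sigma,
    alpha = alpha,
    reference_temperature = reference_temperature,
    seed = as.integer(seed)
  )
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is_scalar_number(cfg$n_consumers) && cfg$n_consumers >= 1,
      "n_consumers must be a count >= 1")
  chk(is_scalar_number(cfg$n_resources) && cfg$n_resources >= 1,
      "n_resources must be a count >= 1")
  chk(is_scalar_number(cfg$consumer_mass_median) && cfg$consumer_mass_median > 0,
      "consumer_mass_median must be > 0")
  chk(is_scalar_number(cfg$consumer_mass_sigma) && cfg$consumer_mass_sigma >= 0,
      "consumer_mass_sigma must be >= 0")
  chk(is_scalar_number(cfg$allometry_prefactor) && cfg$allometry_prefactor > 0,
      "allometry_prefactor must be > 0")
  chk(is_scalar_number(cfg$allometry_exponent),
      "allometry_exponent must be a finite number")
  chk(is_scalar_number(cfg$cutting_force_median) && cfg$cutting_force_median > 0,
      "cutting_force_median must be > 0")
  chk(is_scalar_number(cfg$cutting_force_sigma) && cfg$cutting_force_sigma >= 0,
      "cutting_force_sigma must be >= 0")
  chk(is_scalar_number(cfg$alpha) && cfg$alpha > 0, "alpha must be > 0")
  chk(is_scalar_number(cfg$reference_temperature),
      "reference_temperature must be a finite number")
  chk(length(cfg$seed) == 1 && !is.na(cfg$seed), "seed must be a single integer")
  if (length(problems) > 0) {
    abort_validation(paste0(
      "invalid synthetic_config:\n",
      paste0("  - ", problems, collapse = "\n")
    ))
  }
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<synthetic_config> %d consumers (mass ~ lognormal(median %g mg, sigma %g)),\n",
      "  %d resources (cutting force ~ lognormal(median %g mN, sigma %g)),\n",
      "  allometry %g * m^%g, alpha %g per degree C (ref %g degrees C), seed %d\n"
    ),
    x$n_consumers, x$consumer_mass_median, x$consumer_mass_sigma,
    x$n_resources, x$cutting_force_median, x$cutting_force_sigma,
    x$allometry_prefactor, x$allometry_exponent,
    x$alpha, x$reference_temperature, x$seed
  ))
  invisible(x)
}

#' Generate a synthetic consumer-resource community
#'
#' Draws consumer body masses and resource cutting forces from log-normal
#' distributions with the configured medians and log-scale sigmas, and
#' attaches the shared bite-force allometry to each consumer. With
#' `sigma = 0` every draw collapses to the median. Deterministic for a
#' fixed `seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `community` with elements `consumers` and
#'   `resources` (validated tibbles) and `config`.
#' @examples
#' comm <- generate_community(synthetic_config(seed = 42))
#' comm$consumers
#' @export
generate_community <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  widths <- list(
    consumer = max(1, nchar(as.character(config$n_consumers))),
    resource = max(1, nchar(as.character(config$n_resources)))
  )
  withr::with_seed(config$seed, {
    masses <- stats::rlnorm(
      config$n_consumers,
      meanlog = log(config$consumer_mass_median),
      sdlog = config$consumer_mass_sigma
    )
    cuts <- stats::rlnorm(
      config$n_resources,
      meanlog = log(config$cutting_force_median),
      sdlog = config$cutting_force_sigma
    )
  })
  consumers <- consumer_table(
    id = sprintf(paste0("colony_%0", widths$consumer, "d"),
                 seq_len(config$n_consumers)),
    reference_mass_mg = masses,
    allometry = allometric_model(config$allometry_prefactor,
                                 config$allometry_exponent)
  )
  resources <- resource_table(
    id = sprintf(paste0("plant_%0", widths$resource, "d"),
                 seq_len(config$n_resources)),
    cutting_force_mn = cuts
  )
  structure(
    list(consumers = consumers, resources = resources, config = config),
    class = "community"
  )
}

#' @export
print.community <- function(x, ...) {
  cat(sprintf(
    "<community> %d consumers, %d resources\n",
    nrow(x$consumers), nrow(x$resources)
  ))
  cat(sprintf(
    "  consumer baseline bite force: %.3g-%.3g mN; resource cutting force: %.3g-%.3g mN\n",
    min(x$consumers$baseline_bite_force_mn),
    max(x$consumers$baseline_bite_force_mn),
    min(x$resources$cutting_force_mn),
    max(x$resources$cutting_force_mn)
  ))
  invisible(x)
}

guess_delim <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a consumer trait table from CSV/TSV
#'
#' Requires columns `id` and `reference_mass_mg`; per-row `prefactor` and
#' `exponent` columns override the `allometry` argument. Row order is
#' preserved and all invariants are validated (positive masses, unique ids).
#'
#' @param path CSV or TSV file (delimiter inferred from extension).
#' @param allometry An [allometric_model()] applied to rows lacking their
#'   own `prefactor`/`exponent` columns.
#' @return A validated consumer tibble.
#' @export
read_consumers <- function(path, allometry = NULL) {
  tbl <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  if (!all(c("prefactor", "exponent") %in% names(tbl))) {
    if (is.null(allometry)) {
      abort_schema(paste0(
        "consumer table has no prefactor/exponent columns; ",
        "supply a shared `allometry`"
      ))
    }
    tbl$prefactor <- allometry$prefactor
    tbl$exponent <- allometry$exponent
  }
  tbl$baseline_bite_force_mn <- NULL # recompute from traits
  validate_consumers(tbl)
}

#' Read a resource trait table from CSV/TSV
#'
#' Requires columns `id` and `cutting_force_mn`; an optional `abundance`
#' column is carried through.
#'
#' @param path CSV or TSV file (delimiter inferred from extension).
#' @return A validated resource tibble.
#' @export
read_resources <- function(path) {
  tbl <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  validate_resources(tbl)
}

#' Write consumer and resource trait tables
#'
#' Writes `consumers.csv` and `resources.csv` under `dir` in the schema
#' that [read_consumers()]/[read_resources()] round-trip.
#'
#' @param consumers,resources Validated trait tibbles.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_community <- function(consumers, resources, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  consumer_path <- file.path(dir, "consumers.csv")
  resource_path <- file.path(dir, "resources.csv")
  readr::write_csv(validate_consumers(consumers), consumer_path)
  readr::write_csv(validate_resources(resources), resource_path)
  invisible(c(consumers = consumer_path, resources = resource_path))
}
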