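# Temperature sweep: one feasibility network per grid point, stacked into a
# multilayer result with per-layer metrics, interlayer turnover, and
# verdicts on the three warming hypotheses.

#' Sweep a community across a temperature grid
#'
#' Builds one feasibility network per grid temperature, computes per-layer
#' metrics (consumer degrees, generality, connectance) and the link
#' turnover between adjacent layers. The grid must be sorted ascending and
#' contain the rule's reference temperature, so the baseline layer is
#' always present.
#'
#' @param consumers,resources Trait tibbles ([consumer_table()],
#'   [resource_table()]).
#' @param t_grid Ascending numeric temperature grid (degrees C), or a
#'   `"start:stop:step"` string (see [parse_t_grid()]). Default 20-30 by
#'   0.5.
#' @param rule A [temp_size_rule()].
#' @return An object of class `sweep_result`: `temperatures`, `networks`
#'   (list of `feasibility_network`s), `metrics` (tibble `temperature`,
#'   `n_edges`, `connectance`, `generality`), `degrees` (tibble
#'   `temperature`, `consumer_id`, `degree`), `turnover` (tibble
#'   `from_temperature`, `to_temperature`, `turnover`), plus the inputs.
#' @examples
#' comm <- generate_community(synthetic_config(seed = 7))
#' sw <- temperature_sweep(comm$consumers, comm$resources,
#'                         t_grid = seq(20, 30, 2),
#'                         rule = temp_size_rule(0.9, 20))
#' sw$metrics
#' @export
temperature_sweep <- function(consumers, resources,
                              t_grid = seq(20, 30, by = 0.5),
                              rule = temp_size_rule(0.9, 20)) {
  if (is.character(t_grid)) t_grid <- parse_t_grid(t_grid)
  check_finite(t_grid, "t_grid")
  if (is.unsorted(t_grid, strictly = TRUE)) {
    abort_usage("t_grid must be sorted strictly ascending")
  }
  if (min(abs(t_grid - rule$reference_temperature)) > 1e-9) {
    abort_usage(sprintf(
      "t_grid must include the rule's reference temperature (%g degrees C)",
      rule$reference_temperature
    ))
  }
  consumers <- validate_consumers(consumers)
  resources <- validate_resources(resources)
  networks <- purrr::map(
    t_grid, ~ build_network(consumers, resources, .x, rule)
  )
  metrics <- purrr::map2_dfr(networks, t_grid, function(net, tt) {
    tibble::tibble(
      temperature = tt,
      n_edges = nrow(net$edges),
      connectance = connectance(net),
      generality = generality(net)
    )
  })
  degrees <- purrr::map2_dfr(networks, t_grid, function(net, tt) {
    dplyr::mutate(consumer_degrees(net), temperature = tt, .before = 1)
  })
  turnover <- if (length(t_grid) > 1) {
    tibble::tibble(
      from_temperature = t_grid[-length(t_grid)],
      to_temperature = t_grid[-1],
      turnover = purrr::map2_dbl(
        networks[-length(networks)], networks[-1], link_turnover
      )
    )
  } else {
    tibble::tibble(from_temperature = numeric(), to_temperature = numeric(),
                   turnover = numeric())
  }
  structure(
    list(
      temperatures = t_grid,
      networks = networks,
      metrics = metrics,
      degrees = degrees,
      turnover = turnover,
      consumers = consumers,
      resources = resources,
      rule = rule
    ),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "<sweep_result> %d layers over %g-%g degrees C; generality %.2f -> %.2f\n",
    length(x$temperatures), min(x$temperatures), max(x$temperatures),
    x$metrics$generality[1], x$metrics$generality[nrow(x$metrics)]
  ))
  invisible(x)
}

# Spearman rank correlation, NA-safe for constant series.
spearman_or_na <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Evaluate the three warming hypotheses on a sweep
#'
#' The warming hypotheses for a bite-force-limited consumer guild are:
#' H1, generality declines with temperature; H2, individual consumers'
#' degrees decline with temperature; H3, the magnitude of degree loss
#' differs between consumers depending on their baseline bite force.
#'
#' Verdicts are sign-based on deterministic series (no p-values): H1 is
#' supported when the Spearman rank correlation of generality with
#' temperature is negative; H2 when every consumer whose degree series
#' changes at all has a negative rank correlation (and at least one
#' changes); H3 when the range of per-consumer total degree losses
#' (first minus last layer) is positive, i.e. losses are heterogeneous.
#'
#' @param sweep A `sweep_result` with at least 3 grid points.
#' @return A tibble with columns `hypothesis`, `description`, `statistic`,
#'   `value`, `supported`.
#' @export
evaluate_hypotheses <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (length(sweep$temperatures) < 3) {
    abort_usage("hypothesis evaluation needs at least 3 grid points")
  }
  rho_gen <- spearman_or_na(sweep$metrics$temperature,
                            sweep$metrics$generality)
  per_consumer <- sweep$degrees |>
    dplyr::group_by(.data$consumer_id) |>
    dplyr::summarise(
      rho = spearman_or_na(.data$temperature, .data$degree),
      loss = .data$degree[1] - .data$degree[dplyr::n()],
      nonconstant = stats::sd(.data$degree) > 0,
      .groups = "drop"
    )
  n_noncon <- sum(per_consumer$nonconstant)
  frac_negative <- if (n_noncon > 0) {
    sum(per_consumer$rho < 0, na.rm = TRUE) / n_noncon
  } else {
    0
  }
  loss_range <- diff(range(per_consumer$loss))
  tibble::tibble(
    hypothesis = c("H1", "H2", "H3"),
    description = c(
      "warming decreases consumer generality",
      "warming decreases individual consumer degrees",
      "degree loss differs between consumers (baseline bite force)"
    ),
    statistic = c(
      "spearman_rho_generality_vs_temperature",
      "fraction_of_nonconstant_consumers_with_negative_rho",
      "range_of_per_consumer_degree_losses"
    ),
    value = c(rho_gen, frac_negative, loss_range),
    supported = c(
      isTRUE(rho_gen < 0),
      n_noncon > 0 && frac_negative == 1,
      isTRUE(loss_range > 0)
    )
  )
}

#' Closed-form temperature offset at which an edge disappears
#'
#' For a consumer with baseline bite force `f_bite0` scaling as
#' `mass^exponent` under per-degree size factor `alpha < 1`, the edge to a
#' resource requiring `f_cut` (with `f_cut <= f_bite0`) is lost once
#' `f_bite0 * alpha^(exponent * delta_t) < f_cut`, i.e. beyond
#' `delta_t = log(f_cut / f_bite0) / (exponent * log(alpha))`.
#'
#' @param f_bite0 Baseline bite force (mN).
#' @param f_cut Required cutting force (mN).
#' @param alpha Per-degree size factor in (0, 1).
#' @param exponent Positive allometric exponent.
#' @return The warming offset (degrees C) at which feasibility is lost.
#' @export
edge_loss_delta_t <- function(f_bite0, f_cut, alpha, exponent) {
  check_positive(f_bite0, "f_bite0")
  check_positive(f_cut, "f_cut")
  check_positive(alpha, "alpha")
  check_positive(exponent, "exponent")
  if (alpha >= 1) abort_usage("edge loss requires alpha < 1")
  log(f_cut / f_bite0) / (exponent * log(alpha))
}
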