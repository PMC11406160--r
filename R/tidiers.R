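# broom-style tidiers and ggplot2 autoplot methods for the result classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a feasibility network into its edge tibble
#'
#' @param x A `feasibility_network`.
#' @param ... Unused.
#' @return The edge tibble (`consumer_id`, `resource_id`, `weight_mn`) with
#'   a `temperature` column prepended.
#' @export
tidy.feasibility_network <- function(x, ...) {
  dplyr::mutate(x$edges, temperature = x$temperature, .before = 1)
}

#' One-row summary of a feasibility network
#'
#' @param x A `feasibility_network`.
#' @param ... Unused.
#' @return A one-row tibble: `temperature`, `n_consumers`, `n_resources`,
#'   `n_edges`, `connectance`, `generality`.
#' @export
glance.feasibility_network <- function(x, ...) {
  tibble::tibble(
    temperature = x$temperature,
    n_consumers = nrow(x$consumers),
    n_resources = nrow(x$resources),
    n_edges = nrow(x$edges),
    connectance = connectance(x),
    generality = generality(x)
  )
}

#' Tidy a sweep into long per-layer metrics
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return A long tibble `temperature`, `metric`, `value` covering
#'   generality, connectance and edge count per layer.
#' @export
tidy.sweep_result <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, -"temperature",
                      names_to = "metric", values_to = "value")
}

#' One-row summary of a temperature sweep
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return A one-row tibble with layer counts, baseline and final
#'   generality, mean interlayer turnover, and the complete-collapse
#'   temperature (`NA` when no layer is empty).
#' @export
glance.sweep_result <- function(x, ...) {
  collapse_idx <- which(x$metrics$n_edges == 0)
  tibble::tibble(
    n_layers = length(x$temperatures),
    n_consumers = nrow(x$consumers),
    n_resources = nrow(x$resources),
    baseline_generality = x$metrics$generality[1],
    final_generality = x$metrics$generality[nrow(x$metrics)],
    mean_turnover = if (nrow(x$turnover) > 0) mean(x$turnover$turnover) else NA_real_,
    collapse_temperature = if (length(collapse_idx) > 0) {
      x$temperatures[min(collapse_idx)]
    } else {
      NA_real_
    }
  )
}

#' Tidy a robustness result into its mean attack-tolerance curve
#'
#' @param x A `robustness_result`.
#' @param ... Unused.
#' @return The mean curve tibble (`removal_fraction`,
#'   `surviving_fraction`).
#' @export
tidy.robustness_result <- function(x, ...) {
  x$curve
}

#' One-row summary of a robustness analysis
#'
#' @param x A `robustness_result`.
#' @param ... Unused.
#' @return A one-row tibble: `robustness_r`, `removal_strategy`,
#'   `n_replicates`, `seed`.
#' @export
glance.robustness_result <- function(x, ...) {
  tibble::tibble(
    robustness_r = x$robustness_r,
    removal_strategy = x$removal_strategy,
    n_replicates = x$n_replicates,
    seed = x$seed
  )
}

#' Niche-contraction plot for a temperature sweep
#'
#' Per-consumer degree trajectories (thin lines) with the guild-level
#' generality (thick line) against temperature: the visual signature of
#' trophic-niche contraction under warming.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = object$degrees,
      ggplot2::aes(.data$temperature, .data$degree,
                   group = .data$consumer_id, colour = .data$consumer_id),
      linewidth = 0.4, alpha = 0.8
    ) +
    ggplot2::geom_line(
      data = object$metrics,
      ggplot2::aes(.data$temperature, .data$generality),
      linewidth = 1.1, colour = "black"
    ) +
    ggplot2::labs(
      x = "temperature (°C)",
      y = "resources accessible (degree; black = generality)",
      colour = "consumer",
      title = "Trophic niche contraction under warming"
    ) +
    ggplot2::theme_minimal()
}

#' Attack-tolerance curve plot
#'
#' @param object A `robustness_result`.
#' @param ... Unused.
#' @return A ggplot object of the mean surviving fraction versus fraction
#'   of resources removed, annotated with R.
#' @export
autoplot.robustness_result <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(.data$removal_fraction,
                               .data$surviving_fraction)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "fraction of resources removed",
      y = "fraction of consumers surviving",
      title = sprintf("Attack tolerance (%s removal), R = %.3f",
                      object$removal_strategy, object$robustness_r)
    ) +
    ggplot2::theme_minimal()
}
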