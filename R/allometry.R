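# Trait-level biomechanics: allometric scaling, the temperature-size rule,
# propagation of size change to performance, and Q10 thermal performance.

#' Allometric power-law model for a biomechanical trait
#'
#' Describes how a trait (here, maximum bite force in mN) scales with body
#' mass as `trait = prefactor * mass^exponent`. Evaluating the model at unit
#' mass returns the prefactor exactly.
#'
#' @param prefactor Trait value at unit body mass (e.g. mN at 1 mg); must be
#'   positive.
#' @param exponent Dimensionless scaling coefficient. Classic geometric
#'   expectations are 1/3 (length-like traits), 2/3 (area-like, e.g. muscle
#'   cross-section and hence force), 1 (volume-like).
#' @return An object of class `allometric_model`.
#' @examples
#' mod <- allometric_model(prefactor = 10, exponent = 2 / 3)
#' scale_trait(100, mod)
#' @export
allometric_model <- function(prefactor, exponent) {
  check_positive(prefactor, "prefactor")
  check_finite(exponent, "exponent")
  if (!is_scalar_number(prefactor) || !is_scalar_number(exponent)) {
    abort_domain("prefactor and exponent must be single finite numbers")
  }
  structure(
    list(prefactor = prefactor, exponent = exponent),
    class = "allometric_model"
  )
}

#' @export
print.allometric_model <- function(x, ...) {
  cat(sprintf(
    "<allometric_model> trait = %g * mass^%g\n", x$prefactor, x$exponent
  ))
  invisible(x)
}

#' Temperature-size rule
#'
#' Multiplicative body-size response to warming: for each degree Celsius
#' above the reference temperature, body mass is multiplied by `alpha`.
#' Over a temperature offset `delta_t` the factor compounds geometrically as
#' `alpha^delta_t`, which preserves positivity and reduces to the
#' single-degree factor at `delta_t = 1`. `alpha = 1` is the identity rule
#' (no shrinkage); `alpha < 1` encodes shrinkage under warming, the typical
#' ectotherm response.
#'
#' @param alpha Dimensionless body-size factor per +1 degree C; must be
#'   positive. A 10% shrink per degree is `alpha = 0.9`.
#' @param reference_temperature Temperature (degrees C) at which reference
#'   body masses are defined. Default 20.
#' @return An object of class `temp_size_rule`.
#' @examples
#' rule <- temp_size_rule(alpha = 0.9, reference_temperature = 20)
#' apply_size_rule(100, delta_t = 1, rule) # 90
#' @export
temp_size_rule <- function(alpha, reference_temperature = 20) {
  check_positive(alpha, "alpha")
  check_finite(reference_temperature, "reference_temperature")
  structure(
    list(alpha = alpha, reference_temperature = reference_temperature),
    class = "temp_size_rule"
  )
}

#' @export
print.temp_size_rule <- function(x, ...) {
  cat(sprintf(
    "<temp_size_rule> alpha = %g per degree C (reference %g degrees C)\n",
    x$alpha, x$reference_temperature
  ))
  invisible(x)
}

#' Q10 thermal performance model with a high-temperature plateau
#'
#' Muscle-driven performance rises with temperature by a factor `q10` per
#' 10 degrees C until it plateaus at high temperature; above
#' `plateau_temperature` performance is held at the plateau value (a hard
#' cap, continuous at the junction).
#'
#' @param q10 Dimensionless rate factor per +10 degrees C; must be positive.
#'   Muscle performance typically has `q10` near 2.
#' @param reference_temperature Temperature (degrees C) at which the
#'   reference trait value is defined.
#' @param plateau_temperature Temperature (degrees C) above which performance
#'   stops increasing; must be at least `reference_temperature`.
#' @return An object of class `thermal_performance_model`.
#' @export
thermal_performance_model <- function(q10 = 2, reference_temperature = 20,
                                      plateau_temperature = 40) {
  check_positive(q10, "q10")
  check_finite(reference_temperature, "reference_temperature")
  check_finite(plateau_temperature, "plateau_temperature")
  if (plateau_temperature < reference_temperature) {
    abort_domain("plateau_temperature must be >= reference_temperature")
  }
  structure(
    list(
      q10 = q10,
      reference_temperature = reference_temperature,
      plateau_temperature = plateau_temperature
    ),
    class = "thermal_performance_model"
  )
}

#' @export
print.thermal_performance_model <- function(x, ...) {
  cat(sprintf(
    "<thermal_performance_model> Q10 = %g, reference %g degrees C, plateau %g degrees C\n",
    x$q10, x$reference_temperature, x$plateau_temperature
  ))
  invisible(x)
}

#' Evaluate an allometric trait at a given body mass
#'
#' @param mass Body mass (mg); positive, vectorised.
#' @param model An [allometric_model()].
#' @return Trait value(s) `prefactor * mass^exponent`.
#' @examples
#' scale_trait(100, allometric_model(10, 2 / 3)) # 215.44
#' @export
scale_trait <- function(mass, model) {
  stopifnot(inherits(model, "allometric_model"))
  check_positive(mass, "mass")
  model$prefactor * mass^model$exponent
}

#' Shrink (or grow) a body mass according to the temperature-size rule
#'
#' @param mass0 Reference body mass (mg); positive, vectorised.
#' @param delta_t Temperature offset from the reference (degrees C); may be
#'   negative (cooling).
#' @param rule A [temp_size_rule()].
#' @return Body mass `mass0 * alpha^delta_t`; the identity at `delta_t = 0`.
#' @export
apply_size_rule <- function(mass0, delta_t, rule) {
  stopifnot(inherits(rule, "temp_size_rule"))
  check_positive(mass0, "mass0")
  check_finite(delta_t, "delta_t")
  mass0 * rule$alpha^delta_t
}

#' Performance change implied by temperature-driven size change
#'
#' A trait scaling as `mass^exponent` responds to a per-degree size factor
#' `alpha` with a per-degree performance factor `alpha^exponent`; over
#' `delta_t` degrees the factor is `(alpha^delta_t)^exponent`. With
#' `alpha = 0.9` and one degree of warming, traits scaling with length
#' (1/3), area (2/3) or volume (1) lose about 3.5%, 6.8% and 10%
#' respectively.
#'
#' @param alpha Per-degree body-size factor; positive.
#' @param exponent Allometric scaling coefficient of the trait.
#' @param delta_t Temperature offset in degrees C (default 1).
#' @return The multiplicative performance factor.
#' @examples
#' propagate_performance_factor(0.9, 1)      # 0.9  (10% decrease)
#' propagate_performance_factor(0.9, 1 / 3)  # 0.9655 (~3.45% decrease)
#' @export
propagate_performance_factor <- function(alpha, exponent, delta_t = 1) {
  check_positive(alpha, "alpha")
  check_finite(exponent, "exponent")
  check_finite(delta_t, "delta_t")
  (alpha^delta_t)^exponent
}

#' Q10 thermal performance with plateau
#'
#' Scales a reference trait value to another temperature using the Q10 rule,
#' holding performance constant above the plateau temperature:
#' `value * q10^((min(temperature, plateau) - reference) / 10)`.
#'
#' @param reference_value Trait value at the model's reference temperature;
#'   positive, vectorised.
#' @param temperature Temperature (degrees C) at which to evaluate;
#'   vectorised.
#' @param model A [thermal_performance_model()].
#' @return Trait value(s) at `temperature`.
#' @examples
#' m <- thermal_performance_model(q10 = 2, reference_temperature = 20,
#'                                plateau_temperature = 40)
#' thermal_performance(1, 30, m) # 2: doubles over 10 degrees C
#' @export
thermal_performance <- function(reference_value, temperature, model) {
  stopifnot(inherits(model, "thermal_performance_model"))
  check_positive(reference_value, "reference_value")
  check_finite(temperature, "temperature")
  t_eff <- pmin(temperature, model$plateau_temperature)
  reference_value * model$q10^((t_eff - model$reference_temperature) / 10)
}

#' Per-degree readings of a Q10 factor
#'
#' A Q10 of 2 (doubling over 10 degrees C) is commonly quoted as a "10%
#' increase per degree": the linear reading `(q10 - 1) / 10`. The exact
#' geometric per-degree factor is `q10^0.1` (about 1.0718 for Q10 = 2).
#' Both are returned.
#'
#' @param q10 Dimensionless rate factor per +10 degrees C.
#' @return A one-row tibble with columns `q10`, `linear_pct_per_degree`,
#'   `geometric_factor_per_degree`, `geometric_pct_per_degree`.
#' @examples
#' q10_per_degree(2)
#' @export
q10_per_degree <- function(q10 = 2) {
  check_positive(q10, "q10")
  tibble::tibble(
    q10 = q10,
    linear_pct_per_degree = (q10 - 1) / 10 * 100,
    geometric_factor_per_degree = q10^0.1,
    geometric_pct_per_degree = (q10^0.1 - 1) * 100
  )
}

#' Bite force of consumers at a given temperature
#'
#' Composes the temperature-size rule with each consumer's bite-force
#' allometry: reference mass is shrunk by `alpha^(temperature - reference)`,
#' then the allometry is evaluated at the shrunken mass. At the rule's
#' reference temperature this returns the baseline bite force.
#'
#' @param consumers A consumer tibble as returned by [consumer_table()] or
#'   [generate_community()]: columns `id`, `reference_mass_mg`, `prefactor`,
#'   `exponent`.
#' @param temperature Temperature (degrees C).
#' @param rule A [temp_size_rule()].
#' @return The input tibble with columns `mass_mg` (mass at `temperature`)
#'   and `bite_force_mn` appended.
#' @examples
#' cons <- consumer_table(
#'   id = "c1", reference_mass_mg = 100,
#'   allometry = allometric_model(10, 2 / 3)
#' )
#' bite_force_at_temperature(cons, 21, temp_size_rule(0.9, 20))
#' @export
bite_force_at_temperature <- function(consumers, temperature, rule) {
  stopifnot(inherits(rule, "temp_size_rule"))
  consumers <- validate_consumers(consumers)
  check_finite(temperature, "temperature")
  delta_t <- temperature - rule$reference_temperature
  dplyr::mutate(
    consumers,
    mass_mg = .data$reference_mass_mg * rule$alpha^delta_t,
    bite_force_mn = .data$prefactor * .data$mass_mg^.data$exponent
  )
}
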