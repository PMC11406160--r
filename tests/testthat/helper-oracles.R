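# Independent oracles and random-instance generators for property tests.
# These deliberately avoid the package's vectorised code paths: the edge
# oracle is an explicit double loop, and the robustness oracle enumerates
# removal orders and counts survivors by raw set logic.

# Random community with bite and cutting forces drawn on overlapping
# log-scales so instances are neither empty nor complete too often.
random_instance <- function(n_consumers, n_resources) {
  consumers <- consumer_table(
    id = paste0("c", seq_len(n_consumers)),
    reference_mass_mg = stats::rlnorm(n_consumers, log(30), 0.6),
    prefactor = stats::runif(n_consumers, 5, 15),
    exponent = stats::runif(n_consumers, 0.3, 1.2)
  )
  resources <- resource_table(
    id = paste0("p", seq_len(n_resources)),
    cutting_force_mn = stats::rlnorm(n_resources, log(90), 0.8)
  )
  list(consumers = consumers, resources = resources)
}

# Brute-force feasibility edges as sorted "consumer|resource" keys.
oracle_edge_keys <- function(consumers, resources, temperature, rule) {
  keys <- character(0)
  for (i in seq_len(nrow(consumers))) {
    mass_t <- consumers$reference_mass_mg[i] *
      rule$alpha^(temperature - rule$reference_temperature)
    bite <- consumers$prefactor[i] * mass_t^consumers$exponent[i]
    for (j in seq_len(nrow(resources))) {
      if (bite >= resources$cutting_force_mn[j]) {
        keys <- c(keys, paste(consumers$id[i], resources$id[j], sep = "|"))
      }
    }
  }
  sort(keys)
}

edge_keys <- function(network) {
  sort(paste(network$edges$consumer_id, network$edges$resource_id, sep = "|"))
}

# All permutations of a vector (n <= 5 in tests).
all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}

# Survivors after removing resources in `order`, by raw set logic.
oracle_curve <- function(network, order) {
  sapply(seq_along(order), function(k) {
    remaining <- setdiff(network$resources$id, order[seq_len(k)])
    alive <- vapply(network$consumers$id, function(cid) {
      any(network$edges$consumer_id == cid &
            network$edges$resource_id %in% remaining)
    }, logical(1))
    mean(alive)
  })
}

# Exact expected robustness under uniformly random removal order:
# average of the trapezoid area over every permutation.
oracle_random_robustness <- function(network) {
  orders <- all_permutations(network$resources$id)
  n <- length(network$resources$id)
  x <- c(0, seq_len(n) / n)
  mean(vapply(orders, function(ord) {
    y <- c(1, oracle_curve(network, ord))
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  }, numeric(1)))
}

# Identity-rule shorthand used all over the network tests.
identity_rule <- function(reference_temperature = 20) {
  temp_size_rule(alpha = 1, reference_temperature = reference_temperature)
}
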