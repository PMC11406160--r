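# Structural metrics: degree, generality, connectance, robustness to
# secondary extinctions, and interlayer link turnover.

#' Degree of one consumer
#'
#' @param network A `feasibility_network`.
#' @param consumer_id A consumer label present in the network.
#' @return Number of resources the consumer is linked to.
#' @export
consumer_degree <- function(network, consumer_id) {
  stopifnot(inherits(network, "feasibility_network"))
  if (!consumer_id %in% network$consumers$id) {
    abort_usage(sprintf("unknown consumer id: %s", consumer_id))
  }
  sum(network$edges$consumer_id == consumer_id)
}

#' Degrees of all consumers
#'
#' @param network A `feasibility_network`.
#' @return A tibble `consumer_id`, `degree`, one row per consumer in the
#'   network's order (isolated consumers included with degree 0).
#' @export
consumer_degrees <- function(network) {
  stopifnot(inherits(network, "feasibility_network"))
  counts <- table(factor(network$edges$consumer_id,
                         levels = network$consumers$id))
  tibble::tibble(
    consumer_id = network$consumers$id,
    degree = as.integer(counts)
  )
}

#' Generality: mean niche breadth of consumers
#'
#' The unweighted default is the arithmetic mean consumer degree, i.e. the
#' mean number of resources a consumer can mechanically access. The
#' weighted variant is the mean exponential Shannon diversity of each
#' consumer's edge weights (force surpluses), a standard effective-number
#' reading of niche breadth; isolated consumers contribute 0 under both.
#'
#' @param network A `feasibility_network`.
#' @param weighted If `TRUE`, use the Shannon-exponential variant.
#' @return A single number; 0 for an empty edge set.
#' @export
generality <- function(network, weighted = FALSE) {
  stopifnot(inherits(network, "feasibility_network"))
  if (!weighted) {
    return(mean(consumer_degrees(network)$degree))
  }
  eff <- vapply(network$consumers$id, function(cid) {
    w <- network$edges$weight_mn[network$edges$consumer_id == cid]
    w <- w[w > 0]
    if (length(w) == 0) return(0)
    p <- w / sum(w)
    exp(-sum(p * log(p)))
  }, numeric(1))
  mean(eff)
}

#' Connectance: realised fraction of possible links
#'
#' @param network A `feasibility_network`.
#' @return `|edges| / (n_consumers * n_resources)`, in `[0, 1]`.
#' @export
connectance <- function(network) {
  stopifnot(inherits(network, "feasibility_network"))
  nrow(network$edges) / (nrow(network$consumers) * nrow(network$resources))
}

#' Link turnover (rewiring) between two network layers
#'
#' Jaccard dissimilarity of the two edge sets:
#' `1 - |A intersect B| / |A union B|`. Identical layers give 0, disjoint
#' non-empty layers give 1; two empty layers are defined as 0 turnover.
#'
#' @param network_a,network_b Two `feasibility_network`s over the same node
#'   label spaces (e.g. adjacent temperature layers).
#' @return A fraction in `[0, 1]`.
#' @export
link_turnover <- function(network_a, network_b) {
  stopifnot(inherits(network_a, "feasibility_network"),
            inherits(network_b, "feasibility_network"))
  if (!setequal(network_a$consumers$id, network_b$consumers$id) ||
      !setequal(network_a$resources$id, network_b$resources$id)) {
    abort_usage("layers must share consumer and resource label spaces")
  }
  key_a <- paste(network_a$edges$consumer_id, network_a$edges$resource_id,
                 sep = "\r")
  key_b <- paste(network_b$edges$consumer_id, network_b$edges$resource_id,
                 sep = "\r")
  union_n <- length(union(key_a, key_b))
  if (union_n == 0) return(0)
  1 - length(intersect(key_a, key_b)) / union_n
}

resolve_removal_order <- function(network, strategy) {
  res_ids <- network$resources$id
  switch(
    strategy,
    "most-connected-first" = {
      # In a bipartite graph removing resources never changes the degree of
      # the remaining resources, so the iterative rule collapses to a static
      # sort by initial resource degree (ties keep table order).
      deg <- as.integer(table(factor(network$edges$resource_id,
                                     levels = res_ids)))
      res_ids[order(-deg)]
    },
    "toughest-resource-first" = {
      if (!"cutting_force_mn" %in% names(network$resources)) {
        abort_usage(
          "toughest-resource-first needs a cutting_force_mn column on resources"
        )
      }
      res_ids[order(-network$resources$cutting_force_mn)]
    },
    abort_usage(sprintf("unknown removal strategy: %s", strategy))
  )
}

# Surviving-consumer fractions after each removal in `order`.
# A consumer goes secondarily extinct when its last linked resource is
# removed; consumers with no links count as extinct from the first step.
survival_curve <- function(network, order) {
  n_cons <- nrow(network$consumers)
  pos <- match(network$edges$resource_id, order)
  # per consumer: the step at which its last resource disappears (0 if none)
  last_step <- rep(0L, n_cons)
  if (nrow(network$edges) > 0) {
    idx <- match(network$edges$consumer_id, network$consumers$id)
    agg <- tapply(pos, idx, max)
    last_step[as.integer(names(agg))] <- as.integer(agg)
  }
  vapply(seq_along(order), function(k) sum(last_step > k) / n_cons,
         numeric(1))
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Robustness to sequential extinctions (attack-tolerance curve)
#'
#' Resources (the default primary-extinction side) are removed one at a
#' time according to `strategy`; a consumer suffers secondary extinction
#' when its degree reaches zero. The surviving-consumer fraction is
#' recorded after each removal, with the conventional starting point
#' (0, 1) prepended, and robustness R is the trapezoidal area under the
#' curve of surviving fraction versus fraction removed — 1 for a network
#' that never loses a consumer, towards 0 for one that collapses
#' immediately. The `random` strategy averages curves over `n_replicates`
#' uniformly random removal orders drawn under `seed`; the two
#' deterministic strategies yield a single curve.
#'
#' @param network A `feasibility_network`.
#' @param strategy One of `"random"`, `"most-connected-first"`,
#'   `"toughest-resource-first"`.
#' @param n_replicates Replicates for the random strategy (ignored, with a
#'   single curve, for deterministic strategies).
#' @param seed RNG seed for the random strategy; recorded in the result.
#' @param side Which side suffers primary extinctions; `"resources"`
#'   (default) or `"consumers"` (roles swapped symmetrically).
#' @return An object of class `robustness_result`: `curve` (tibble
#'   `removal_fraction`, `surviving_fraction`, the replicate mean),
#'   `replicate_curves` (long tibble `replicate`, `step`,
#'   `removal_fraction`, `surviving_fraction`), `robustness_r`,
#'   `removal_strategy`, `n_replicates`, `seed`.
#' @examples
#' cons <- consumer_table("c1", 1, allometry = allometric_model(10, 0))
#' res <- resource_table(c("p1", "p2"), c(5, 5))
#' net <- build_network(cons, res, 20, temp_size_rule(1))
#' robustness(net, "most-connected-first")$robustness_r # 0.75
#' @export
robustness <- function(network,
                       strategy = c("random", "most-connected-first",
                                    "toughest-resource-first"),
                       n_replicates = 100, seed = 1L,
                       side = c("resources", "consumers")) {
  stopifnot(inherits(network, "feasibility_network"))
  if (length(strategy) != 1 || !strategy %in%
        c("random", "most-connected-first", "toughest-resource-first")) {
    strategy <- tryCatch(match.arg(strategy),
                         error = function(e) abort_usage(
                           sprintf("unknown removal strategy: %s",
                                   paste(strategy, collapse = "/"))))
  }
  side <- match.arg(side)
  if (side == "consumers") network <- transpose_network(network)
  if (nrow(network$resources) == 0) {
    abort_usage("robustness needs at least one resource to remove")
  }
  n_res <- nrow(network$resources)
  removal_fractions <- c(0, seq_len(n_res) / n_res)
  if (strategy == "random") {
    orders <- withr::with_seed(seed, {
      lapply(seq_len(n_replicates), function(i) sample(network$resources$id))
    })
  } else {
    orders <- list(resolve_removal_order(network, strategy))
    n_replicates <- length(orders)
  }
  curves <- vapply(orders, function(ord) c(1, survival_curve(network, ord)),
                   numeric(n_res + 1))
  mean_curve <- rowMeans(curves)
  replicate_curves <- tibble::tibble(
    replicate = rep(seq_along(orders), each = n_res + 1),
    step = rep(0:n_res, times = length(orders)),
    removal_fraction = rep(removal_fractions, times = length(orders)),
    surviving_fraction = as.vector(curves)
  )
  structure(
    list(
      curve = tibble::tibble(
        removal_fraction = removal_fractions,
        surviving_fraction = mean_curve
      ),
      replicate_curves = replicate_curves,
      robustness_r = trapezoid_area(removal_fractions, mean_curve),
      removal_strategy = strategy,
      n_replicates = n_replicates,
      seed = as.integer(seed),
      side = side
    ),
    class = "robustness_result"
  )
}

# Swap consumer/resource roles so consumer-side removal reuses the same
# machinery. The transposed "resources" (original consumers) carry no
# cutting force, so toughest-resource-first is unavailable on that side.
transpose_network <- function(network) {
  structure(
    list(
      temperature = network$temperature,
      consumers = tibble::tibble(id = network$resources$id),
      resources = tibble::tibble(id = network$consumers$id),
      edges = tibble::tibble(
        consumer_id = network$edges$resource_id,
        resource_id = network$edges$consumer_id,
        weight_mn = network$edges$weight_mn
      )
    ),
    class = "feasibility_network"
  )
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf(
    "<robustness_result> R = %.4f (%s removal, %d replicate%s, seed %d)\n",
    x$robustness_r, x$removal_strategy, x$n_replicates,
    if (x$n_replicates == 1) "" else "s", x$seed
  ))
  invisible(x)
}

#' Write robustness replicate curves as long-format CSV
#'
#' Columns `replicate`, `step`, `removal_fraction`, `surviving_fraction`.
#'
#' @param result A `robustness_result`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_robustness_curves <- function(result, path) {
  stopifnot(inherits(result, "robustness_result"))
  readr::write_csv(result$replicate_curves, path)
  invisible(path)
}
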