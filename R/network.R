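# Temperature-stamped bipartite feasibility networks.
#
# An interaction is mechanically feasible when a consumer's bite force at
# the network's temperature is at least the resource's required cutting
# force (ties count as feasible). Edge weights are the force surplus
# (bite - cutting, mN), never interaction frequencies.

#' Build a bite-force feasibility network at a temperature
#'
#' Consumers' bite forces are evaluated at `temperature` via the
#' temperature-size rule and each consumer-resource pair is linked iff
#' bite force >= required cutting force. The edge set is a deterministic
#' function of traits and temperature.
#'
#' @param consumers Consumer tibble ([consumer_table()]).
#' @param resources Resource tibble ([resource_table()]).
#' @param temperature Temperature (degrees C) stamped on the network.
#' @param rule A [temp_size_rule()].
#' @return An object of class `feasibility_network`: list with
#'   `temperature`, `consumers` (with `bite_force_mn` at this temperature),
#'   `resources`, and `edges` (tibble `consumer_id`, `resource_id`,
#'   `weight_mn` with all weights >= 0).
#' @examples
#' cons <- consumer_table(c("c1", "c2"), c(8, 42.875),
#'                        allometry = allometric_model(10, 2 / 3))
#' res <- resource_table(c("p1", "p2", "p3"), c(10, 25, 50))
#' build_network(cons, res, 20, temp_size_rule(0.9, 20))
#' @export
build_network <- function(consumers, resources, temperature, rule) {
  consumers <- validate_consumers(consumers)
  resources <- validate_resources(resources)
  if (nrow(consumers) == 0 || nrow(resources) == 0) {
    abort_usage("consumers and resources must both be non-empty")
  }
  consumers_t <- bite_force_at_temperature(consumers, temperature, rule)
  # vectorised pairwise comparison: surplus matrix, consumers x resources
  surplus <- outer(consumers_t$bite_force_mn, resources$cutting_force_mn, `-`)
  idx <- which(surplus >= 0, arr.ind = TRUE)
  edges <- tibble::tibble(
    consumer_id = consumers_t$id[idx[, 1]],
    resource_id = resources$id[idx[, 2]],
    weight_mn = surplus[idx]
  )
  edges <- dplyr::arrange(
    edges,
    match(.data$consumer_id, consumers_t$id),
    match(.data$resource_id, resources$id)
  )
  structure(
    list(
      temperature = temperature,
      consumers = consumers_t,
      resources = resources,
      edges = edges
    ),
    class = "feasibility_network"
  )
}

#' @export
print.feasibility_network <- function(x, ...) {
  cat(sprintf(
    "<feasibility_network> %g degrees C: %d consumers x %d resources, %d edges (connectance %.3f)\n",
    x$temperature, nrow(x$consumers), nrow(x$resources),
    nrow(x$edges), connectance(x)
  ))
  invisible(x)
}

#' Recover per-consumer feasibility thresholds from network structure
#'
#' Trait matching in reverse: given only which resources each consumer is
#' linked to, the consumer's bite force must lie in the half-open interval
#' `[max cutting force among linked resources, min cutting force among
#' unlinked resources)`. Consumers with no links get lower bound 0;
#' consumers linked to everything get upper bound `Inf`. For networks built
#' by [build_network()] the interval always brackets the true bite force
#' (parameter recovery).
#'
#' @param network A `feasibility_network`.
#' @param resources Resource tibble sharing the network's resource ids;
#'   defaults to the network's own table.
#' @return A tibble with columns `consumer_id`, `lower_mn`, `upper_mn`.
#' @export
infer_feasibility_threshold <- function(network, resources = NULL) {
  stopifnot(inherits(network, "feasibility_network"))
  resources <- validate_resources(resources %||% network$resources)
  if (!setequal(resources$id, network$resources$id)) {
    abort_usage("resource table and network must share resource ids")
  }
  cuts <- stats::setNames(resources$cutting_force_mn, resources$id)
  purrr::map_dfr(network$consumers$id, function(cid) {
    linked <- network$edges$resource_id[network$edges$consumer_id == cid]
    unlinked <- setdiff(resources$id, linked)
    tibble::tibble(
      consumer_id = cid,
      lower_mn = if (length(linked) > 0) max(cuts[linked]) else 0,
      upper_mn = if (length(unlinked) > 0) min(cuts[unlinked]) else Inf
    )
  })
}

#' Write a network's edge list as TSV
#'
#' Columns `consumer_id`, `resource_id`, `weight_mn`, `temperature_c`.
#'
#' @param network A `feasibility_network`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "feasibility_network"))
  out <- dplyr::mutate(network$edges, temperature_c = network$temperature)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read an edge-list TSV back into a feasibility network
#'
#' Accepts files written by [write_edge_list()] (or conforming). Node trait
#' tables may be supplied to restore attributes; otherwise minimal node
#' sets are reconstructed from the edges themselves. Malformed rows are
#' reported with their line numbers.
#'
#' @param path Edge-list TSV with columns `consumer_id`, `resource_id`,
#'   `weight_mn` and optionally `temperature_c`.
#' @param consumers,resources Optional trait tibbles naming the full node
#'   sets (so isolated nodes survive the round trip).
#' @return A `feasibility_network` (with `consumers`/`resources` reduced to
#'   id tables when traits are not supplied).
#' @export
read_edge_list <- function(path, consumers = NULL, resources = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("consumer_id", "resource_id", "weight_mn")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort_schema(sprintf(
      "edge list %s is missing column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  bad <- which(!is.finite(tbl$weight_mn) | tbl$weight_mn < 0)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "edge list %s: negative or non-numeric weight_mn at line(s) %s",
      path, paste(bad + 1L, collapse = ", ") # +1 for the header line
    ))
  }
  temperature <- if ("temperature_c" %in% names(tbl) && nrow(tbl) > 0) {
    tbl$temperature_c[1]
  } else {
    NA_real_
  }
  consumer_tbl <- if (!is.null(consumers)) {
    validate_consumers(consumers)
  } else {
    tibble::tibble(id = unique(as.character(tbl$consumer_id)))
  }
  resource_tbl <- if (!is.null(resources)) {
    validate_resources(resources)
  } else {
    tibble::tibble(id = unique(as.character(tbl$resource_id)))
  }
  unknown <- setdiff(tbl$consumer_id, consumer_tbl$id)
  unknown <- c(unknown, setdiff(tbl$resource_id, resource_tbl$id))
  if (length(unknown) > 0) {
    abort_validation(sprintf(
      "edge list %s references unknown node id(s): %s",
      path, paste(unique(unknown), collapse = ", ")
    ))
  }
  structure(
    list(
      temperature = temperature,
      consumers = consumer_tbl,
      resources = resource_tbl,
      edges = tibble::tibble(
        consumer_id = as.character(tbl$consumer_id),
        resource_id = as.character(tbl$resource_id),
        weight_mn = tbl$weight_mn
      )
    ),
    class = "feasibility_network"
  )
}

#' Convert a feasibility network to an igraph bipartite graph
#'
#' Node attributes carry the traits (mass and bite force at the network's
#' temperature for consumers; required cutting force for resources);
#' `type` is `FALSE` for consumers and `TRUE` for resources, the usual
#' igraph bipartite convention.
#'
#' @param network A `feasibility_network`.
#' @return An igraph graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "feasibility_network"))
  vertices <- dplyr::bind_rows(
    tibble::tibble(
      name = network$consumers$id,
      type = FALSE,
      mass_mg = if ("mass_mg" %in% names(network$consumers))
        network$consumers$mass_mg else NA_real_,
      bite_force_mn = if ("bite_force_mn" %in% names(network$consumers))
        network$consumers$bite_force_mn else NA_real_,
      cutting_force_mn = NA_real_
    ),
    tibble::tibble(
      name = network$resources$id,
      type = TRUE,
      mass_mg = NA_real_,
      bite_force_mn = NA_real_,
      cutting_force_mn = if ("cutting_force_mn" %in% names(network$resources))
        network$resources$cutting_force_mn else NA_real_
    )
  )
  edges <- data.frame(
    from = network$edges$consumer_id,
    to = network$edges$resource_id,
    weight = network$edges$weight_mn
  )
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = as.data.frame(vertices))
}

#' Export a feasibility network as GraphML
#'
#' @param network A `feasibility_network`.
#' @param path Output `.graphml` path.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}
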