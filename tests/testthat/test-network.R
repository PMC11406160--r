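# Feasibility network construction and trait-matching threshold recovery.

# Consumers whose baseline bite forces are exactly the given values
# (prefactor = force, exponent = 0 keeps them temperature-invariant under
# any rule only via alpha; with exponent > 0 they respond to warming).
consumers_with_bites <- function(bites, exponent = 0) {
  consumer_table(
    id = paste0("c", seq_along(bites)),
    reference_mass_mg = rep(1, length(bites)),
    prefactor = bites,
    exponent = exponent
  )
}

test_that("edges exist exactly where bite force meets cutting force", {
  cons <- consumers_with_bites(c(20, 35))
  res <- resource_table(c("p1", "p2", "p3"), c(10, 25, 50))
  net <- build_network(cons, res, 20, identity_rule())
  expect_equal(
    dplyr::select(net$edges, consumer_id, resource_id),
    tibble::tibble(consumer_id = c("c1", "c2", "c2"),
                   resource_id = c("p1", "p1", "p2"))
  )
  expect_equal(consumer_degrees(net)$degree, c(1, 2))
  expect_true(all(net$edges$weight_mn >= 0))

  # exact tie: edge present with zero surplus
  tie <- build_network(consumers_with_bites(25), resource_table("p", 25),
                       20, identity_rule())
  expect_equal(nrow(tie$edges), 1)
  expect_equal(tie$edges$weight_mn, 0)

  # all bites below every cutting force: empty edge set
  empty <- build_network(consumers_with_bites(c(1, 2)),
                         resource_table("p", 50), 20, identity_rule())
  expect_equal(nrow(empty$edges), 0)

  expect_error(build_network(cons[0, ], res, 20, identity_rule()),
               class = "bitenet_usage_error")
})

test_that("edge sets match the brute-force oracle on random instances", {
  rule <- temp_size_rule(0.92, 20)
  withr::with_seed(31, {
    for (i in 1:30) {
      inst <- random_instance(sample(1:50, 1), sample(1:200, 1))
      tt <- stats::runif(1, 20, 30)
      net <- build_network(inst$consumers, inst$resources, tt, rule)
      expect_identical(
        edge_keys(net),
        oracle_edge_keys(inst$consumers, inst$resources, tt, rule)
      )
    }
  })
})

test_that("warming only ever removes edges (nested feasibility)", {
  rule <- temp_size_rule(0.9, 20)
  withr::with_seed(32, {
    for (i in 1:20) {
      inst <- random_instance(sample(2:10, 1), sample(5:40, 1))
      t1 <- stats::runif(1, 20, 24)
      t2 <- t1 + stats::runif(1, 0.5, 6)
      cold <- build_network(inst$consumers, inst$resources, t1, rule)
      hot <- build_network(inst$consumers, inst$resources, t2, rule)
      expect_true(all(edge_keys(hot) %in% edge_keys(cold)))
    }
  })
})

test_that("alpha = 1 gives the same network at every temperature", {
  withr::with_seed(33, inst <- random_instance(5, 30))
  base <- build_network(inst$consumers, inst$resources, 20, identity_rule())
  for (tt in c(20, 25, 31.5)) {
    layer <- build_network(inst$consumers, inst$resources, tt,
                           identity_rule())
    expect_identical(edge_keys(layer), edge_keys(base))
  }
})

test_that("threshold recovery brackets every true bite force", {
  cons <- consumers_with_bites(35)
  res <- resource_table(c("p1", "p2", "p3"), c(10, 25, 50))
  net <- build_network(cons, res, 20, identity_rule())
  iv <- infer_feasibility_threshold(net)
  expect_equal(iv$lower_mn, 25)
  expect_equal(iv$upper_mn, 50)

  # linked to everything / to nothing
  all_net <- build_network(consumers_with_bites(99), res, 20, identity_rule())
  iv_all <- infer_feasibility_threshold(all_net)
  expect_equal(iv_all$lower_mn, 50)
  expect_equal(iv_all$upper_mn, Inf)
  none_net <- build_network(consumers_with_bites(5), res, 20, identity_rule())
  iv_none <- infer_feasibility_threshold(none_net)
  expect_equal(iv_none$lower_mn, 0)
  expect_equal(iv_none$upper_mn, 10)

  # parameter recovery on random instances
  rule <- temp_size_rule(0.9, 20)
  withr::with_seed(34, {
    for (i in 1:40) {
      inst <- random_instance(sample(1:8, 1), sample(3:30, 1))
      tt <- stats::runif(1, 20, 28)
      net <- build_network(inst$consumers, inst$resources, tt, rule)
      iv <- infer_feasibility_threshold(net)
      bites <- bite_force_at_temperature(inst$consumers, tt, rule)$bite_force_mn
      expect_true(all(iv$lower_mn <= bites & bites < iv$upper_mn))
    }
  })
})

test_that("igraph agrees on degrees and edge counts (cross-check)", {
  withr::with_seed(35, inst <- random_instance(6, 40))
  net <- build_network(inst$consumers, inst$resources, 22,
                       temp_size_rule(0.9, 20))
  g <- as_igraph(net)
  ig_degrees <- igraph::degree(g)[net$consumers$id]
  expect_equal(unname(ig_degrees), consumer_degrees(net)$degree)
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_true(igraph::bipartite_mapping(g)$res)
})
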