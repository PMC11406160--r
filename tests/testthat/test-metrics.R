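# Degree, generality, connectance, robustness and link turnover.

two_by_three <- function() {
  cons <- consumer_table(c("c1", "c2"), c(1, 1),
                         prefactor = c(20, 35), exponent = 0)
  res <- resource_table(c("p1", "p2", "p3"), c(10, 25, 50))
  build_network(cons, res, 20, identity_rule())
}

test_that("degree and generality count accessible resources", {
  net <- two_by_three()
  expect_equal(consumer_degree(net, "c2"), 2)
  expect_equal(consumer_degree(net, "c1"), 1)
  expect_error(consumer_degree(net, "nope"), class = "bitenet_usage_error")
  expect_equal(generality(net), 1.5)

  # isolated consumer and empty network
  lonely <- build_network(
    consumer_table(c("c1", "c2"), c(1, 1), prefactor = c(20, 1), exponent = 0),
    resource_table(c("p1", "p2"), c(10, 15)), 20, identity_rule()
  )
  expect_equal(consumer_degree(lonely, "c2"), 0)
  empty <- build_network(
    consumer_table("c1", 1, prefactor = 1, exponent = 0),
    resource_table("p1", 50), 20, identity_rule()
  )
  expect_equal(generality(empty), 0)

  # complete bipartite: every degree equals the resource count
  full <- build_network(
    consumer_table(c("a", "b"), c(1, 1), prefactor = 99, exponent = 0),
    resource_table(paste0("p", 1:4), rep(5, 4)), 20, identity_rule()
  )
  expect_equal(consumer_degrees(full)$degree, c(4, 4))
  expect_equal(generality(full), 4)
  # weighted variant is bounded by the unweighted degree reading
  expect_lte(generality(full, weighted = TRUE), generality(full))
})

test_that("connectance is the realised link fraction, label-invariant", {
  net <- two_by_three()
  expect_equal(connectance(net), 3 / 6)
  relabeled <- net
  relabeled$consumers$id <- c("z9", "z1")
  relabeled$edges$consumer_id <-
    c("z9", "z1", "z1")[match(net$edges$consumer_id, c("c1", "c2"))[c(1, 2, 3)]]
  expect_equal(connectance(relabeled), connectance(net))
})

test_that("robustness reproduces the closed-form toy networks", {
  # single consumer, single resource, one edge: curve (0,1)-(1,0), R = 1/2
  net11 <- build_network(
    consumer_table("c1", 1, prefactor = 10, exponent = 0),
    resource_table("p1", 5), 20, identity_rule()
  )
  for (strat in c("random", "most-connected-first", "toughest-resource-first")) {
    r <- robustness(net11, strat, n_replicates = 7, seed = 2)
    expect_equal(r$curve$removal_fraction, c(0, 1))
    expect_equal(r$curve$surviving_fraction, c(1, 0))
    expect_equal(r$robustness_r, 0.5)
  }

  # one consumer linked to both of two resources: R = 3/4 by trapezoid
  net12 <- build_network(
    consumer_table("c1", 1, prefactor = 10, exponent = 0),
    resource_table(c("p1", "p2"), c(5, 6)), 20, identity_rule()
  )
  r <- robustness(net12, "random", n_replicates = 3, seed = 1)
  expect_equal(r$curve$surviving_fraction, c(1, 1, 0))
  expect_equal(r$robustness_r, 0.75)

  expect_error(robustness(net11, "destroy-everything"),
               class = "bitenet_usage_error")
})

test_that("an initially isolated consumer counts as lost from the start", {
  net <- build_network(
    consumer_table(c("c1", "c2"), c(1, 1), prefactor = c(10, 1), exponent = 0),
    resource_table(c("p1", "p2"), c(5, 6)), 20, identity_rule()
  )
  r <- robustness(net, "most-connected-first")
  expect_equal(r$curve$surviving_fraction[1], 1) # (0, 1) by convention
  expect_equal(r$curve$surviving_fraction[2], 0.5)
  expect_true(all(diff(r$curve$surviving_fraction) <= 0))
  expect_gte(r$robustness_r, 0)
  expect_lte(r$robustness_r, 1)
})

test_that("random-order robustness matches exhaustive enumeration", {
  withr::with_seed(41, {
    for (i in 1:5) {
      inst <- random_instance(sample(2:5, 1), sample(2:5, 1))
      net <- build_network(inst$consumers, inst$resources, 22,
                           temp_size_rule(0.95, 20))
      exact <- oracle_random_robustness(net)
      mc <- robustness(net, "random", n_replicates = 2000, seed = 7)
      expect_equal(mc$robustness_r, exact, tolerance = 0.02)
      # mean curve matches the pointwise enumeration mean too
      expect_equal(
        mc$curve$surviving_fraction[-1],
        rowMeans(vapply(all_permutations(net$resources$id),
                        function(o) oracle_curve(net, o),
                        numeric(nrow(net$resources)))),
        tolerance = 0.05
      )
    }
  })
})

test_that("deterministic strategies ignore replication and follow traits", {
  withr::with_seed(42, inst <- random_instance(4, 8))
  net <- build_network(inst$consumers, inst$resources, 21,
                       temp_size_rule(0.9, 20))
  a <- robustness(net, "toughest-resource-first", n_replicates = 1)
  b <- robustness(net, "toughest-resource-first", n_replicates = 1000)
  expect_identical(a$curve, b$curve)
  expect_identical(a$robustness_r, b$robustness_r)
  # toughest-first removes in descending cutting force
  expect_equal(
    resolve_order <- bitenet:::resolve_removal_order(net, "toughest-resource-first"),
    net$resources$id[order(-net$resources$cutting_force_mn)]
  )
})

test_that("consumer-side primary extinctions are available behind a flag", {
  net <- two_by_three()
  r <- robustness(net, "random", n_replicates = 50, seed = 3,
                  side = "consumers")
  # removing both consumers always strands p3 (nobody can cut it): it is
  # "extinct" from the start; p1 and p2 die with their last consumer
  expect_equal(r$curve$removal_fraction, c(0, 0.5, 1))
  expect_equal(r$curve$surviving_fraction[3], 0)
  expect_gte(r$robustness_r, 0)
  expect_lte(r$robustness_r, 1)
})

test_that("link turnover is the Jaccard dissimilarity of edge sets", {
  net <- two_by_three()
  expect_equal(link_turnover(net, net), 0)

  # hand-built layers: {ab, ac} vs {ab} -> 0.5
  a <- net
  a$edges <- tibble::tibble(consumer_id = c("c1", "c1"),
                            resource_id = c("p1", "p2"),
                            weight_mn = c(1, 1))
  b <- net
  b$edges <- tibble::tibble(consumer_id = "c1", resource_id = "p1",
                            weight_mn = 1)
  expect_equal(link_turnover(a, b), 0.5)

  # disjoint non-empty layers -> 1; two empty layers -> 0
  d <- net
  d$edges <- tibble::tibble(consumer_id = "c2", resource_id = "p3",
                            weight_mn = 1)
  expect_equal(link_turnover(a, d), 1)
  e1 <- net
  e1$edges <- e1$edges[0, ]
  expect_equal(link_turnover(e1, e1), 0)

  # nested layers obey the subset identity 1 - |hot|/|cold|
  rule <- temp_size_rule(0.9, 20)
  withr::with_seed(43, inst <- random_instance(5, 30))
  cold <- build_network(inst$consumers, inst$resources, 20, rule)
  hot <- build_network(inst$consumers, inst$resources, 26, rule)
  expect_equal(link_turnover(cold, hot),
               1 - nrow(hot$edges) / nrow(cold$edges))
})
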