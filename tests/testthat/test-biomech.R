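# Trait-level biomechanics: allometric scaling, the temperature-size rule,
# size-to-performance propagation, and Q10 thermal performance.

test_that("allometric scaling follows the power law and guards its domain", {
  mod <- allometric_model(prefactor = 10, exponent = 2 / 3)
  expect_equal(scale_trait(100, mod), 10 * 100^(2 / 3))
  expect_equal(scale_trait(100, mod), 215.44, tolerance = 1e-4)
  # unit mass returns the prefactor exactly; exponent 0 is size-independent
  expect_identical(scale_trait(1, allometric_model(5, 0.667)), 5)
  expect_equal(scale_trait(c(0.1, 7, 1234), allometric_model(3, 0)),
               rep(3, 3))
  # strictly increasing in mass for positive exponent
  masses <- sort(stats::runif(20, 0.01, 500))
  expect_true(all(diff(scale_trait(masses, mod)) > 0))
  expect_error(scale_trait(-2, mod), "-2", class = "bitenet_domain_error")
  expect_error(allometric_model(0, 1), class = "bitenet_domain_error")
})

test_that("temperature-size rule compounds geometrically per degree", {
  rule <- temp_size_rule(alpha = 0.9, reference_temperature = 20)
  expect_equal(apply_size_rule(100, 1, rule), 90)
  expect_identical(apply_size_rule(100, 0, rule), 100)
  expect_equal(apply_size_rule(100, 7, temp_size_rule(1)), 100)
  # monotone decreasing in delta_t when alpha < 1
  dts <- 0:10
  expect_true(all(diff(apply_size_rule(50, dts, rule)) < 0))
  expect_error(apply_size_rule(0, 1, rule), class = "bitenet_domain_error")
})

test_that("size change propagates to performance as alpha^(x * delta_t)", {
  # the worked single-degree family: 10% size loss means 3.45-10%
  # performance loss for length-, area- and volume-scaling traits
  expect_equal(propagate_performance_factor(0.9, 1), 0.9)
  expect_equal(propagate_performance_factor(0.9, 1 / 3), 0.9655,
               tolerance = 1e-4)
  expect_equal(propagate_performance_factor(0.9, 2 / 3), 0.9322,
               tolerance = 1e-4)
  decreases <- 100 * (1 - propagate_performance_factor(0.9, c(1 / 3, 2 / 3, 1)))
  expect_equal(round(min(decreases)), 3)
  expect_equal(max(decreases), 10)

  # single-degree identity against random parameters
  withr::with_seed(11, {
    alpha <- stats::runif(50, 0.01, 1)
    x <- stats::runif(50, 0, 1.5)
  })
  expect_equal(propagate_performance_factor(alpha, x, 1), alpha^x)

  # power laws distribute over the size rule: shrinking mass then scaling
  # the trait equals scaling the trait then applying the performance factor
  withr::with_seed(12, {
    for (i in 1:25) {
      a <- stats::runif(1, 0.5, 1)
      xp <- stats::runif(1, 0.1, 1.5)
      m <- stats::runif(1, 1, 200)
      dt <- stats::runif(1, 0, 8)
      mod <- allometric_model(stats::runif(1, 1, 20), xp)
      rule <- temp_size_rule(a, 20)
      expect_equal(
        scale_trait(apply_size_rule(m, dt, rule), mod),
        propagate_performance_factor(a, xp, dt) * scale_trait(m, mod)
      )
    }
  })
})

test_that("Q10 performance doubles per 10 degrees and plateaus", {
  m <- thermal_performance_model(q10 = 2, reference_temperature = 20,
                                 plateau_temperature = 40)
  expect_equal(thermal_performance(1, 30, m), 2)
  expect_identical(thermal_performance(3.5, 20, m), 3.5)
  expect_equal(thermal_performance(1, 21, m), 2^0.1)
  expect_equal(thermal_performance(1, 21, m), 1.0718, tolerance = 1e-4)
  # non-decreasing in temperature, exactly constant above the plateau,
  # continuous at the junction
  temps <- seq(10, 60, by = 0.5)
  vals <- thermal_performance(1, temps, m)
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals[temps >= 40] == thermal_performance(1, 40, m)))
  expect_error(thermal_performance_model(2, 30, 20),
               class = "bitenet_domain_error")
  expect_error(thermal_performance(-1, 25, m), class = "bitenet_domain_error")
})

test_that("both per-degree readings of Q10 = 2 are exposed", {
  r <- q10_per_degree(2)
  expect_equal(r$linear_pct_per_degree, 10)
  expect_equal(r$geometric_factor_per_degree, 2^0.1)
  expect_equal(r$geometric_pct_per_degree, 7.18, tolerance = 1e-3)
})

test_that("bite force at temperature composes the size rule and allometry", {
  cons <- consumer_table("c1", 100, allometry = allometric_model(10, 2 / 3))
  rule <- temp_size_rule(0.9, 20)
  at_ref <- bite_force_at_temperature(cons, 20, rule)
  expect_equal(at_ref$bite_force_mn, cons$baseline_bite_force_mn)
  warmed <- bite_force_at_temperature(cons, 21, rule)
  expect_equal(warmed$mass_mg, 90)
  expect_equal(warmed$bite_force_mn, 10 * 90^(2 / 3))
  expect_equal(warmed$bite_force_mn, 200.83, tolerance = 1e-4)
  # alpha = 1: baseline at any temperature
  frozen <- bite_force_at_temperature(cons, 37.2, temp_size_rule(1, 20))
  expect_equal(frozen$bite_force_mn, cons$baseline_bite_force_mn)
})
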