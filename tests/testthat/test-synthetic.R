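test_that("degenerate spec yields the constant target median", {
  spec <- route_spec("R", n = 10, target_median = 0.03, body_scale = 0,
                     contamination_rate = 0, seed = 1)
  expect_equal(generate_route(spec)$value, rep(0.03, 10))
})

test_that("generation is deterministic in the seed", {
  spec <- route_spec("R", n = 200, target_median = 0.036, body_scale = 0.6,
                     contamination_rate = 0.05, contamination_scale = 10,
                     seed = 7)
  expect_identical(generate_route(spec), generate_route(spec))
  spec2 <- spec
  spec2$seed <- 8L
  expect_false(identical(generate_route(spec)$value,
                         generate_route(spec2)$value))
})

test_that("spec validation rejects out-of-contract parameters", {
  expect_error(route_spec("R", 10, target_median = -1), "nonnegative")
  expect_error(route_spec("R", 10, 0.03, contamination_rate = 0.3), "0, 0.2")
  expect_error(route_spec("R", 10, 0.03, contamination_scale = 0.5), ">= 1")
  expect_error(route_spec("R", 0, 0.03), "positive integer")
  expect_error(route_spec("R", 10, 0.03,
                          trend_segments = list(c(0.5, 0.2, 1))),
               "trend_segments")
})

test_that("large-sample median recovers the generator-implied median, skew positive", {
  spec <- route_spec("R", n = 5000, target_median = 0.036, body_scale = 0.6,
                     contamination_rate = 0.05, contamination_scale = 10,
                     seed = 11)
  v <- generate_route(spec)$value
  # upward spikes shift the mixture median to the body quantile where
  # (1 - rate) * F(m) = 1/2; that is the generator-implied median
  implied <- 0.036 * exp(0.6 * qnorm(0.5 / 0.95))
  expect_lt(abs(median(v) - implied) / implied, 0.05)
  expect_gt(summary_stats(v)$skewness, 0)

  # without contamination the sample median sits on the target itself
  clean <- route_spec("R", n = 5000, target_median = 0.036, body_scale = 0.6,
                      seed = 11)
  vc <- generate_route(clean)$value
  expect_lt(abs(median(vc) - 0.036) / 0.036, 0.05)
})

test_that("all generated values are nonnegative across randomized specs", {
  set.seed(31)
  for (i in 1:15) {
    spec <- route_spec(
      "R", n = sample(20:150, 1),
      target_median = runif(1, 0, 0.1),
      body_scale = runif(1, 0, 1.5),
      contamination_rate = runif(1, 0, 0.2),
      contamination_scale = runif(1, 1, 20),
      trend_segments = list(c(0, 0.3, runif(1, -0.05, 0.05))),
      seed = i
    )
    expect_true(all(generate_route(spec)$value >= 0))
  }
})

test_that("uncontaminated trend-free medians converge to the target", {
  err <- vapply(c(200, 2000, 20000), function(n) {
    spec <- route_spec("R", n = n, target_median = 0.02, body_scale = 0.5,
                       seed = 5)
    abs(median(generate_route(spec)$value) - 0.02)
  }, numeric(1))
  expect_lt(err[3], 0.002)
  expect_lt(err[3], err[1])
})

test_that("contamination barely moves the MAD but inflates the SD", {
  base <- route_spec("R", n = 4000, target_median = 0.036, body_scale = 0.5,
                     contamination_rate = 0, contamination_scale = 10,
                     seed = 9)
  dirty <- base
  dirty$contamination_rate <- 0.05
  v0 <- generate_route(base)$value
  v1 <- generate_route(dirty)$value
  expect_lt(abs(mad_raw(v1) - mad_raw(v0)) / mad_raw(v0), 0.10)
  expect_gt(abs(sample_sd(v1) - sample_sd(v0)) / sample_sd(v0), 0.25)
})

test_that("study generation derives independent reproducible route streams", {
  study <- six_route_study()
  d1 <- generate_study(study, seed = 3)
  d2 <- generate_study(study, seed = 3)
  expect_identical(d1, d2)
  counts <- dplyr::count(d1, route_id)
  expect_equal(counts$n[match(c("X1", "X2", "X3", "Y1", "Y2", "Y3"),
                              counts$route_id)],
               c(156L, 83L, 102L, 70L, 70L, 82L))
  # changing the study seed changes every route
  d3 <- generate_study(study, seed = 4)
  expect_false(any(tapply(d1$value == d3$value, d1$route_id, all)))

  empty <- generate_study(study_spec(list()), seed = 1)
  expect_equal(nrow(empty), 0)
  expect_error(study_spec(list(route_spec("A", 5, 0.01),
                               route_spec("A", 5, 0.02))),
               "unique")
})

test_that("the preset matches the heavy-tailed study structure", {
  d <- generate_study(six_route_study(), seed = 1)
  s <- route_summary(d)
  expect_true(all(s$skewness > 0))
  expect_true(all(s$minimum >= 0))
  # the largest route has clipped low-side zeros and high spikes
  x1 <- s[s$route_id == "X1", ]
  expect_equal(x1$minimum, 0)
  expect_gt(x1$maximum / x1$median, 5)
})
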