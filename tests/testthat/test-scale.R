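test_that("point scale estimators match hand-computed values", {
  x <- c(1, 2, 3, 4, 100)
  expect_equal(mean_abs_dev(x), 31.2)
  expect_equal(mean_abs_dev(c(0, 4)), 2)
  expect_equal(sample_sd(c(0, 1, 2, 3, 4)), sqrt(2.5))
  expect_equal(sample_sd(c(0, 4)), sqrt(8))
  expect_equal(mad_raw(x), 1)
  expect_equal(mad_raw(c(1, 1, 2, 2, 4, 7)), 1)
  expect_equal(sir(c(1, 2, 3, 4, 5)), 1)
  expect_equal(sir(c(1, 2, 3, 4)), 1)
  expect_equal(lms_scale(x), 1)
  expect_equal(lms_scale(c(0, 10, 11, 12, 13, 100)), 1.5)
  for (f in list(mean_abs_dev, mad_raw, sir, lms_scale)) {
    expect_equal(f(rep(3, 6)), 0)
  }
  expect_error(sample_sd(3), "at least 2")
})

test_that("biweight midvariance matches direct evaluation and its c->inf limit", {
  x <- c(0, 1, 2, 3, 4)
  # frozen from direct evaluation with u = (-2,-1,0,1,2)/9
  expect_equal(biweight_midvariance(x, c = 9), 2.2970638, tolerance = 1e-6)
  expect_equal(sbi_scale(x, 9), sqrt(biweight_midvariance(x, 9)))
  expect_equal(biweight_midvariance(rep(2, 5), 9), 0)
  expect_error(biweight_midvariance(x, c = 0), "positive")

  set.seed(13)
  for (i in 1:10) {
    y <- rlnorm(sample(5:50, 1))
    m <- median(y)
    limit <- mean((y - m)^2)
    expect_equal(biweight_midvariance(y, c = 1e6), limit,
                 tolerance = 1e-4)
  }
})

test_that("subrange estimator matches normalizer arithmetic and a brute-force oracle", {
  x <- c(1, 2, 3, 4, 100)
  expect_equal(subrange_scale(x, 0.2), 2 / (qnorm(0.75) - qnorm(0.55)))
  expect_equal(subrange_scale(x, 0.2), 3.645, tolerance = 1e-3)
  expect_equal(subrange_scale(x, 0.45), 3 / (qnorm(0.75) - qnorm(0.30)))
  expect_equal(subrange_scale(x, 0.45), 2.502, tolerance = 1e-3)
  expect_equal(subrange_scale(rep(2, 9), 0.3), 0)
  expect_error(subrange_scale(x, 0.6), "0, 0.5")

  raw_oracle <- function(x, h) {
    x <- sort(x)
    best <- Inf
    for (i in seq_len(length(x) - h)) {
      best <- min(best, x[i + h] - x[i])
    }
    best
  }
  set.seed(14)
  for (n in c(5, 9, 14, 22, 30)) {
    x <- runif(n, 0, 50)
    for (a in c(0.1, 0.25, 0.4)) {
      h <- floor(a * n) + 1
      expect_equal(subrange_scale(x, a),
                   raw_oracle(x, h) / (qnorm(0.75) - qnorm(0.75 - a)))
    }
  }
})

test_that("all seven estimators are shift-invariant and scale-equivariant", {
  set.seed(15)
  estimators <- list(
    mad_mean = mean_abs_dev,
    sd = sample_sd,
    mad = mad_raw,
    sir = sir,
    sbi = function(v) sbi_scale(v, 9),
    cn = function(v) subrange_scale(v, 0.25),
    lms = lms_scale
  )
  for (i in 1:15) {
    x <- rlnorm(sample(8:60, 1))
    lambda <- runif(1, -5, 5)
    shift <- runif(1, -10, 10)
    for (nm in names(estimators)) {
      f <- estimators[[nm]]
      s <- f(x)
      expect_gte(s, 0)
      expect_equal(f(x + shift), s, tolerance = 1e-9,
                   label = paste(nm, "shift"))
      expect_equal(f(lambda * x), abs(lambda) * s, tolerance = 1e-9,
                   label = paste(nm, "scale"))
    }
  }
})

test_that("unscaled MAD has expectation near (2/3) sigma for normal data", {
  set.seed(16)
  x <- rnorm(2e5, sd = 3)
  expect_equal(mad_raw(x) / 3, 2 / 3, tolerance = 0.02)
})

test_that("robust estimators resist massive contamination where the SD explodes", {
  set.seed(17)
  x <- rnorm(200, 10, 1)
  # moderate contamination: high-breakdown estimators move < 50%
  x_mid <- x
  x_mid[1:40] <- 1e6 # 20% replaced
  expect_lt(abs(mad_raw(x_mid) - mad_raw(x)) / mad_raw(x), 0.5)
  expect_lt(abs(lms_scale(x_mid) - lms_scale(x)) / lms_scale(x), 0.5)
  # just below the 50% breakdown point: biased but still bounded, while
  # the SD is inflated by orders of magnitude
  x_bad <- x
  x_bad[1:80] <- 1e6 # 40% replaced
  expect_lt(mad_raw(x_bad) / mad_raw(x), 5)
  expect_lt(lms_scale(x_bad) / lms_scale(x), 5)
  expect_gt(sample_sd(x_bad) / sample_sd(x), 1e3)
})

test_that("route_scale_table and curves mirror the normal-consistency oracle", {
  set.seed(18)
  d <- one_route(rnorm(1e5))
  tab <- route_scale_table(d)
  expect_equal(tab$mad, qnorm(0.75), tolerance = 0.02)
  expect_equal(tab$sir, qnorm(0.75), tolerance = 0.02)
  expect_equal(subrange_scale(d$value, 0.25), 1, tolerance = 0.1)

  curves <- route_scale_curves(one_route(c(rlnorm(50), 40, 60)),
                               c_grid = c(3, 9, 15),
                               alpha_grid = c(0.1, 0.25, 0.4))
  expect_setequal(unique(curves$family), c("sbi", "cn"))
  expect_true(all(curves$estimate >= 0))

  const <- route_scale_table(one_route(rep(2, 10)))
  expect_equal(unlist(const[, c("mad_mean", "sd", "mad", "sir", "lms")]),
               c(mad_mean = 0, sd = 0, mad = 0, sir = 0, lms = 0))
})

test_that("contaminated series order the estimators sd > mad_mean > mad", {
  set.seed(19)
  x <- rlnorm(300, log(0.03), 0.4)
  x[1:15] <- x[1:15] * 12
  tab <- route_scale_table(one_route(x))
  expect_gt(tab$sd, tab$mad_mean)
  expect_gt(tab$mad_mean, tab$mad)
})
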