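test_that("pooled share density normalizes and has the pooled mean and variance", {
  d <- resource_dist(mean_x = 4, theta = 1, group_size = 4)
  total <- integrate(function(x) pooled_share_density(x, d), 0, Inf,
                     rel.tol = 1e-12)$value
  expect_equal(total, 1, tolerance = 1e-8)
  m1 <- integrate(function(x) x * pooled_share_density(x, d), 0, Inf,
                  rel.tol = 1e-12)$value
  m2 <- integrate(function(x) x^2 * pooled_share_density(x, d), 0, Inf,
                  rel.tol = 1e-12)$value
  expect_equal(m1, 4, tolerance = 1e-6)
  expect_equal(m2 - m1^2, 4 * 1 / 4, tolerance = 1e-6)

  # shape > 1 forces zero density at the origin
  expect_identical(pooled_share_density(0, resource_dist(4, 1, 1)), 0)

  # pooling reduces per-capita variance exactly as 1/N
  for (N in c(2L, 5L, 12L)) {
    dN <- resource_dist(4, 1, N)
    expect_equal((dN$shape * dN$scale^2) / (d$shape * d$scale^2 * 4), 1 / N)
  }
})

test_that("pooled share cdf matches the Erlang closed form and is monotone", {
  d1 <- resource_dist(4, 1, 1)  # integer shape 4: Erlang
  expect_equal(pooled_share_cdf(1, d1), erlang_cdf(1, 4), tolerance = 1e-12)
  expect_equal(pooled_share_cdf(1, d1), 0.01899, tolerance = 1e-4)
  expect_identical(pooled_share_cdf(0, d1), 0)
  expect_equal(pooled_share_cdf(1e4, d1), 1)

  set.seed(11)
  for (i in 1:20) {
    d <- resource_dist(runif(1, 0.5, 8), exp(runif(1, log(0.1), log(16))),
                       sample(1:8, 1))
    xs <- sort(runif(10, 0, 20))
    expect_true(all(diff(pooled_share_cdf(xs, d)) >= 0))
  }
})

test_that("coefficient of variation spans the documented range and handles zero variance", {
  expect_equal(round(coefficient_of_variation(4, 0.1), 2), 0.16)
  expect_identical(coefficient_of_variation(4, 16), 2)
  expect_identical(coefficient_of_variation(4, 0), 0)
  # consistency with the mean-variance relation sigma^2 = mean_x * theta
  expect_equal(coefficient_of_variation(3, 5), sqrt(3 * 5) / 3)
  expect_error(coefficient_of_variation(0, 1), "positive")
  expect_error(coefficient_of_variation(-2, 1), "positive")
})

test_that("sampling is reproducible and converges to the analytic law", {
  d <- resource_dist(4, 1, 4)
  s1 <- sample_pooled_shares(1e5, d, seed = 7)
  s2 <- sample_pooled_shares(1e5, d, seed = 7)
  expect_identical(s1, s2)

  # CLT bounds at ~3 standard errors for mean and variance
  expect_lt(abs(mean(s1) - 4), 0.02)
  expect_lt(abs(var(s1) - 1), 0.05)

  # empirical CDF converges to the analytic cdf (Kolmogorov-Smirnov distance)
  ks <- max(abs(ecdf(s1)(s1) - pooled_share_cdf(s1, d)))
  expect_lt(ks, 0.01)

  # N = 1 sampling is plain Gamma sampling
  d1 <- resource_dist(4, 1, 1)
  ref <- local({set.seed(99); rgamma(2e4, shape = 4, scale = 1)})
  p <- suppressWarnings(
    ks.test(sample_pooled_shares(2e4, d1, seed = 3), ref)$p.value)
  expect_gt(p, 0.01)
})

test_that("tiny item sizes route to the deterministic point-mass limit", {
  d <- resource_dist(4, 1e-9, 3)
  expect_true(d$deterministic)
  expect_identical(pooled_share_cdf(c(0, 3.999, 4, 5), d), c(0, 0, 1, 1))
  expect_identical(sample_pooled_shares(10, d, seed = 1), rep(4, 10))
  expect_error(pooled_share_density(1, d), "point mass")
  # at the default threshold itself the Gamma law still applies
  expect_false(resource_dist(4, 1e-6, 3)$deterministic)
})

test_that("resource distribution inputs are validated", {
  expect_error(resource_dist(-1, 1, 1))
  expect_error(resource_dist(4, -0.5, 1))
  expect_error(resource_dist(4, 1, 2.5))
  d <- resource_dist(4, 1, 1)
  expect_error(pooled_share_cdf(-1, d), "nonnegative")
  expect_error(pooled_share_density(-1, d), "nonnegative")
  expect_error(pooled_share_density(1, list(shape = 4)), "resource_dist")
})
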