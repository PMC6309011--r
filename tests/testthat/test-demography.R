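test_that("step mortality kills below the threshold and spares the boundary", {
  expect_identical(mortality_probability(0.5, std), 1)
  expect_identical(mortality_probability(2, std), 0.1)
  expect_identical(mortality_probability(1, std), 0.1)  # boundary survives
  expect_error(mortality_probability(-1, std), "nonnegative")
})

test_that("mean mortality combines starvation risk and baseline mortality", {
  sol <- group_strategy("egalitarian", 1)
  # Erlang closed form: C + (1 - C) * M_b at shape 4
  C <- erlang_cdf(1, 4)
  expect_equal(mean_mortality(sol, 4, 1, std), C + (1 - C) * 0.1,
               tolerance = 1e-12)
  expect_equal(mean_mortality(sol, 4, 1, std), 0.1171, tolerance = 1e-4)

  # abundant resources: threshold almost surely crossed
  expect_equal(mean_mortality(sol, 1000, 1, std), 0.1, tolerance = 1e-6)

  # closed form equals direct quadrature of density * step mortality
  set.seed(21)
  for (i in 1:8) {
    mean_x <- runif(1, 0.5, 8)
    theta <- exp(runif(1, log(0.2), log(8)))
    N <- sample(1:8, 1)
    strat <- group_strategy("eusocial", N)
    d <- resource_dist(mean_x, theta, N)
    hi <- qgamma(1e-15, d$shape, scale = d$scale, lower.tail = FALSE)
    # quadrature split at the survival threshold where the step sits
    direct <- integrate(function(x)
      pooled_share_density(x, d) * mortality_probability(x, std),
      0, std$o_M, rel.tol = 1e-12, subdivisions = 500L)$value +
      integrate(function(x)
        pooled_share_density(x, d) * mortality_probability(x, std),
        std$o_M, hi, rel.tol = 1e-12, subdivisions = 500L)$value
    expect_equal(mean_mortality(strat, mean_x, theta, std), direct,
                 tolerance = 1e-8)
  }

  # strictly decreasing in mean resources
  mus <- sapply(c(0.5, 1, 2, 4, 8), function(m)
    mean_mortality(group_strategy("egalitarian", 4), m, 2, std))
  expect_true(all(diff(mus) < 0))
})

test_that("fertility is sigmoid with the documented asymptote and inflection", {
  expect_identical(fertility(0, std), 0)
  expect_equal(fertility(1e6, std), std$F_max, tolerance = 1e-9)
  xi <- std$c0 * std$F_max * log(2)
  expect_equal(fertility(xi, std), std$F_max / 4, tolerance = 1e-12)

  # increasing; convex below the inflection, concave above (second differences)
  h <- 1e-3
  d2 <- function(x) (fertility(x + h, std) - 2 * fertility(x, std) +
                       fertility(x - h, std)) / h^2
  expect_gt(d2(xi * 0.5), 0)
  expect_lt(d2(xi * 1.5), 0)
  xr <- seq(0.1, 40, length.out = 50)
  expect_true(all(diff(fertility(xr, std)) > 0))
  expect_error(fertility(-1, std), "nonnegative")
})

test_that("eusocial natality reduces to egalitarian natality for solitaries", {
  set.seed(31)
  for (i in 1:10) {
    mean_x <- runif(1, 0.5, 10)
    theta <- exp(runif(1, log(0.1), log(16)))
    expect_equal(
      natality(group_strategy("eusocial", 1), mean_x, theta, std),
      natality(group_strategy("egalitarian", 1), mean_x, theta, std),
      tolerance = 1e-10)
  }
})

test_that("natality approaches the point-mass limit as variance vanishes", {
  for (N in c(1L, 4L)) {
    for (mean_x in c(2, 5)) {
      egal <- natality(group_strategy("egalitarian", N), mean_x, 1e-5, std)
      eus <- natality(group_strategy("eusocial", N), mean_x, 1e-5, std)
      x_r <- max(0, mean_x - std$o_M)
      expect_equal(egal, fertility(x_r, std), tolerance = 1e-3)
      expect_equal(eus, fertility(N * x_r, std) / N, tolerance = 1e-3)
    }
  }
  # below theta_min the limit is exact
  expect_identical(natality(group_strategy("egalitarian", 2), 3, 1e-9, std),
                   fertility(2, std))
})

test_that("natality is bounded, increasing in resources, and Jensen-consistent", {
  # eusocial per-capita natality never exceeds F_max / N
  for (N in c(2L, 8L, 20L))
    expect_lt(natality(group_strategy("eusocial", N), 50, 4, std),
              std$F_max / N)

  for (type in c("egalitarian", "eusocial")) {
    phis <- sapply(c(1, 2, 4, 8), function(m)
      natality(group_strategy(type, 6), m, 2, std))
    expect_true(all(diff(phis) > 0))
  }

  # variance reduction hurts convex payoffs: with the mean in the convex
  # region of F, egalitarian natality falls as groups grow...
  phi_egal <- sapply(c(1L, 2L, 4L, 8L), function(N)
    natality(group_strategy("egalitarian", N), 3, 4, std))
  expect_true(all(diff(phi_egal) < 0))
  # ...while the same variance reduction lowers mortality
  mu_N <- sapply(c(1L, 2L, 4L, 8L), function(N)
    mean_mortality(group_strategy("egalitarian", N), 3, 4, std))
  expect_true(all(diff(mu_N) < 0))
})

test_that("lifetime reproductive success is natality over mortality", {
  strat <- group_strategy("eusocial", 4)
  psi <- lifetime_reproductive_success(strat, 4, 1, std)
  expect_equal(psi, natality(strat, 4, 1, std) /
                 mean_mortality(strat, 4, 1, std))

  # one-period lifetime: Psi equals natality
  p1 <- model_params(F_max = 3, c0 = 4, M_b = 1, o_M = 0)
  expect_equal(lifetime_reproductive_success(strat, 4, 1, p1),
               natality(strat, 4, 1, p1))

  psis <- sapply(c(1.5, 2, 3, 5, 8), function(m)
    lifetime_reproductive_success(strat, m, 2, std))
  expect_true(all(diff(psis) > 0))
})
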