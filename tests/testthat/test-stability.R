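test_that("subordinate inclusive fitness is linear in relatedness and equals N at equilibrium", {
  theta <- 1
  eq <- equilibrium_requirement(group_strategy("eusocial", 10), theta, std)
  xb <- eq$xbar_N
  expect_identical(inclusive_fitness_subordinate(10, theta, 0, std, xb), 0)
  f1 <- inclusive_fitness_subordinate(10, theta, 0.3, std, xb)
  f2 <- inclusive_fitness_subordinate(10, theta, 0.6, std, xb)
  expect_equal(f2, 2 * f1, tolerance = 1e-12)
  # at the resident equilibrium and r = 1 the dominant's lifetime output is N
  expect_equal(inclusive_fitness_subordinate(10, theta, 1, std, xb), 10,
               tolerance = 1e-6)
  expect_error(inclusive_fitness_subordinate(1, theta, 0.5, std, xb),
               "at least 2")
})

test_that("defector inclusive fitness is affine with the documented intercept and slope", {
  theta <- 1
  xb <- 2.1
  sol_psi <- lifetime_reproductive_success(group_strategy("eusocial", 1),
                                           xb, theta, std)
  # intercept: own offspring weighted by parent-offspring relatedness 1/2
  expect_equal(inclusive_fitness_defector(2, theta, 0, std, xb),
               0.5 * sol_psi, tolerance = 1e-12)
  # the Hamilton-rule normalization is recovered with r_self = 1
  expect_equal(inclusive_fitness_defector(2, theta, 0, std, xb, r_self = 1),
               sol_psi, tolerance = 1e-12)
  # slope at N = 2: one remaining (solitary) relative
  gap <- inclusive_fitness_defector(2, theta, 1, std, xb) -
    inclusive_fitness_defector(2, theta, 0, std, xb)
  expect_equal(gap, sol_psi, tolerance = 1e-12)
  expect_error(inclusive_fitness_defector(1, theta, 0.5, std, xb),
               "at least 2")
})

test_that("minimum relatedness solves the inclusive-fitness balance", {
  for (theta in c(0.5, 2)) {
    st <- minimum_relatedness(theta, std)
    expect_true(st$defined)
    expect_gt(st$N, 1)
    # closed-form linear solve equals an independent bisection root
    g <- function(r) inclusive_fitness_defector(st$N, theta, r, std, st$xbar_N) -
      inclusive_fitness_subordinate(st$N, theta, r, std, st$xbar_N)
    expect_equal(st$r_min, uniroot(g, c(0, 1), tol = 1e-12)$root,
                 tolerance = 1e-10)
    # balance at r_min, stability above, instability below
    expect_equal(st$phi_sub_at_rmin, st$phi_def_at_rmin, tolerance = 1e-8)
    eps <- 1e-3
    expect_gt(inclusive_fitness_subordinate(st$N, theta, st$r_min + eps, std,
                                            st$xbar_N),
              inclusive_fitness_defector(st$N, theta, st$r_min + eps, std,
                                         st$xbar_N))
    expect_lt(inclusive_fitness_subordinate(st$N, theta, st$r_min - eps, std,
                                            st$xbar_N),
              inclusive_fitness_defector(st$N, theta, st$r_min - eps, std,
                                         st$xbar_N))
  }
})

test_that("groups no relatedness can stabilize are flagged, with diagnostics kept", {
  # far above the optimum the solitary option dominates any kin benefit
  st <- minimum_relatedness(0.25, std, N = 29)
  expect_true(st$feasible)
  expect_false(st$defined)
  expect_gt(st$r_min, 1)  # raw balance point retained for diagnostics
  # infeasible strategies propagate as infeasible, not as an error
  st_inf <- minimum_relatedness(2, std, N = 31)
  expect_false(st_inf$feasible)
  expect_false(st_inf$defined)
})

test_that("invasion fitness is one on the diagonal and tracks resource efficiency", {
  theta <- 2
  res <- group_strategy("eusocial", 8)
  self <- invasion_fitness(res, res, theta, std)
  expect_equal(self$psi, 1, tolerance = 1e-6)

  # a solitary invader fails against an efficient eusocial resident
  opt <- optimal_group_size("eusocial", theta, std)
  inv <- invasion_fitness(group_strategy("egalitarian", 1),
                          group_strategy("eusocial", opt$N_opt), theta, std)
  expect_lt(inv$psi, 1)

  # Psi > 1 exactly when the invader needs fewer resources than the resident
  strategies <- list(group_strategy("egalitarian", 1),
                     group_strategy("egalitarian", 4),
                     group_strategy("eusocial", 4),
                     group_strategy("eusocial", 12))
  xbar <- vapply(strategies, function(s)
    equilibrium_requirement(s, theta, std)$xbar_N, numeric(1))
  psi <- pairwise_invasibility_grid(strategies, theta, std)
  for (i in seq_along(strategies)) {
    for (j in seq_along(strategies)) {
      if (i == j) next
      expect_identical(psi[i, j] > 1, xbar[i] < xbar[j])
    }
  }
  # diagonal is one, and the most efficient strategy is uninvadable
  expect_equal(unname(diag(psi)), rep(1, 4), tolerance = 1e-6)
  best <- which.min(xbar)
  expect_true(all(psi[, best] <= 1 + 1e-6))
  # degenerate one-strategy grid
  one <- pairwise_invasibility_grid(strategies[1], theta, std)
  expect_equal(dim(one), c(1L, 1L))
  expect_equal(one[1, 1], 1, tolerance = 1e-6)
  # infeasible residents raise an informative error
  expect_error(invasion_fitness(res, group_strategy("eusocial", 31), theta,
                                std), "no equilibrium")
})
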