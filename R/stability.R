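#' Inclusive fitness of a eusocial subordinate
#'
#' A subordinate in a eusocial group of size N never reproduces directly; its
#' inclusive fitness is its relatedness-weighted share of the dominant's
#' reproduction over its own lifetime:
#' `Phi_sub = r * N * phi_eusocial(N, xbar_pop) / mu(N, xbar_pop)`, where
#' `N * phi_eusocial` is the fertility of the dominant and `1/mu` the
#' subordinate's life expectancy. Linear and homogeneous in `r`.
#'
#' @section Relatedness accounting:
#' Inclusive fitness is counted in gene-copy units: every offspring produced
#' anywhere is weighted by the focal individual's relatedness to *that
#' offspring*. The coefficient `r` is therefore the subordinate's relatedness
#' to the offspring of its dominant. In the companion
#' [inclusive_fitness_defector()], the defector's own offspring carry the
#' weight `r_self` (default 1/2, the parent-offspring relatedness of an
#' outbred diploid) in the same currency. Setting `r_self = 1` instead
#' treats `r` as a Hamilton-rule weight relative to own reproduction.
#'
#' @param N Group size, at least 2 (a solitary has no subordinates).
#' @param theta Mean resource item size.
#' @param r Coefficient of relatedness to the dominant's offspring, in
#'   `[0, 1]`.
#' @param params A [model_params()] object.
#' @param xbar_pop Mean per-capita resource level set by the resident
#'   population (normally the resident's equilibrium `xbar_N`).
#' @return The inclusive fitness value.
#' @export
inclusive_fitness_subordinate <- function(N, theta, r, params, xbar_pop) {
  assert_params(params)
  stopifnot(is.numeric(N), length(N) == 1L, N == round(N),
            is.numeric(r), length(r) == 1L, r >= 0, r <= 1,
            is.numeric(xbar_pop), length(xbar_pop) == 1L, xbar_pop > 0)
  if (N < 2) stop("`N` must be at least 2: solitaries have no subordinates",
                  call. = FALSE)
  eus <- group_strategy("eusocial", N)
  r * N * natality(eus, xbar_pop, theta, params) /
    mean_mortality(eus, xbar_pop, theta, params)
}

#' Inclusive fitness of a defecting subordinate
#'
#' A subordinate that leaves its group of size N forages solitarily at the
#' resource level `xbar_pop` set by the resident population, gaining direct
#' reproduction but leaving its related group one helper short:
#' `Phi_def = r_self * Psi_solitary(xbar_pop) + r * (N - 1) *
#' phi_eusocial(N - 1, xbar_pop) / mu(N - 1, xbar_pop)`. Affine in `r` with
#' slope `(N - 1)` times the reduced group's per-capita lifetime reproductive
#' success; the intercept is the solitary lifetime reproductive success
#' weighted by the defector's relatedness `r_self` to its own offspring (see
#' the accounting section of [inclusive_fitness_subordinate()]).
#'
#' @inheritParams inclusive_fitness_subordinate
#' @param r_self Relatedness of an individual to its own offspring, weighting
#'   the direct-reproduction term; 1/2 for an outbred diploid. `r_self = 1`
#'   recovers the Hamilton-rule normalization in which `r` is measured
#'   relative to own reproduction.
#' @return The inclusive fitness value.
#' @export
inclusive_fitness_defector <- function(N, theta, r, params, xbar_pop,
                                       r_self = 0.5) {
  assert_params(params)
  stopifnot(is.numeric(N), length(N) == 1L, N == round(N),
            is.numeric(r), length(r) == 1L, r >= 0, r <= 1,
            is.numeric(xbar_pop), length(xbar_pop) == 1L, xbar_pop > 0,
            is.numeric(r_self), length(r_self) == 1L, r_self > 0, r_self <= 1)
  if (N < 2) stop("`N` must be at least 2: solitaries cannot defect",
                  call. = FALSE)
  solitary <- lifetime_reproductive_success(
    group_strategy("eusocial", 1L), xbar_pop, theta, params)
  remaining <- group_strategy("eusocial", N - 1L)
  r_self * solitary +
    r * (N - 1) * natality(remaining, xbar_pop, theta, params) /
      mean_mortality(remaining, xbar_pop, theta, params)
}

#' Minimum relatedness stabilizing a eusocial group
#'
#' The smallest coefficient of relatedness at which a subordinate's inclusive
#' fitness in the group at least matches that of defecting to solitary life,
#' evaluated at the resident equilibrium resource level `xbar_N`. Both
#' inclusive-fitness expressions are affine in `r`, so the balance point has
#' the closed form
#' `r_min = r_self * D(1) / (N * D(N) - (N - 1) * D(N - 1))`, where `D(k)`
#' is the per-capita eusocial lifetime reproductive success of a size-k
#' group at `xbar_N` (and `D(1)` the solitary value). Above `r_min` staying
#' beats defecting; below it the group is unstable.
#'
#' @inheritParams inclusive_fitness_defector
#' @param theta Mean resource item size.
#' @param params A [model_params()] object.
#' @param N Group size, at least 2; defaults to the eusocial optimal group
#'   size at `theta`.
#' @param N_max Group-size search cap passed to [optimal_group_size()] when
#'   `N` is `NULL`.
#' @return An object of class `"stability_result"`: a list with `N`, `theta`,
#'   `r_min`, `phi_sub_at_rmin`, `phi_def_at_rmin`, `xbar_N`, `defined`
#'   (`FALSE` when no `r` in `[0, 1]` stabilizes the group; the raw `r_min`
#'   is retained for diagnostics) and `feasible`.
#' @examples
#' minimum_relatedness(theta = 0.25, params = model_params())
#' @export
minimum_relatedness <- function(theta, params, N = NULL, N_max = NULL,
                                r_self = 0.5) {
  assert_params(params)
  if (is.null(N)) {
    N <- optimal_group_size("eusocial", theta, params, N_max = N_max)$N_opt
    if (N < 2)
      return(structure(
        list(N = N, theta = theta, r_min = NA_real_,
             phi_sub_at_rmin = NA_real_, phi_def_at_rmin = NA_real_,
             xbar_N = NA_real_, defined = FALSE, feasible = TRUE),
        class = "stability_result"))
  }
  stopifnot(N == round(N), N >= 2)
  N <- as.integer(N)
  eq <- equilibrium_requirement(group_strategy("eusocial", N), theta, params)
  if (!eq$feasible)
    return(structure(
      list(N = N, theta = theta, r_min = NA_real_,
           phi_sub_at_rmin = NA_real_, phi_def_at_rmin = NA_real_,
           xbar_N = NA_real_, defined = FALSE, feasible = FALSE),
      class = "stability_result"))
  xbar_N <- eq$xbar_N
  D <- function(k) lifetime_reproductive_success(
    group_strategy("eusocial", k), xbar_N, theta, params)
  D1 <- D(1L); DN <- D(N); DNm1 <- D(N - 1L)
  denom <- N * DN - (N - 1) * DNm1
  r_min <- if (denom > 0) r_self * D1 / denom else NA_real_
  defined <- is.finite(r_min) && r_min >= 0 && r_min <= 1
  structure(
    list(N = N, theta = theta, r_min = r_min,
         phi_sub_at_rmin = if (defined) r_min * N * DN else NA_real_,
         phi_def_at_rmin = if (defined) r_self * D1 + r_min * (N - 1) * DNm1
                           else NA_real_,
         xbar_N = xbar_N, defined = defined, feasible = TRUE),
    class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  if (!x$feasible) {
    cat(sprintf("<stability_result> N = %d, theta = %g: infeasible strategy\n",
                x$N, x$theta))
  } else if (x$defined) {
    cat(sprintf("<stability_result> N = %d, theta = %g: r_min = %.4g\n",
                x$N, x$theta, x$r_min))
  } else {
    cat(sprintf(
      "<stability_result> N = %d, theta = %g: no stabilizing r in [0, 1] (raw %.4g)\n",
      x$N, x$theta, x$r_min))
  }
  invisible(x)
}

#' Minimum relatedness across an environmental-variance grid
#'
#' Convenience driver: for each item size, finds the eusocial optimal group
#' size and the minimum relatedness stabilizing it.
#'
#' @inheritParams inclusive_fitness_defector
#' @param theta_grid Positive, strictly increasing grid of item sizes.
#' @param params A [model_params()] object.
#' @param N_max Group-size search cap (see [optimal_group_size()]).
#' @return A data frame with columns `theta`, `N_opt`, `r_min`, `defined`.
#' @examples
#' rmin_sweep(c(0.25, 1, 4), model_params())
#' @export
rmin_sweep <- function(theta_grid, params, N_max = NULL, r_self = 0.5) {
  stopifnot(length(theta_grid) >= 1, all(theta_grid > 0),
            !is.unsorted(theta_grid, strictly = TRUE))
  rows <- lapply(theta_grid, function(theta) {
    opt <- optimal_group_size("eusocial", theta, params, N_max = N_max)
    st <- if (opt$N_opt >= 2)
      minimum_relatedness(theta, params, N = opt$N_opt, r_self = r_self)
    else
      list(r_min = NA_real_, defined = FALSE)
    data.frame(theta = theta, N_opt = opt$N_opt, r_min = st$r_min,
               defined = st$defined)
  })
  do.call(rbind, rows)
}

#' Invasion fitness of a rare strategy
#'
#' Lifetime reproductive success `Psi` of a rare invader strategy in an
#' infinitely large resident population at the resident's equilibrium
#' resource level: `Psi(invader, resident) = phi_invader(xbar_resident) /
#' mu_invader(xbar_resident)`. The resident against itself has `Psi = 1`;
#' `Psi > 1` means the invader grows.
#'
#' @param invader,resident [group_strategy()] objects.
#' @param theta Mean resource item size.
#' @param params A [model_params()] object.
#' @return A list of class `"invasion_cell"` with `invader`, `resident`,
#'   `theta`, `xbar_resident` and `psi`.
#' @export
invasion_fitness <- function(invader, resident, theta, params) {
  assert_strategy(invader)
  assert_strategy(resident)
  eq <- equilibrium_requirement(resident, theta, params)
  if (!eq$feasible)
    stop(sprintf("resident strategy (%s, N = %d) has no equilibrium at theta = %g",
                 resident$type, resident$size, theta), call. = FALSE)
  psi <- lifetime_reproductive_success(invader, eq$xbar_N, theta, params)
  structure(list(invader = invader, resident = resident, theta = theta,
                 xbar_resident = eq$xbar_N, psi = psi),
            class = "invasion_cell")
}

#' @export
print.invasion_cell <- function(x, ...) {
  cat(sprintf(
    "<invasion_cell> %s N = %d invading %s N = %d at theta = %g: Psi = %.6g\n",
    x$invader$type, x$invader$size, x$resident$type, x$resident$size,
    x$theta, x$psi))
  invisible(x)
}

#' Pairwise invasibility matrix
#'
#' Invasion fitness `Psi` for every ordered pair of strategies: rows are
#' invaders, columns residents, each evaluated at the resident's equilibrium
#' resource level. The strategy with the lowest equilibrium requirement has
#' all off-diagonal entries in its column at or below one — minimizing
#' `xbar_N` and uninvadability coincide — and the diagonal is identically
#' one.
#'
#' @param strategies A list of [group_strategy()] objects, all feasible at
#'   `theta`.
#' @param theta Mean resource item size.
#' @param params A [model_params()] object.
#' @return A numeric matrix of class `"invasibility_grid"` with invaders in
#'   rows and residents in columns, dimnames labelling the strategies, and
#'   the residents' `xbar_N` attached as attribute `"xbar_resident"`.
#' @examples
#' strategies <- list(group_strategy("eusocial", 1),
#'                    group_strategy("eusocial", 6))
#' pairwise_invasibility_grid(strategies, theta = 2, params = model_params())
#' @export
pairwise_invasibility_grid <- function(strategies, theta, params) {
  stopifnot(is.list(strategies), length(strategies) >= 1)
  lapply(strategies, assert_strategy)
  labels <- vapply(strategies, function(s)
    sprintf("%s_N%d", s$type, s$size), character(1))
  xbar_res <- vapply(strategies, function(s) {
    eq <- equilibrium_requirement(s, theta, params)
    if (!eq$feasible)
      stop(sprintf("strategy %s_N%d has no equilibrium at theta = %g",
                   s$type, s$size, theta), call. = FALSE)
    eq$xbar_N
  }, numeric(1))
  psi <- matrix(NA_real_, length(strategies), length(strategies),
                dimnames = list(invader = labels, resident = labels))
  for (j in seq_along(strategies)) {
    for (i in seq_along(strategies)) {
      psi[i, j] <- lifetime_reproductive_success(
        strategies[[i]], xbar_res[j], theta, params)
    }
  }
  attr(psi, "xbar_resident") <- stats::setNames(xbar_res, labels)
  attr(psi, "theta") <- theta
  class(psi) <- c("invasibility_grid", class(psi))
  psi
}

#' @export
print.invasibility_grid <- function(x, ...) {
  cat(sprintf("<invasibility_grid> theta = %g (rows invade columns)\n",
              attr(x, "theta")))
  m <- x
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  print(round(m, 4))
  invisible(x)
}
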