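#' Step mortality function
#'
#' An individual dies with certainty if the resources allocated to survival
#' fall below the threshold `o_M`; otherwise it faces only the
#' resource-independent baseline mortality `M_b` (predation, disease).
#' Receiving exactly `o_M` counts as survival.
#'
#' @param x_s Resources allocated to survival, nonnegative; vectorized.
#' @param params A [model_params()] object.
#' @return Death probabilities.
#' @examples
#' mortality_probability(c(0.5, 1, 2), model_params())
#' @export
mortality_probability <- function(x_s, params) {
  assert_params(params)
  if (any(!is.finite(x_s)) || any(x_s < 0))
    stop("`x_s` must be finite and nonnegative", call. = FALSE)
  ifelse(x_s < params$o_M, 1, params$M_b)
}

#' Mean per-capita mortality in a group
#'
#' Expected death probability of a group member when the per-capita pooled
#' share follows the Gamma law for (`mean_x`, `theta`, N): the probability
#' `C` of falling below the survival threshold plus baseline mortality for
#' the rest, `mu = C + (1 - C) * M_b`. Identical for egalitarian and
#' eusocial groups, strictly decreasing in `mean_x`.
#'
#' @param strategy A [group_strategy()] (only the group size enters).
#' @param mean_x Mean per-capita resources, positive.
#' @param theta Mean resource item size.
#' @param params A [model_params()] object.
#' @return Death probability in `[M_b, 1]`.
#' @examples
#' mean_mortality(group_strategy("egalitarian", 1), 4, 1, model_params())
#' @export
mean_mortality <- function(strategy, mean_x, theta, params) {
  assert_strategy(strategy)
  assert_params(params)
  dist <- resource_dist(mean_x, theta, strategy$size,
                        theta_min = params$theta_min)
  if (dist$deterministic) {
    # point mass at mean_x; the boundary share x = o_M survives
    C <- as.numeric(mean_x < params$o_M)
  } else {
    C <- pooled_share_cdf(params$o_M, dist)
  }
  C + (1 - C) * params$M_b
}

#' Sigmoid fertility function
#'
#' Expected offspring from `x_r` resources allocated to reproduction:
#' `F(x_r) = F_max * (1 - exp(-x_r / (c0 * F_max)))^2`. Zero at zero,
#' saturating at the maximal fecundity `F_max`, with initial steepness
#' set by `1/c0`; convex below the inflection point `c0 * F_max * log(2)`
#' and concave above it. The convex region is what makes increased variance
#' in reproductive resources profitable (Jensen's inequality), the central
#' mechanism favouring reproductive skew under scarcity.
#'
#' @param x_r Resources allocated to reproduction, nonnegative; vectorized.
#'   Callers apply `x_r = max(0, x - o_M)` beforehand.
#' @param params A [model_params()] object.
#' @return Expected offspring in `[0, F_max)`.
#' @examples
#' p <- model_params()
#' fertility(p$c0 * p$F_max * log(2), p)  # quarter of F_max at the inflection
#' @export
fertility <- function(x_r, params) {
  assert_params(params)
  if (any(!is.finite(x_r)) || any(x_r < 0))
    stop("`x_r` must be finite and nonnegative", call. = FALSE)
  params$F_max * (1 - exp(-x_r / (params$c0 * params$F_max)))^2
}

# Quadrature of integrand(x) * dgamma(x) over [max(o_M, lo), hi] where
# lo/hi are extreme Gamma quantiles; truncated tail mass < 2e-15, and the
# integrand is bounded, so truncation error is negligible.
.expect_over_share <- function(fun, dist, o_M) {
  lo <- max(o_M, stats::qgamma(1e-15, shape = dist$shape, scale = dist$scale))
  hi <- stats::qgamma(1e-15, shape = dist$shape, scale = dist$scale,
                      lower.tail = FALSE)
  if (hi <= lo) return(0)
  res <- stats::integrate(
    function(x) fun(x) * stats::dgamma(x, shape = dist$shape,
                                       scale = dist$scale),
    lower = lo, upper = hi,
    rel.tol = 1e-10, abs.tol = 1e-12, subdivisions = 1000L,
    stop.on.error = FALSE)
  if (res$message != "OK")
    stop(sprintf(
      "quadrature failed (%s) on [%g, %g], shape = %g, scale = %g",
      res$message, lo, hi, dist$shape, dist$scale), call. = FALSE)
  res$value
}

#' Per-capita natality of a group
#'
#' Expected per-capita offspring given the pooled per-capita share
#' distribution. Egalitarian groups: each member keeps its share, so
#' `phi = E[F(max(0, x - o_M))]`. Eusocial groups: surplus shares are
#' channelled to one reproductive dominant, so
#' `phi = E[F(N * max(0, x - o_M))] / N` — the fertility function is
#' evaluated at N times greater resource values and divided by N for the
#' per-capita rate. At N = 1 both coincide.
#'
#' @inheritParams mean_mortality
#' @return Expected per-capita offspring, bounded by `F_max` (egalitarian)
#'   or `F_max / N` (eusocial).
#' @examples
#' natality(group_strategy("eusocial", 4), 4, 1, model_params())
#' @export
natality <- function(strategy, mean_x, theta, params) {
  assert_strategy(strategy)
  assert_params(params)
  stopifnot(is.numeric(mean_x), length(mean_x) == 1L, mean_x > 0)
  N <- strategy$size
  o_M <- params$o_M
  dist <- resource_dist(mean_x, theta, N, theta_min = params$theta_min)
  if (dist$deterministic) {
    x_r <- max(0, mean_x - o_M)
    return(switch(strategy$type,
                  egalitarian = fertility(x_r, params),
                  eusocial    = fertility(N * x_r, params) / N))
  }
  switch(strategy$type,
    egalitarian = .expect_over_share(
      function(x) fertility(pmax(0, x - o_M), params), dist, o_M),
    eusocial = .expect_over_share(
      function(x) fertility(N * pmax(0, x - o_M), params), dist, o_M) / N
  )
}

#' Lifetime reproductive success
#'
#' Expected offspring over a lifetime, `Psi = phi / mu`: per-capita natality
#' times the mean lifetime `1/mu`. The resident strategy at its own
#' demographic equilibrium has `Psi = 1`; values above (below) one indicate
#' a growing (shrinking) strategy at the given resource level.
#'
#' @inheritParams mean_mortality
#' @return The dimensionless lifetime reproductive success.
#' @export
lifetime_reproductive_success <- function(strategy, mean_x, theta, params) {
  mu <- mean_mortality(strategy, mean_x, theta, params)
  if (mu <= 0)
    stop("mortality is zero (M_b = 0 and no starvation risk): ",
         "lifetime reproductive success is unbounded", call. = FALSE)
  natality(strategy, mean_x, theta, params) / mu
}
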