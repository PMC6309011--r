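#' Individual-based simulation of one foraging season
#'
#' Stochastic enactment of the model used to validate every quadrature and
#' closed-form result. Each replicate group of size N draws N independent
#' Gamma harvests, pools them and splits the total equally, so every member
#' holds the same per-capita share. Members whose share falls below the
#' survival threshold starve (share allocation is identical within a group,
#' so starvation is group-wide); survivors face independent Bernoulli
#' baseline mortality. Reproductive resources `x_r = max(0, share - o_M)`
#' are kept per capita (egalitarian: each member realizes `F(x_r)`) or
#' pooled for one dominant (eusocial: the dominant realizes `F(N * x_r)`,
#' divided by N for the per-capita rate). Fertility is realized as the
#' deterministic expected offspring per share; a stochastic (e.g. Poisson)
#' realization would have the identical mean.
#'
#' Two RNG streams derived from `seed` (harvests, baseline mortality) are
#' drawn column-wise, so enlarging `n_groups` appends replicates without
#' reshuffling earlier ones.
#'
#' @param strategy A [group_strategy()].
#' @param mean_x Mean per-capita resources, positive.
#' @param theta Mean resource item size.
#' @param params A [model_params()] object.
#' @param n_groups Number of replicate groups, at least 1.
#' @param seed Integer master seed.
#' @return An object of class `"mc_estimate"`: a list with `mu_hat`,
#'   `phi_hat` (empirical per-capita mortality and natality), `se_mu`,
#'   `se_phi` (standard errors over groups), `n_groups` and `seed`.
#' @examples
#' simulate_season(group_strategy("egalitarian", 4), mean_x = 4, theta = 1,
#'                 params = model_params(), n_groups = 1000, seed = 1)
#' @export
simulate_season <- function(strategy, mean_x, theta, params, n_groups, seed) {
  assert_strategy(strategy)
  assert_params(params)
  stopifnot(is.numeric(mean_x), length(mean_x) == 1L, mean_x > 0,
            is.numeric(n_groups), length(n_groups) == 1L, n_groups >= 1,
            n_groups == round(n_groups),
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  n_groups <- as.integer(n_groups)
  N <- strategy$size
  dist <- resource_dist(mean_x, theta, N, theta_min = params$theta_min)

  shares <- sample_pooled_shares(n_groups, dist, seed = seed)
  starved <- shares < params$o_M

  # second stream, offset so it is independent of the harvest stream
  u <- with_seed((seed + 1000003) %% .Machine$integer.max,
                 matrix(stats::runif(N * n_groups), nrow = N))
  baseline_deaths <- colSums(u < params$M_b)
  mort <- ifelse(starved, 1, baseline_deaths / N)

  x_r <- pmax(0, shares - params$o_M)
  nat <- switch(strategy$type,
                egalitarian = fertility(x_r, params),
                eusocial    = fertility(N * x_r, params) / N)

  structure(
    list(mu_hat = mean(mort),
         phi_hat = mean(nat),
         se_mu = stats::sd(mort) / sqrt(n_groups),
         se_phi = stats::sd(nat) / sqrt(n_groups),
         n_groups = n_groups, seed = seed),
    class = "mc_estimate")
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat(sprintf(
    "<mc_estimate> n = %d: mu_hat = %.5f (se %.2g), phi_hat = %.5f (se %.2g)\n",
    x$n_groups, x$mu_hat, x$se_mu, x$phi_hat, x$se_phi))
  invisible(x)
}

#' Random validation panel: simulation versus quadrature
#'
#' Draws a random panel of (parameter set, strategy, mean resources, item
#' size) combinations, runs the individual-based simulator on each and
#' compares the empirical per-capita mortality and natality with the
#' analytic values, reporting z-scores. Under a correct implementation about
#' 99.7% of z-scores lie within 3.
#'
#' @param n_cases Number of panel cases, at least 1.
#' @param n_groups Replicate groups per case.
#' @param seed Integer master seed (drives both the case draw and the
#'   per-case simulations).
#' @return A data frame with one row per case: the case definition
#'   (`preset`, `group_type`, `N`, `mean_x`, `theta`), analytic `mu` and
#'   `phi`, empirical `mu_hat` and `phi_hat` with standard errors, and
#'   `z_mu`, `z_phi`.
#' @examples
#' panel <- oracle_panel(n_cases = 5, n_groups = 2000, seed = 1)
#' max(abs(panel$z_mu), abs(panel$z_phi))
#' @export
oracle_panel <- function(n_cases = 24L, n_groups = 20000L, seed = 1L) {
  stopifnot(n_cases >= 1, n_groups >= 2)
  presets <- c("standard", "increased-mortality", "increased-cost",
               "increased-fecundity")
  cases <- with_seed(seed, data.frame(
    preset = sample(presets, n_cases, replace = TRUE),
    group_type = sample(c("egalitarian", "eusocial"), n_cases,
                        replace = TRUE),
    N = sample(1:8, n_cases, replace = TRUE),
    mean_x = stats::runif(n_cases, 1.2, 8),
    theta = exp(stats::runif(n_cases, log(0.1), log(16)))
  ))
  rows <- lapply(seq_len(n_cases), function(i) {
    params <- preset_params(cases$preset[i])
    strat <- group_strategy(cases$group_type[i], cases$N[i])
    mu <- mean_mortality(strat, cases$mean_x[i], cases$theta[i], params)
    phi <- natality(strat, cases$mean_x[i], cases$theta[i], params)
    est <- simulate_season(strat, cases$mean_x[i], cases$theta[i], params,
                           n_groups = n_groups,
                           seed = (seed + 7919L * i) %% .Machine$integer.max)
    data.frame(
      cases[i, , drop = FALSE],
      mu = mu, phi = phi,
      mu_hat = est$mu_hat, se_mu = est$se_mu,
      phi_hat = est$phi_hat, se_phi = est$se_phi,
      z_mu = if (est$se_mu > 0) (est$mu_hat - mu) / est$se_mu else 0,
      z_phi = if (est$se_phi > 0) (est$phi_hat - phi) / est$se_phi else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
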