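#' Equilibrium per-capita resource requirement of a strategy
#'
#' Solves the demographic equilibrium condition `phi(N, xbar, theta) =
#' mu(N, xbar, theta)` for the minimal mean per-capita resource amount
#' `xbar_N` at which reproduction balances mortality. Under resource
#' limitation this is the resource level a population of that strategy draws
#' the environment down to; strategies with smaller `xbar_N` are more
#' resource-use efficient and reach higher carrying capacities.
#'
#' The net growth profile `phi - mu` is strictly increasing in `xbar`
#' (natality increases and mortality decreases with resources), so the root,
#' when it exists inside the search window, is unique. The solver scans a
#' geometric grid on `[o_M * (1 + 1e-6), o_M + 10 * c0 * F_max]` for the
#' first sign change and then bisects with [stats::uniroot()]. Eusocial
#' groups with `F_max / N <= M_b` can never balance baseline mortality
#' (per-capita natality is bounded by `F_max / N`) and are reported
#' infeasible without solving.
#'
#' @param strategy A [group_strategy()].
#' @param theta Mean resource item size (environmental variance proxy).
#' @param params A [model_params()] object.
#' @param xbar_solitary Optional precomputed solitary requirement `xbar_1`
#'   used for the relative carrying capacity; solved internally when `NULL`.
#' @param n_scan Number of scan points used to bracket the root.
#' @param rel_tol Relative tolerance of the bisection.
#' @return An object of class `"equilibrium_result"`: a list with `strategy`,
#'   `theta`, `xbar_N`, `residual` (absolute value of `phi - mu` at the
#'   root), `K_rel` (carrying capacity relative to the solitary strategy,
#'   `xbar_1 / xbar_N`), `feasible` and the search `bracket`.
#' @examples
#' eq <- equilibrium_requirement(group_strategy("eusocial", 8), theta = 5,
#'                               params = model_params())
#' eq$xbar_N
#' @export
equilibrium_requirement <- function(strategy, theta, params,
                                    xbar_solitary = NULL,
                                    n_scan = 64L, rel_tol = 1e-10) {
  assert_strategy(strategy)
  assert_params(params)
  N <- strategy$size

  infeasible <- function(bracket) {
    structure(list(strategy = strategy, theta = theta, xbar_N = NA_real_,
                   residual = NA_real_, K_rel = NA_real_, feasible = FALSE,
                   bracket = bracket),
              class = "equilibrium_result")
  }

  # per-capita natality of eusocial groups is bounded by F_max / N
  if (strategy$type == "eusocial" && params$F_max / N <= params$M_b)
    return(infeasible(c(NA_real_, NA_real_)))

  g <- function(x) {
    natality(strategy, x, theta, params) -
      mean_mortality(strategy, x, theta, params)
  }

  lo <- params$o_M * (1 + 1e-6)
  hi <- params$o_M + 10 * params$c0 * params$F_max
  grid <- exp(seq(log(lo), log(hi), length.out = n_scan))
  gv <- vapply(grid, g, numeric(1))

  if (gv[1] >= 0) {
    # root below the nominal window start: extend the bracket downwards
    lower <- lo
    repeat {
      lower <- lower / 2
      if (g(lower) < 0 || lower < 1e-6 * params$o_M) break
    }
    bracket <- c(lower, grid[1])
  } else {
    i <- which(gv >= 0)[1]
    if (is.na(i)) return(infeasible(c(lo, hi)))
    bracket <- c(grid[i - 1L], grid[i])
  }

  root <- stats::uniroot(g, lower = bracket[1], upper = bracket[2],
                         tol = rel_tol * bracket[2])
  xbar_N <- root$root
  if (is.null(xbar_solitary)) {
    xbar_solitary <- if (N == 1L) xbar_N else
      equilibrium_requirement(group_strategy(strategy$type, 1L), theta,
                              params, n_scan = n_scan,
                              rel_tol = rel_tol)$xbar_N
  }
  structure(
    list(strategy = strategy, theta = theta, xbar_N = xbar_N,
         residual = abs(g(xbar_N)), K_rel = xbar_solitary / xbar_N,
         feasible = TRUE, bracket = bracket),
    class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf(
      "<equilibrium_result> %s N = %d, theta = %g: xbar_N = %.6g (K_rel = %.4g)\n",
      x$strategy$type, x$strategy$size, x$theta, x$xbar_N, x$K_rel))
  } else {
    cat(sprintf("<equilibrium_result> %s N = %d, theta = %g: infeasible\n",
                x$strategy$type, x$strategy$size, x$theta))
  }
  invisible(x)
}

#' Carrying capacity
#'
#' Equilibrium population size supported by a total resource supply `X` when
#' each individual requires `xbar_N` resources: `K = X / xbar_N`.
#'
#' @param total_resources Total amount of resources available, positive.
#' @param xbar_N Per-capita equilibrium resource requirement, positive.
#' @return The carrying capacity.
#' @examples
#' carrying_capacity(100, 4)
#' @export
carrying_capacity <- function(total_resources, xbar_N) {
  if (any(!is.finite(total_resources)) || any(total_resources <= 0))
    stop("`total_resources` must be positive", call. = FALSE)
  if (any(!is.finite(xbar_N)) || any(xbar_N <= 0))
    stop("`xbar_N` must be positive", call. = FALSE)
  total_resources / xbar_N
}

# default upper end of the group-size search: the eusocial feasibility bound
# ceil(F_max / M_b) plus a margin so infeasibility at the boundary is
# confirmed rather than assumed
default_N_max <- function(params) {
  if (params$M_b <= 0) return(32L)
  as.integer(ceiling(params$F_max / params$M_b)) + 2L
}

#' Optimal group size at a given environmental variance
#'
#' Solves the equilibrium requirement for every group size `N = 1 ... N_max`
#' and returns the feasible `N` minimizing `xbar_N` — equivalently,
#' maximizing carrying capacity. The scan is exhaustive and ties go to the
#' smaller group size.
#'
#' @param group_type `"egalitarian"` or `"eusocial"`.
#' @param theta Mean resource item size.
#' @param params A [model_params()] object.
#' @param N_max Upper end of the group-size search; defaults to
#'   `ceiling(F_max / M_b) + 2`.
#' @return An object of class `"sweep_record"`: a list with `theta`,
#'   `group_type`, `N_opt`, `xbar_at_opt`, `K_rel_at_opt` and `table`, a
#'   per-N data frame with columns `N`, `xbar_N`, `K_rel`, `feasible`,
#'   `is_opt`.
#' @examples
#' optimal_group_size("eusocial", theta = 5, params = model_params())
#' @export
optimal_group_size <- function(group_type = c("egalitarian", "eusocial"),
                               theta, params, N_max = NULL) {
  group_type <- match.arg(group_type)
  assert_params(params)
  if (is.null(N_max)) N_max <- default_N_max(params)
  stopifnot(N_max >= 1)

  sol <- equilibrium_requirement(group_strategy(group_type, 1L), theta, params)
  if (!sol$feasible)
    stop("no feasible group size: even the solitary strategy has no ",
         "demographic equilibrium at theta = ", theta, call. = FALSE)
  results <- vector("list", N_max)
  results[[1L]] <- sol
  for (N in seq_len(N_max)[-1L]) {
    results[[N]] <- equilibrium_requirement(
      group_strategy(group_type, N), theta, params,
      xbar_solitary = sol$xbar_N)
  }
  xbar <- vapply(results, function(r) r$xbar_N, numeric(1))
  feasible <- vapply(results, function(r) r$feasible, logical(1))
  K_rel <- vapply(results, function(r) r$K_rel, numeric(1))
  N_opt <- which.min(ifelse(feasible, xbar, Inf))  # first minimum: ties -> smaller N
  tab <- data.frame(N = seq_len(N_max), xbar_N = xbar, K_rel = K_rel,
                    feasible = feasible,
                    is_opt = seq_len(N_max) == N_opt)
  structure(
    list(theta = theta, group_type = group_type, N_opt = as.integer(N_opt),
         xbar_at_opt = xbar[N_opt], K_rel_at_opt = K_rel[N_opt], table = tab),
    class = "sweep_record")
}

#' @export
print.sweep_record <- function(x, ...) {
  cat(sprintf(
    "<sweep_record> %s, theta = %g: N_opt = %d, xbar = %.6g, K_rel = %.4g\n",
    x$group_type, x$theta, x$N_opt, x$xbar_at_opt, x$K_rel_at_opt))
  invisible(x)
}

#' Default environmental-variance grid
#'
#' Log-spaced grid of mean item sizes used by the sweep drivers.
#'
#' @param n Number of grid points.
#' @param range Lower and upper item size.
#' @return Numeric vector, strictly increasing.
#' @export
default_theta_grid <- function(n = 48L, range = c(0.1, 16)) {
  stopifnot(n >= 1, length(range) == 2L, all(range > 0), range[1] <= range[2])
  if (n == 1L) return(range[1])
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' Sweep optimal group sizes over environmental variance
#'
#' Runs [optimal_group_size()] for every combination of group type and item
#' size, producing the resource-requirement and optimal-group-size profiles
#' over the environmental-variance axis.
#'
#' @param group_types Character vector, subset of
#'   `c("egalitarian", "eusocial")`.
#' @param theta_grid Strictly increasing positive grid of item sizes.
#' @param params A [model_params()] object.
#' @param N_max Upper end of the group-size search (see
#'   [optimal_group_size()]).
#' @return An object of class `"theta_sweep"`: a list with `records` (one
#'   [optimal_group_size()] record per type/theta), `summary` (one row per
#'   record) and `table`, the long per-N data frame with columns
#'   `theta, group_type, N, xbar_N, K_rel, feasible, is_opt`.
#' @examples
#' sw <- theta_sweep("eusocial", c(2, 4), model_params(), N_max = 12)
#' sw$summary
#' @export
theta_sweep <- function(group_types = c("egalitarian", "eusocial"),
                        theta_grid = default_theta_grid(),
                        params = model_params(), N_max = NULL) {
  group_types <- match.arg(group_types, several.ok = TRUE)
  if (length(theta_grid) < 1 || any(theta_grid <= 0) ||
      is.unsorted(theta_grid, strictly = TRUE))
    stop("`theta_grid` must be a nonempty, strictly increasing, positive grid",
         call. = FALSE)
  records <- list()
  for (type in group_types) {
    for (theta in theta_grid) {
      records[[length(records) + 1L]] <-
        optimal_group_size(type, theta, params, N_max = N_max)
    }
  }
  summary <- do.call(rbind, lapply(records, function(r) {
    data.frame(theta = r$theta, group_type = r$group_type, N_opt = r$N_opt,
               xbar_at_opt = r$xbar_at_opt, K_rel_at_opt = r$K_rel_at_opt)
  }))
  table <- do.call(rbind, lapply(records, function(r) {
    cbind(data.frame(theta = r$theta, group_type = r$group_type),
          r$table)
  }))
  table <- table[, c("theta", "group_type", "N", "xbar_N", "K_rel",
                     "feasible", "is_opt")]
  structure(list(records = records, summary = summary, table = table),
            class = "theta_sweep")
}

#' @export
print.theta_sweep <- function(x, ...) {
  cat(sprintf("<theta_sweep> %d records\n", length(x$records)))
  print(utils::head(x$summary, 10))
  if (nrow(x$summary) > 10) cat("...\n")
  invisible(x)
}
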