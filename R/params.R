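#' Demographic and environmental model parameters
#'
#' Bundles the constants of the consumer-resource group-formation model:
#' maximal fecundity, cost of reproduction, baseline mortality and the
#' survival resource threshold. Environmental variance (the mean resource
#' item size `theta`) is *not* part of this object: it is the swept
#' environmental variable and is passed explicitly to the functions that
#' need it.
#'
#' @param F_max Maximal fecundity: net number of offspring per reproductive
#'   period that the fertility function saturates at. Must be positive.
#' @param c0 Cost of reproduction (resource units per offspring scale); the
#'   initial steepness of the fertility function is governed by `1/c0`.
#'   Must be positive.
#' @param M_b Baseline per-period mortality probability (predation, disease),
#'   independent of resources. In `[0, 1]`.
#' @param o_M Survival resource threshold: an individual that receives less
#'   than `o_M` resources in a period starves. Nonnegative.
#' @param theta_min Item sizes below this threshold are treated as the
#'   deterministic-resources limit (a point mass at the mean) to avoid
#'   degenerate Gamma shape parameters.
#'
#' @return An object of class `"model_params"`.
#' @seealso [preset_params()] for the four named parameter sets used
#'   throughout the package's worked examples.
#' @examples
#' model_params()                 # standard parameter set
#' model_params(F_max = 5)        # increased fecundity
#' @export
model_params <- function(F_max = 3, c0 = 4, M_b = 0.1, o_M = 1,
                         theta_min = 1e-6) {
  stopifnot(
    is.numeric(F_max), length(F_max) == 1L, is.finite(F_max), F_max > 0,
    is.numeric(c0), length(c0) == 1L, is.finite(c0), c0 > 0,
    is.numeric(M_b), length(M_b) == 1L, M_b >= 0, M_b <= 1,
    is.numeric(o_M), length(o_M) == 1L, is.finite(o_M), o_M >= 0,
    is.numeric(theta_min), length(theta_min) == 1L, theta_min > 0
  )
  structure(
    list(F_max = F_max, c0 = c0, M_b = M_b, o_M = o_M, theta_min = theta_min),
    class = "model_params"
  )
}

#' Named parameter presets
#'
#' The four parameter combinations used as exemplary panels throughout the
#' package: the standard set, increased mortality, increased cost of
#' reproduction and increased fecundity.
#'
#' @param preset One of `"standard"`, `"increased-mortality"`,
#'   `"increased-cost"`, `"increased-fecundity"`.
#' @return A [model_params()] object.
#' @examples
#' preset_params("increased-fecundity")
#' @export
preset_params <- function(preset = c("standard", "increased-mortality",
                                     "increased-cost", "increased-fecundity")) {
  preset <- match.arg(preset)
  switch(preset,
    "standard"            = model_params(F_max = 3, c0 = 4, M_b = 0.1, o_M = 1),
    "increased-mortality" = model_params(F_max = 3, c0 = 4, M_b = 0.2, o_M = 1),
    "increased-cost"      = model_params(F_max = 3, c0 = 8, M_b = 0.1, o_M = 1),
    "increased-fecundity" = model_params(F_max = 5, c0 = 4, M_b = 0.1, o_M = 1)
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters:\n")
  cat(sprintf("  F_max = %g (maximal fecundity)\n", x$F_max))
  cat(sprintf("  c0    = %g (cost of reproduction)\n", x$c0))
  cat(sprintf("  M_b   = %g (baseline mortality)\n", x$M_b))
  cat(sprintf("  o_M   = %g (survival threshold)\n", x$o_M))
  invisible(x)
}

assert_params <- function(params) {
  if (!inherits(params, "model_params"))
    stop("`params` must be a `model_params` object; see model_params()",
         call. = FALSE)
  invisible(params)
}

#' Group strategy
#'
#' A competing strategy is a pair of group type and group size. Egalitarian
#' groups share pooled resources equally for both survival and reproduction;
#' eusocial groups channel all resources beyond individual survival needs to
#' a single reproductive dominant. At `size = 1` both types describe the same
#' solitary strategy.
#'
#' @param type `"egalitarian"` or `"eusocial"` (partial matching allowed).
#' @param size Group size N, a positive integer.
#' @return An object of class `"group_strategy"` with elements `type` and
#'   `size`.
#' @examples
#' group_strategy("eusocial", 8)
#' @export
group_strategy <- function(type = c("egalitarian", "eusocial"), size = 1L) {
  type <- match.arg(type)
  stopifnot(is.numeric(size), length(size) == 1L, is.finite(size),
            size >= 1, size == round(size))
  structure(list(type = type, size = as.integer(size)),
            class = "group_strategy")
}

#' @export
print.group_strategy <- function(x, ...) {
  cat(sprintf("<group_strategy> %s, N = %d\n", x$type, x$size))
  invisible(x)
}

assert_strategy <- function(strategy) {
  if (!inherits(strategy, "group_strategy"))
    stop("`strategy` must be a `group_strategy` object", call. = FALSE)
  invisible(strategy)
}

# Evaluate code with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
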