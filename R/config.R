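#' Experiment configuration
#'
#' Collects everything a full model run needs: the demographic parameters,
#' the environmental-variance grids, which group types to compare, solver
#' settings and the simulator settings. Serializes losslessly to JSON or
#' YAML via [save_config()] / [load_config()].
#'
#' @param params A [model_params()] object or the name of a preset
#'   understood by [preset_params()].
#' @param theta_grid Strictly increasing positive grid of item sizes for the
#'   group-size sweep.
#' @param group_types Subset of `c("egalitarian", "eusocial")`.
#' @param theta_focus Single item size at which the per-group-size
#'   equilibrium table is produced.
#' @param rmin_theta_grid Grid for the minimum-relatedness sweep; defaults
#'   to `theta_grid`.
#' @param N_max Group-size search cap; `NULL` for the default
#'   `ceiling(F_max / M_b) + 2`.
#' @param oracle List with `n_groups` and `seed` for the simulation panel.
#' @param output_dir Directory that [run_experiment()] writes into.
#' @param make_plots Whether [run_experiment()] renders PNG figures next to
#'   the CSV tables.
#' @return An object of class `"experiment_config"`.
#' @examples
#' cfg <- experiment_config(params = "standard", theta_grid = c(1, 2, 4))
#' @export
experiment_config <- function(params = preset_params("standard"),
                              theta_grid = default_theta_grid(),
                              group_types = c("egalitarian", "eusocial"),
                              theta_focus = 5,
                              rmin_theta_grid = NULL,
                              N_max = NULL,
                              oracle = list(n_groups = 10000L, seed = 42L),
                              output_dir = ".",
                              make_plots = TRUE) {
  if (is.character(params)) params <- preset_params(params)
  assert_params(params)
  if (length(theta_grid) < 1 || any(theta_grid <= 0) ||
      is.unsorted(theta_grid, strictly = TRUE))
    stop("`theta_grid` must be a nonempty, strictly increasing, positive grid",
         call. = FALSE)
  group_types <- match.arg(group_types, c("egalitarian", "eusocial"),
                           several.ok = TRUE)
  if (is.null(rmin_theta_grid)) rmin_theta_grid <- theta_grid
  if (any(rmin_theta_grid <= 0) ||
      is.unsorted(rmin_theta_grid, strictly = TRUE))
    stop("`rmin_theta_grid` must be strictly increasing and positive",
         call. = FALSE)
  stopifnot(is.numeric(theta_focus), length(theta_focus) == 1L,
            theta_focus > 0,
            is.list(oracle), is.numeric(oracle$n_groups),
            is.numeric(oracle$seed),
            is.character(output_dir), length(output_dir) == 1L,
            is.logical(make_plots), length(make_plots) == 1L)
  if (!is.null(N_max))
    stopifnot(is.numeric(N_max), length(N_max) == 1L, N_max >= 1)
  structure(
    list(params = params, theta_grid = as.numeric(theta_grid),
         group_types = group_types, theta_focus = theta_focus,
         rmin_theta_grid = as.numeric(rmin_theta_grid),
         N_max = if (is.null(N_max)) NULL else as.integer(N_max),
         oracle = list(n_groups = as.integer(oracle$n_groups),
                       seed = as.integer(oracle$seed)),
         output_dir = output_dir, make_plots = make_plots),
    class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config>\n")
  print(x$params)
  cat(sprintf("  theta grid: %d points on [%g, %g]; focus theta = %g\n",
              length(x$theta_grid), min(x$theta_grid), max(x$theta_grid),
              x$theta_focus))
  cat(sprintf("  group types: %s\n", paste(x$group_types, collapse = ", ")))
  cat(sprintf("  oracle: n_groups = %d, seed = %d\n",
              x$oracle$n_groups, x$oracle$seed))
  invisible(x)
}

config_to_list <- function(config) {
  list(params = config$params[c("F_max", "c0", "M_b", "o_M", "theta_min")],
       theta_grid = config$theta_grid,
       group_types = config$group_types,
       theta_focus = config$theta_focus,
       rmin_theta_grid = config$rmin_theta_grid,
       N_max = config$N_max,
       oracle = config$oracle,
       output_dir = config$output_dir,
       make_plots = config$make_plots)
}

#' Write an experiment configuration to JSON or YAML
#'
#' @param config An [experiment_config()] object.
#' @param path Output path; the extension (`.json`, `.yaml`/`.yml`) selects
#'   the format.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  if (!inherits(config, "experiment_config"))
    stop("`config` must be an `experiment_config` object", call. = FALSE)
  lst <- config_to_list(config)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(lst, path, precision = 15L)
  } else {
    stop("unsupported config format: '", ext, "' (use .json, .yaml or .yml)",
         call. = FALSE)
  }
  invisible(path)
}

#' Read an experiment configuration from JSON or YAML
#'
#' Strict: unknown keys (at the top level or inside `params`) are rejected
#' with a named-key error, so typos cannot silently fall back to defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An [experiment_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported config format: '", ext, "' (use .json, .yaml or .yml)",
         call. = FALSE)
  }
  allowed <- c("params", "theta_grid", "group_types", "theta_focus",
               "rmin_theta_grid", "N_max", "oracle", "output_dir",
               "make_plots")
  unknown <- setdiff(names(lst), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(lst$params)) {
    if (is.list(lst$params)) {
      bad <- setdiff(names(lst$params),
                     c("F_max", "c0", "M_b", "o_M", "theta_min"))
      if (length(bad))
        stop("unknown params key(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      lst$params <- do.call(model_params, lst$params)
    }
  }
  if (!is.null(lst$oracle)) lst$oracle <- as.list(lst$oracle)
  do.call(experiment_config, lst)
}

#' Write result tables as CSV
#'
#' Fixed column order as supplied, floats formatted with 12 significant
#' digits, no row names: byte-identical files for identical inputs.
#'
#' @param records A data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tables <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- trimws(formatC(out[[j]], digits = 12, format = "g"))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
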