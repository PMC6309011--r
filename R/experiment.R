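#' Run a full model experiment
#'
#' Config-driven driver producing the package's standard output set in
#' `config$output_dir`:
#' \describe{
#'   \item{`sweep.csv`}{Per-N equilibrium table over the whole item-size
#'     grid (columns `theta, group_type, N, xbar_N, K_rel, feasible,
#'     is_opt`).}
#'   \item{`sweep_summary.csv`}{One row per (type, theta): optimal group
#'     size, requirement and relative carrying capacity.}
#'   \item{`equilibrium_by_N.csv`}{Per-N table at the focus item size
#'     `theta_focus` (resource requirement and relative carrying capacity
#'     against group size).}
#'   \item{`rmin_vs_theta.csv`}{Minimum relatedness stabilizing eusocial
#'     groups of optimal size across `rmin_theta_grid`.}
#'   \item{`oracle_panel.csv`}{Simulation-versus-quadrature validation
#'     panel.}
#'   \item{`manifest.json`}{Config echo, config hash, seed and versions.}
#' }
#' PNG figures are rendered alongside when `make_plots` is set and a PNG
#' device is available. Identical configs give byte-identical CSVs.
#'
#' @param config An [experiment_config()] object.
#' @return Invisibly, a named character vector of the files written.
#' @export
run_experiment <- function(config) {
  if (!inherits(config, "experiment_config"))
    stop("`config` must be an `experiment_config` object", call. = FALSE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(config$output_dir, mode = 2) != 0)
    stop("output directory is not writable: ", config$output_dir,
         call. = FALSE)
  out <- function(name) file.path(config$output_dir, name)
  files <- character(0)

  sweep <- theta_sweep(config$group_types, config$theta_grid, config$params,
                       N_max = config$N_max)
  write_tables(sweep$table, out("sweep.csv"))
  write_tables(sweep$summary, out("sweep_summary.csv"))
  files <- c(files, sweep = out("sweep.csv"),
             sweep_summary = out("sweep_summary.csv"))

  focus <- lapply(config$group_types, function(type)
    optimal_group_size(type, config$theta_focus, config$params,
                       N_max = config$N_max))
  focus_tab <- do.call(rbind, lapply(focus, function(r)
    cbind(data.frame(theta = r$theta, group_type = r$group_type),
          r$table)))
  focus_tab <- focus_tab[, c("theta", "group_type", "N", "xbar_N", "K_rel",
                             "feasible", "is_opt")]
  write_tables(focus_tab, out("equilibrium_by_N.csv"))
  files <- c(files, equilibrium_by_N = out("equilibrium_by_N.csv"))

  rmin <- rmin_sweep(config$rmin_theta_grid, config$params,
                     N_max = config$N_max)
  write_tables(rmin, out("rmin_vs_theta.csv"))
  files <- c(files, rmin_vs_theta = out("rmin_vs_theta.csv"))

  panel <- oracle_panel(n_cases = 24L, n_groups = config$oracle$n_groups,
                        seed = config$oracle$seed)
  write_tables(panel, out("oracle_panel.csv"))
  files <- c(files, oracle_panel = out("oracle_panel.csv"))

  manifest <- list(
    config = config_to_list(config),
    config_hash = config_hash(config),
    seed = config$oracle$seed,
    versions = list(r = R.version.string,
                    groupskew = as.character(utils::packageVersion("groupskew"))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  files <- c(files, manifest = out("manifest.json"))

  if (isTRUE(config$make_plots) && isTRUE(capabilities("png"))) {
    files <- c(files, plot_experiment(sweep, focus_tab, rmin,
                                      config$output_dir))
  }
  invisible(files)
}

# md5 of the canonical JSON serialization of the config
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config_to_list(config), tmp, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

plot_experiment <- function(sweep, focus_tab, rmin, output_dir) {
  files <- character(0)
  pch_of <- c(egalitarian = 1, eusocial = 2)

  f <- file.path(output_dir, "sweep.png")
  grDevices::png(f, width = 1200, height = 600, res = 120)
  graphics::par(mfrow = c(1, 2))
  s <- sweep$summary
  graphics::plot(NA, xlim = range(s$theta), ylim = range(s$xbar_at_opt),
                 log = "x", xlab = expression(theta),
                 ylab = "resource requirement at N_opt")
  for (type in unique(s$group_type)) {
    ss <- s[s$group_type == type, ]
    graphics::points(ss$theta, ss$xbar_at_opt, pch = pch_of[[type]],
                     type = "b")
  }
  graphics::legend("topleft", legend = unique(s$group_type),
                   pch = pch_of[unique(s$group_type)], bty = "n")
  graphics::plot(NA, xlim = range(s$theta), ylim = range(s$N_opt),
                 log = "x", xlab = expression(theta), ylab = "N_opt")
  for (type in unique(s$group_type)) {
    ss <- s[s$group_type == type, ]
    graphics::points(ss$theta, ss$N_opt, pch = pch_of[[type]], type = "b")
  }
  grDevices::dev.off()
  files <- c(files, sweep_plot = f)

  f <- file.path(output_dir, "equilibrium_by_N.png")
  grDevices::png(f, width = 1200, height = 600, res = 120)
  graphics::par(mfrow = c(1, 2))
  for (type in unique(focus_tab$group_type)) {
    ft <- focus_tab[focus_tab$group_type == type & focus_tab$feasible, ]
    graphics::plot(ft$N, ft$xbar_N, pch = pch_of[[type]], xlab = "N",
                   ylab = "equilibrium requirement",
                   main = sprintf("%s, theta = %g", type, ft$theta[1]))
    graphics::plot(ft$N, ft$K_rel, pch = pch_of[[type]], xlab = "N",
                   ylab = "relative carrying capacity")
    graphics::abline(h = 1, lty = 3)
  }
  grDevices::dev.off()
  files <- c(files, equilibrium_plot = f)

  f <- file.path(output_dir, "rmin_vs_theta.png")
  grDevices::png(f, width = 700, height = 600, res = 120)
  ok <- rmin$defined
  graphics::plot(rmin$theta[ok], rmin$r_min[ok], log = "x", type = "b",
                 pch = 2, xlab = expression(theta), ylab = expression(r[min]),
                 ylim = c(0, max(0.5, rmin$r_min[ok])))
  grDevices::dev.off()
  files <- c(files, rmin_plot = f)
  files
}
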