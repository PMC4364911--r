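# CSV writers with fixed numeric formatting (10 significant digits) so that
# repeated runs with identical inputs produce bitwise-identical files.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    sprintf("%.10g", v)
  }, character(1))
  out
}

write_hypha_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Run a scenario and write its tabular outputs
#'
#' Simulates a scenario and writes, into \code{out_dir}:
#' \describe{
#'   \item{\code{timeseries.csv}}{one row per sample (division events
#'     included): \code{t_h}, \code{n_tanks}, \code{tip_length_um},
#'     \code{total_length_um}, \code{extension_um},
#'     \code{tip_nutrient_g_dm3}, \code{tip_vesicles_g_dm3},
#'     \code{source_nutrient_g_dm3}.}
#'   \item{\code{profiles.csv}}{long-format spatial profiles at the
#'     requested profile times: \code{t_h}, \code{position_um},
#'     \code{nutrient_g_dm3}, \code{vesicles_g_dm3}.}
#'   \item{\code{manifest.json}}{run manifest: scenario, settings echo,
#'     package version, division-event count, extension-rate audit and
#'     wall time.}
#' }
#'
#' @param scenario preset name, config file path, or
#'   \code{"hypha_scenario"} object.
#' @param t_end horizon, h; default the scenario's own.
#' @param sample_interval sample spacing, h.
#' @param out_dir output directory (created if missing).
#' @param profile_times times for \code{profiles.csv}; default four evenly
#'   spaced times plus \code{t_end}.
#' @param ... passed to \code{\link{simulate_hypha}}.
#' @return The trajectory, invisibly, with the file paths in attribute
#'   \code{"files"}.
#' @export
run_experiment <- function(scenario, t_end = NULL, sample_interval = 1,
                           out_dir = ".", profile_times = NULL, ...) {
  wall0 <- proc.time()[["elapsed"]]
  scenario <- as_hypha_scenario(scenario)
  if (is.null(t_end)) t_end <- scenario$t_end_default
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  samples <- unique(c(seq(0, t_end, by = sample_interval), t_end))
  traj <- simulate_hypha(scenario$params, init = scenario$init,
                         t_end = t_end, sample_times = samples, ...)
  ts_path <- file.path(out_dir, "timeseries.csv")
  write_hypha_csv(traj$series, ts_path)

  if (is.null(profile_times))
    profile_times <- unique(c(seq(0, t_end, length.out = 5)[-1], t_end))
  profs <- do.call(rbind, lapply(profile_times, function(tm) {
    pr <- spatial_profile(traj, tm)
    data.frame(t_h = attr(pr, "time"), position_um = pr$position_um,
               nutrient_g_dm3 = pr$nutrient_g_dm3,
               vesicles_g_dm3 = pr$vesicles_g_dm3)
  }))
  pr_path <- file.path(out_dir, "profiles.csv")
  write_hypha_csv(profs, pr_path)

  man_path <- file.path(out_dir, "manifest.json")
  write_manifest(man_path, scenario = scenario$name,
                 settings = c(list(t_end_h = t_end,
                                   sample_interval_h = sample_interval),
                              traj$settings[c("rel_tol", "abs_tol")]),
                 n_divisions = length(traj$divisions),
                 audit = traj$audit,
                 wall_time_s = proc.time()[["elapsed"]] - wall0)
  attr(traj, "files") <- c(timeseries = ts_path, profiles = pr_path,
                           manifest = man_path)
  invisible(traj)
}

write_manifest <- function(path, scenario, settings, n_divisions, audit,
                           wall_time_s, extra = NULL) {
  man <- c(list(scenario = scenario,
                package = "hyphasim",
                version = as.character(packageVersion("hyphasim")),
                settings = settings,
                n_divisions = n_divisions,
                audit_extension_below_convection = audit),
           extra,
           list(wall_time_s = round(wall_time_s, 3)))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run a sensitivity sweep and write its outputs
#'
#' One-at-a-time sensitivity of extension at \code{t_end} to one
#' parameter; writes \code{sweep.csv} (columns \code{parameter},
#' \code{value}, \code{extension_um_at_t_end}) and
#' \code{sensitivity.json} (the interval, grid, per-point extensions and
#' the percentage-variation statistic F) into \code{out_dir}.
#'
#' @inheritParams sensitivity_F
#' @param out_dir output directory.
#' @return The \code{\link{sensitivity_F}} result, invisibly.
#' @export
sensitivity_experiment <- function(scenario, parameter, low, high,
                                   grid_size = 9L, t_end = 24,
                                   out_dir = ".", ...) {
  wall0 <- proc.time()[["elapsed"]]
  scenario <- as_hypha_scenario(scenario)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- sensitivity_F(scenario, parameter, low, high,
                       grid_size = grid_size, t_end = t_end, ...)
  write_hypha_csv(data.frame(parameter = parameter, value = res$grid,
                             extension_um_at_t_end = res$lengths_um),
                  file.path(out_dir, "sweep.csv"))
  jsonlite::write_json(
    list(scenario = scenario$name, parameter = parameter,
         low = low, high = high, t_end_h = t_end,
         grid = res$grid, extension_um = res$lengths_um,
         F_percent = res$F_percent,
         wall_time_s = round(proc.time()[["elapsed"]] - wall0, 3)),
    file.path(out_dir, "sensitivity.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
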