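#' Spatial concentration profile at a fixed time
#'
#' Nutrient and vesicle concentrations against distance from the hypha
#' base, taken from the stored trajectory snapshot nearest to the requested
#' time. Positions are the tank centres: \code{(i - 1/2) * dx} for normal
#' tanks and \code{(n - 1) * dx + L/2} for the tip-tank, reported in
#' micrometres.
#'
#' @param traj a \code{\link{simulate_hypha}} trajectory.
#' @param time requested time, h; must lie within the trajectory span.
#' @return An object of class \code{"hypha_profile"}: data frame with
#'   columns \code{position_um}, \code{nutrient_g_dm3},
#'   \code{vesicles_g_dm3} and attributes \code{time} (the snapshot time
#'   actually used) and \code{n_tanks}.
#' @export
spatial_profile <- function(traj, time) {
  ts <- vapply(traj$states, `[[`, numeric(1), "t")
  if (time < min(ts) - 1e-9 || time > max(ts) + 1e-9)
    stop("time ", time, " h outside the trajectory span [",
         min(ts), ", ", max(ts), "]", call. = FALSE)
  s <- traj$states[[which.min(abs(ts - time))]]
  pos <- ((seq_len(s$n) - 0.5) * s$dx) * 1e5
  pos[s$n] <- ((s$n - 1L) * s$dx + s$L / 2) * 1e5
  out <- data.frame(position_um = pos,
                    nutrient_g_dm3 = s$omega,
                    vesicles_g_dm3 = s$phi)
  attr(out, "time") <- s$t
  attr(out, "n_tanks") <- s$n
  class(out) <- c("hypha_profile", "data.frame")
  out
}

#' Vesicle mass per tank behind the tip
#'
#' For each sampled time, the fraction of the total vesicle mass residing
#' in each tank, counted backwards from the tip (bin 1 is the tip-tank,
#' bin 2 the tank behind it, and so on). Masses use the actual tank
#' volumes (\code{A * dx} for normal tanks, \code{A * L} for the tip), so
#' the fractions over all tanks sum to one. Samples holding no vesicle
#' mass at all (e.g. the zero initial condition) are skipped.
#'
#' @param traj a \code{\link{simulate_hypha}} trajectory.
#' @param n_bins number of tanks behind the tip to report individually
#'   (tanks further back contribute to the normalization but are not
#'   listed).
#' @param times which sample times to evaluate; default the trajectory's
#'   requested sample grid (division-event snapshots are not included).
#' @return Data frame with columns \code{t_h}, \code{bin} (1 = tip-tank),
#'   \code{distance_behind_tip_um} (nominal bin start, \code{(bin-1)*dx}),
#'   and \code{fraction}.
#' @examples
#' sc <- hypha_preset("rhizopus_oligosporus")
#' traj <- simulate_hypha(sc$params, t_end = 3)
#' fr <- tip_vesicle_fractions(traj)
#' range(fr$fraction[fr$bin == 1])  # tip-tank share over time
#' @export
tip_vesicle_fractions <- function(traj, n_bins = 5L, times = NULL) {
  if (length(traj$states) == 0L) stop("empty trajectory", call. = FALSE)
  if (is.null(times)) times <- traj$sample_times
  ts <- vapply(traj$states, `[[`, numeric(1), "t")
  A <- traj$params$A
  rows <- list()
  for (tm in times) {
    idx <- which(abs(ts - tm) < 1e-9)
    if (!length(idx)) next
    s <- traj$states[[idx[1L]]]
    vol <- rep(A * s$dx, s$n)
    vol[s$n] <- A * s$L
    mass <- s$phi * vol
    tot <- sum(mass)
    if (tot <= 0) next
    frac_by_bin <- rev(mass)[seq_len(min(n_bins, s$n))] / tot
    rows[[length(rows) + 1L]] <- data.frame(
      t_h = s$t,
      bin = seq_along(frac_by_bin),
      distance_behind_tip_um = (seq_along(frac_by_bin) - 1L) * s$dx * 1e5,
      fraction = frac_by_bin)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# parameters eligible for one-at-a-time sensitivity analysis;
# "lambda" varies the producing-zone length in whole-tank increments of NV
.sweepable <- c("lambda", "kc", "KC", "kp", "KP", "m", "omega0", "v", "psi")
.log_spaced <- c("kc", "KC", "kp", "KP")

apply_sweep_value <- function(params, parameter, value) {
  if (parameter == "lambda") {
    NV <- value / params$dx
    if (abs(NV - round(NV)) > 1e-8)
      stop("zone length ", value, " dm is not a whole number of tanks ",
           "(dx = ", params$dx, " dm)", call. = FALSE)
    params$NV <- as.integer(round(NV))
  } else {
    params[[parameter]] <- value
  }
  assert_params(params)
  params
}

sweep_grid <- function(parameter, low, high, grid_size) {
  if (low > high) stop("low must not exceed high", call. = FALSE)
  if (low == high) return(rep(low, grid_size))
  if (parameter %in% .log_spaced) {
    if (low <= 0) stop("log-spaced grid requires low > 0", call. = FALSE)
    exp(seq(log(low), log(high), length.out = grid_size))
  } else {
    seq(low, high, length.out = grid_size)
  }
}

#' Extension at a fixed horizon across parameter values
#'
#' Re-runs the model once per supplied parameter value, holding every other
#' parameter at the scenario's base value, and records the extension
#' reached at \code{t_end}.
#'
#' @param scenario a \code{"hypha_scenario"} (see \code{\link{hypha_preset}})
#'   or preset name.
#' @param parameter one of \code{"lambda"} (producing-zone length, dm,
#'   varied in whole-tank increments via \code{NV}), \code{"kc"},
#'   \code{"KC"}, \code{"kp"}, \code{"KP"}, \code{"m"}, \code{"omega0"},
#'   \code{"v"}, \code{"psi"}. \code{v = 0} is allowed (diffusion-only
#'   transport, an artificial but instructive case).
#' @param values numeric vector of parameter values, in the parameter's
#'   own units.
#' @param t_end horizon, h.
#' @param ... passed to \code{\link{simulate_hypha}}.
#' @return Data frame with columns \code{value} and \code{extension_um}.
#' @export
sweep_curve <- function(scenario, parameter, values, t_end = 24, ...) {
  scenario <- as_hypha_scenario(scenario)
  if (!parameter %in% .sweepable)
    stop("parameter must be one of: ", paste(.sweepable, collapse = ", "),
         call. = FALSE)
  ext <- vapply(values, function(val) {
    p <- apply_sweep_value(scenario$params, parameter, val)
    traj <- tryCatch(
      simulate_hypha(p, init = hypha_state(p, n = scenario$init$n),
                     t_end = t_end, sample_times = c(0, t_end), ...),
      error = function(e) stop("simulation failed at ", parameter, " = ",
                               val, ": ", conditionMessage(e),
                               call. = FALSE))
    extension_at(traj)
  }, numeric(1))
  data.frame(value = values, extension_um = ext)
}

#' One-at-a-time parameter sensitivity statistic
#'
#' Varies a single parameter over \code{[low, high]} (endpoints always
#' included; geometric spacing for the Michaelis-Menten rate and
#' saturation constants, arithmetic otherwise), records the extension at
#' \code{t_end} for each grid value, and summarizes the spread with the
#' percentage variation
#' \deqn{F = (y_{max} - y_{min}) / y_{min} \times 100\%}
#' where \eqn{y} is the length reached at \code{t_end}.
#'
#' @inheritParams sweep_curve
#' @param low,high interval bounds, in the parameter's own units
#'   (\code{"lambda"} in dm, whole tanks).
#' @param grid_size number of grid values (>= 2).
#' @return An object of class \code{"hypha_sensitivity"}: list with
#'   \code{parameter}, \code{low}, \code{high}, \code{grid},
#'   \code{lengths_um} (extension at \code{t_end} per grid value),
#'   \code{t_end} and \code{F_percent}.
#' @export
sensitivity_F <- function(scenario, parameter, low, high, grid_size = 9L,
                          t_end = 24, ...) {
  scenario <- as_hypha_scenario(scenario)
  grid <- unique(sweep_grid(parameter, low, high, grid_size))
  if (parameter == "lambda") {
    NV <- unique(round(grid / scenario$params$dx))
    NV <- NV[NV >= 1]
    grid <- NV * scenario$params$dx
  }
  sw <- sweep_curve(scenario, parameter, grid, t_end = t_end, ...)
  y <- sw$extension_um
  structure(list(parameter = parameter, low = low, high = high,
                 grid = grid, lengths_um = y, t_end = t_end,
                 F_percent = (max(y) - min(y)) / min(y) * 100),
            class = "hypha_sensitivity")
}

#' @export
print.hypha_sensitivity <- function(x, ...) {
  cat(sprintf(
    "Sensitivity of extension at %g h to '%s' over [%g, %g] (%d values)\n",
    x$t_end, x$parameter, x$low, x$high, length(x$grid)))
  cat(sprintf("  extension range: %.4g - %.4g um\n",
              min(x$lengths_um), max(x$lengths_um)))
  cat(sprintf("  F = (max - min)/min = %.4g%%\n", x$F_percent))
  invisible(x)
}

#' Default sensitivity intervals
#'
#' The parameter intervals used for the calibrated aerial-hypha
#' sensitivity analysis (base scenario \code{rhizopus_oligosporus}).
#' \code{lambda} is expressed in dm.
#'
#' @return Data frame with columns \code{parameter}, \code{low},
#'   \code{high}.
#' @export
sensitivity_intervals <- function() {
  data.frame(
    parameter = c("lambda", "kc", "KC", "kp", "KP", "m", "omega0", "v",
                  "psi"),
    low  = c(100e-5, 1.4e-8, 1,    10,   0.1, 1.8e-4, 1,  0,    0.036),
    high = c(600e-5, 9e-8,   1000, 2000, 50,  1.8e-2, 15, 0.08, 0.36))
}

#' Full sensitivity table
#'
#' Runs \code{\link{sensitivity_F}} for every parameter in
#' \code{\link{sensitivity_intervals}} (or a subset).
#'
#' @inheritParams sweep_curve
#' @param parameters character vector of parameter names; default all nine.
#' @param grid_size grid values per parameter.
#' @return Data frame with columns \code{parameter}, \code{low},
#'   \code{high}, \code{F_percent}.
#' @export
sensitivity_table <- function(scenario = "rhizopus_oligosporus",
                              parameters = NULL, grid_size = 9L,
                              t_end = 24, ...) {
  iv <- sensitivity_intervals()
  if (!is.null(parameters)) iv <- iv[iv$parameter %in% parameters, ]
  res <- lapply(seq_len(nrow(iv)), function(i)
    sensitivity_F(scenario, iv$parameter[i], iv$low[i], iv$high[i],
                  grid_size = grid_size, t_end = t_end, ...))
  data.frame(parameter = iv$parameter, low = iv$low, high = iv$high,
             F_percent = vapply(res, `[[`, numeric(1), "F_percent"))
}
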