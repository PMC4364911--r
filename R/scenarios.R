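#' Calibrated organism presets
#'
#' Returns one of the three calibrated scenarios shipped with the package:
#' \describe{
#'   \item{\code{"rhizopus_oligosporus"}}{reproductive aerial hypha,
#'     10 um tanks, 30-tank producing zone, constant source, 24 h horizon.}
#'   \item{\code{"aspergillus_giganteus"}}{tall conidiophore, 40 um tanks,
#'     40-tank producing zone, constant source, 21 h horizon.}
#'   \item{\code{"phycomyces_blakesleeanus"}}{sporangiophore (final growth
#'     stage), 150 um tanks, 5-tank producing zone, 150 initial tanks,
#'     depleting source tank of cross-section 0.025 dm^2, 110 h horizon.}
#' }
#' All presets start with zero nutrient and vesicle concentrations in every
#' hyphal tank and a normal-sized tip-tank (\code{L = dx}). Reported
#' "extension" is length gained since the start of the simulation.
#'
#' Presets are stored as plain-text configuration files under
#' \code{system.file("extdata", package = "hyphasim")} in the format of
#' \code{\link{read_hypha_config}}, and pass through the same validation as
#' user-supplied files.
#'
#' @param name one of the three scenario names above (partial matching is
#'   not applied).
#' @return An object of class \code{"hypha_scenario"}: list with
#'   \code{name}, \code{params} (\code{\link{hypha_params}}), \code{init}
#'   (\code{\link{hypha_state}}) and \code{t_end_default} (h).
#' @examples
#' sc <- hypha_preset("rhizopus_oligosporus")
#' sc$params$NV * sc$params$dx * 1e5  # producing-zone length, um
#' @export
hypha_preset <- function(name) {
  valid <- hypha_preset_names()
  if (length(name) != 1L || !name %in% valid)
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid names: ", paste(valid, collapse = ", "), call. = FALSE)
  path <- system.file("extdata", paste0(name, ".cfg"),
                      package = "hyphasim", mustWork = TRUE)
  cfg <- read_hypha_config(path)
  structure(list(name = name, params = cfg$params,
                 init = hypha_state(cfg$params, n = cfg$n0),
                 t_end_default = cfg$t_end),
            class = "hypha_scenario")
}

#' @rdname hypha_preset
#' @export
hypha_preset_names <- function() {
  c("rhizopus_oligosporus", "aspergillus_giganteus",
    "phycomyces_blakesleeanus")
}

#' @export
print.hypha_scenario <- function(x, ...) {
  cat("Hypha growth scenario:", x$name, "\n")
  cat(sprintf("  %d initial tanks, default horizon %g h, %s source\n",
              x$init$n, x$t_end_default, x$params$source_mode))
  print(x$params)
  invisible(x)
}

#' Load a scenario from a configuration file or preset name
#'
#' Convenience dispatcher used by the command-line interface: a preset name
#' is resolved with \code{\link{hypha_preset}}, anything else is treated as
#' a path to a \code{\link{read_hypha_config}} file.
#'
#' @param x preset name or config file path.
#' @return A \code{"hypha_scenario"} object.
#' @export
as_hypha_scenario <- function(x) {
  if (inherits(x, "hypha_scenario")) return(x)
  if (x %in% hypha_preset_names()) return(hypha_preset(x))
  cfg <- read_hypha_config(x)
  nm <- if (is.na(cfg$name)) tools::file_path_sans_ext(basename(x))
        else cfg$name
  structure(list(name = nm, params = cfg$params,
                 init = hypha_state(cfg$params, n = cfg$n0),
                 t_end_default = cfg$t_end),
            class = "hypha_scenario")
}
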