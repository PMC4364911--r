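#' Model parameters for a tanks-in-series hypha
#'
#' Bundles every rate, transport, yield and geometry constant of the model
#' into a validated object. All values are in the internal unit system
#' (dm, h, g); see the field list below.
#'
#' @param A hyphal cross-sectional area, dm^2 (> 0).
#' @param D nutrient diffusivity inside the hypha, dm^2 h^-1 (>= 0).
#' @param kc maximum rate of vesicle consumption at the tip,
#'   g-vesicles h^-1 (> 0).
#' @param KC saturation constant for vesicle consumption,
#'   g-vesicles dm^-3 (> 0).
#' @param kp maximum volumetric rate of vesicle production,
#'   g-vesicles dm^-3 h^-1 (>= 0).
#' @param KP saturation constant for vesicle production,
#'   g-nutrient dm^-3 (> 0).
#' @param m maintenance coefficient, g-nutrient g-biomass^-1 h^-1 (>= 0).
#' @param omega0 nutrient concentration in the source tank,
#'   g-nutrient dm^-3 (>= 0). Constant boundary value in
#'   \code{source_mode = "constant"}, initial value in \code{"depleting"}.
#' @param v intracellular convective velocity (cytoplasmic streaming),
#'   dm h^-1 (>= 0).
#' @param YL hyphal length formed per mass of vesicles consumed,
#'   dm g-vesicles^-1 (> 0).
#' @param Yphi vesicle yield on nutrient, g-vesicles g-nutrient^-1 (> 0).
#' @param dx side length of a cubic tank, dm (> 0).
#' @param NV maximum number of vesicle-producing tanks (integer >= 1).
#'   The maximum zone length is \code{lambda = NV * dx}.
#' @param rhoX biomass dry weight per volume, g-biomass dm^-3 (> 0).
#' @param psi active-transport velocity of vesicles, dm h^-1 (>= 0).
#' @param source_mode \code{"constant"} (fixed source concentration) or
#'   \code{"depleting"} (finite source tank whose concentration falls as
#'   nutrient is exported into the hypha).
#' @param A0 source-tank cross-sectional area, dm^2; required (> 0) in
#'   depleting mode, ignored otherwise.
#'
#' @return An object of class \code{"hypha_params"}: a named list of the
#'   validated fields.
#' @seealso \code{\link{validate_params}}, \code{\link{zone_length}},
#'   \code{\link{hypha_preset}}
#' @examples
#' p <- hypha_params(A = 1e-8, D = 2.48e-4, kc = 2e-8, KC = 400, kp = 1000,
#'                   KP = 10, m = 1.8e-3, omega0 = 5, v = 0.026, YL = 1e6,
#'                   Yphi = 0.5, dx = 1e-4, NV = 30, rhoX = 100, psi = 0.05)
#' zone_length(p) * 1e5  # producing-zone length in micrometres
#' @export
hypha_params <- function(A, D, kc, KC, kp, KP, m, omega0, v, YL, Yphi,
                         dx, NV, rhoX, psi,
                         source_mode = c("constant", "depleting"),
                         A0 = NA_real_) {
  source_mode <- match.arg(source_mode)
  p <- list(A = A, A0 = A0, D = D, kc = kc, KC = KC, kp = kp, KP = KP,
            m = m, omega0 = omega0, v = v, YL = YL, Yphi = Yphi,
            dx = dx, NV = as.integer(NV), rhoX = rhoX, psi = psi,
            source_mode = source_mode)
  class(p) <- "hypha_params"
  assert_params(p)
  p
}

# field -> c(kind, unit); kind "pos" strictly positive, "nn" nonnegative
.param_schema <- list(
  A      = c("pos", "dm2"),
  D      = c("nn",  "dm2_h"),
  kc     = c("pos", "g_h"),
  KC     = c("pos", "g_dm3"),
  kp     = c("nn",  "g_dm3_h"),
  KP     = c("pos", "g_dm3"),
  m      = c("nn",  "g_g_h"),
  omega0 = c("nn",  "g_dm3"),
  v      = c("nn",  "dm_h"),
  YL     = c("pos", "dm_g"),
  Yphi   = c("pos", "g_g"),
  dx     = c("pos", "dm"),
  rhoX   = c("pos", "g_dm3"),
  psi    = c("nn",  "dm_h")
)

assert_params <- function(p) {
  for (f in names(.param_schema)) {
    x <- p[[f]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
    kind <- .param_schema[[f]][1L]
    if (kind == "pos" && x <= 0)
      stop("parameter '", f, "' must be strictly positive", call. = FALSE)
    if (kind == "nn" && x < 0)
      stop("parameter '", f, "' must be nonnegative", call. = FALSE)
  }
  if (!is.integer(p$NV) || length(p$NV) != 1L || is.na(p$NV) || p$NV < 1L)
    stop("parameter 'NV' must be a positive integer", call. = FALSE)
  if (!p$source_mode %in% c("constant", "depleting"))
    stop("source_mode must be 'constant' or 'depleting'", call. = FALSE)
  if (p$source_mode == "depleting" &&
      (!is.numeric(p$A0) || !is.finite(p$A0) || p$A0 <= 0))
    stop("parameter 'A0' must be strictly positive in depleting mode",
         call. = FALSE)
  invisible(p)
}

#' Length of the vesicle-producing zone
#'
#' The maximum physical length of the sub-apical vesicle-producing zone,
#' \code{lambda = NV * dx}, in dm.
#'
#' @param params a \code{\link{hypha_params}} object.
#' @return Zone length in dm.
#' @export
zone_length <- function(params) params$NV * params$dx

#' @export
print.hypha_params <- function(x, ...) {
  cat("Hyphal growth model parameters (dm / h / g units)\n")
  num <- vapply(names(.param_schema), function(f) x[[f]], numeric(1))
  for (f in names(num))
    cat(sprintf("  %-7s %-12g %s\n", f, num[[f]],
                gsub("_", " ", .param_schema[[f]][2L])))
  cat(sprintf("  %-7s %d tanks (zone length %g um)\n", "NV", x$NV,
              zone_length(x) * 1e5))
  cat(sprintf("  source: %s", x$source_mode))
  if (x$source_mode == "depleting") cat(sprintf(" (A0 = %g dm2)", x$A0))
  cat("\n")
  invisible(x)
}

# configuration file keys carry their unit as a suffix
.config_keys <- c(
  A = "A_dm2", A0 = "A0_dm2", D = "D_dm2_h", kc = "kc_g_h",
  KC = "KC_g_dm3", kp = "kp_g_dm3_h", KP = "KP_g_dm3", m = "m_g_g_h",
  omega0 = "omega0_g_dm3", v = "v_dm_h", YL = "YL_dm_g", Yphi = "Yphi_g_g",
  dx = "dx_dm", NV = "NV_tanks", rhoX = "rhoX_g_dm3", psi = "psi_dm_h",
  source_mode = "source_mode")

#' Validate a raw configuration mapping into model parameters
#'
#' Takes a flat named list or vector of configuration values, as produced by
#' \code{\link{read_hypha_config}}, checks that every required
#' unit-annotated key is present and valid, and returns a typed
#' \code{\link{hypha_params}} object.
#'
#' @param raw named list of configuration values. Keys are the
#'   unit-annotated parameter names (e.g. \code{v_dm_h}, \code{NV_tanks},
#'   \code{source_mode}); \code{A0_dm2} is required only when
#'   \code{source_mode} is \code{"depleting"}.
#' @return A validated \code{\link{hypha_params}} object, with the implied
#'   zone length attached as attribute \code{"lambda_dm"}.
#' @export
validate_params <- function(raw) {
  raw <- as.list(raw)
  mode <- raw[["source_mode"]]
  if (is.null(mode)) mode <- "constant"
  need <- setdiff(names(.config_keys), c("A0", "source_mode"))
  if (identical(mode, "depleting")) need <- c(need, "A0")
  for (f in need) {
    key <- .config_keys[[f]]
    if (is.null(raw[[key]]))
      stop("missing configuration field '", key, "'", call. = FALSE)
  }
  unknown <- setdiff(names(raw),
                     c(.config_keys, "n0_tanks", "t_end_h", "name"))
  if (length(unknown))
    stop("unknown configuration field(s): ",
         paste(unknown, collapse = ", "),
         " (parameter keys must carry their unit suffix)", call. = FALSE)
  getn <- function(f, default = NA_real_) {
    x <- raw[[.config_keys[[f]]]]
    if (is.null(x)) return(default)
    x <- suppressWarnings(as.numeric(x))
    if (is.na(x)) stop("field '", .config_keys[[f]], "' is not numeric",
                       call. = FALSE)
    x
  }
  p <- hypha_params(
    A = getn("A"), D = getn("D"), kc = getn("kc"), KC = getn("KC"),
    kp = getn("kp"), KP = getn("KP"), m = getn("m"),
    omega0 = getn("omega0"), v = getn("v"), YL = getn("YL"),
    Yphi = getn("Yphi"), dx = getn("dx"), NV = getn("NV"),
    rhoX = getn("rhoX"), psi = getn("psi"),
    source_mode = mode, A0 = getn("A0"))
  attr(p, "lambda_dm") <- zone_length(p)
  p
}

#' Read a flat key = value configuration file
#'
#' Parses a plain-text scenario configuration: one \code{key = value} pair
#' per line, \code{#} starts a comment, keys carry their unit as a suffix
#' (e.g. \code{v_dm_h = 0.026}). Besides the model parameters the file may
#' set the initial tank count \code{n0_tanks} and a default simulation
#' horizon \code{t_end_h}.
#'
#' @param path path to the configuration file.
#' @return A list with elements \code{params} (a validated
#'   \code{\link{hypha_params}}), \code{n0} (integer, default 3),
#'   \code{t_end} (hours, default 24) and \code{name} (character or NA).
#' @seealso \code{\link{write_hypha_config}}, \code{\link{hypha_preset}}
#' @export
read_hypha_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad))
    stop("malformed config line: '", lines[bad][1L], "'", call. = FALSE)
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  if (anyDuplicated(keys))
    stop("duplicated config key: ", keys[duplicated(keys)][1L], call. = FALSE)
  raw <- as.list(vals)
  names(raw) <- keys
  name <- if (!is.null(raw$name)) raw$name else NA_character_
  n0 <- if (!is.null(raw$n0_tanks)) as.integer(raw$n0_tanks) else 3L
  t_end <- if (!is.null(raw$t_end_h)) as.numeric(raw$t_end_h) else 24
  if (is.na(n0) || n0 < 2L)
    stop("n0_tanks must be an integer >= 2", call. = FALSE)
  raw$name <- NULL
  list(params = validate_params(raw), n0 = n0, t_end = t_end, name = name)
}

#' Write a scenario configuration file
#'
#' Serializes a parameter set (plus initial tank count and default horizon)
#' in the flat \code{key = value} format read by
#' \code{\link{read_hypha_config}}. Reading the file back reproduces an
#' identical parameter set.
#'
#' @param params a \code{\link{hypha_params}} object.
#' @param path output file path.
#' @param n0 initial number of tanks.
#' @param t_end default simulation horizon, h.
#' @param name optional scenario name recorded in the file.
#' @return The path, invisibly.
#' @export
write_hypha_config <- function(params, path, n0 = 3L, t_end = 24,
                               name = NULL) {
  assert_params(params)
  fmt <- function(x) sprintf("%.17g", x)
  out <- character(0)
  if (!is.null(name)) out <- c(out, paste("name =", name))
  for (f in names(.config_keys)) {
    if (f == "source_mode") {
      out <- c(out, paste("source_mode =", params$source_mode))
    } else if (f == "A0") {
      if (params$source_mode == "depleting")
        out <- c(out, paste(.config_keys[[f]], "=", fmt(params$A0)))
    } else if (f == "NV") {
      out <- c(out, paste(.config_keys[[f]], "=", params$NV))
    } else {
      out <- c(out, paste(.config_keys[[f]], "=", fmt(params[[f]])))
    }
  }
  out <- c(out, paste("n0_tanks =", as.integer(n0)),
           paste("t_end_h =", fmt(t_end)))
  writeLines(out, path)
  invisible(path)
}
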