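#' Construct a hypha state
#'
#' The live state of the tank chain: per-tank nutrient and vesicle
#' concentrations, the current tip-tank length, the source-tank nutrient
#' concentration and the simulation clock.
#'
#' @param params a \code{\link{hypha_params}} object (supplies \code{dx} and
#'   the initial source concentration).
#' @param n number of tanks (integer >= 2); tank \code{n} is the tip-tank.
#' @param omega,phi numeric vectors of length \code{n}: nutrient and vesicle
#'   concentrations per tank, g dm^-3. Default all zero (a freshly formed
#'   hypha contains neither).
#' @param L tip-tank length, dm, in \code{[dx, 2*dx]}. Default \code{dx}.
#' @param omega_source source-tank nutrient concentration, g dm^-3.
#'   Default \code{params$omega0}.
#' @param t simulation time, h.
#' @return An object of class \code{"hypha_state"}.
#' @export
hypha_state <- function(params, n = 3L, omega = NULL, phi = NULL,
                        L = NULL, omega_source = NULL, t = 0) {
  n <- as.integer(n)
  if (is.null(omega)) omega <- rep(0, n)
  if (is.null(phi)) phi <- rep(0, n)
  if (is.null(L)) L <- params$dx
  if (is.null(omega_source)) omega_source <- params$omega0
  s <- structure(list(t = t, n = n, omega = omega, phi = phi, L = L,
                      omega_source = omega_source, dx = params$dx),
                 class = "hypha_state")
  assert_state(s)
  s
}

assert_state <- function(s, tol = 1e-8) {
  if (!is.integer(s$n) || s$n < 2L)
    stop("a hypha must contain at least 2 tanks", call. = FALSE)
  if (length(s$omega) != s$n || length(s$phi) != s$n)
    stop("omega and phi must have length n = ", s$n, call. = FALSE)
  if (any(!is.finite(s$omega)) || any(!is.finite(s$phi)) || !is.finite(s$L))
    stop("non-finite value in hypha state", call. = FALSE)
  if (s$L < s$dx * (1 - tol) || s$L > 2 * s$dx * (1 + tol))
    stop("tip-tank length L = ", s$L, " outside [dx, 2 dx]", call. = FALSE)
  if (s$omega_source < 0)
    stop("source nutrient concentration must be nonnegative", call. = FALSE)
  invisible(s)
}

#' @export
print.hypha_state <- function(x, ...) {
  cat(sprintf(
    "Hypha state at t = %g h: %d tanks, total length %.4g um\n",
    x$t, x$n, total_length(x) * 1e5))
  cat(sprintf("  tip-tank: L = %.4g um, nutrient %.4g, vesicles %.4g g/dm3\n",
              x$L * 1e5, x$omega[x$n], x$phi[x$n]))
  cat(sprintf("  source nutrient: %.4g g/dm3\n", x$omega_source))
  invisible(x)
}

#' Total hyphal length
#'
#' \code{(n - 1) * dx + L}: all normal tanks plus the variable-length
#' tip-tank, in dm.
#'
#' @param state a \code{\link{hypha_state}}.
#' @return Length in dm.
#' @export
total_length <- function(state) (state$n - 1L) * state$dx + state$L

#' Which tanks produce vesicles?
#'
#' At most \code{NV} tanks immediately behind the tip-tank convert nutrient
#' into vesicles. While the hypha is still short (\code{n <= NV + 1} tanks)
#' every intermediate tank produces; once it is longer, only the \code{NV}
#' tanks directly behind the tip do, and tanks further back fall silent.
#' The tip-tank itself never produces.
#'
#' @param n number of tanks in the hypha (>= 2).
#' @param NV maximum number of vesicle-producing tanks (>= 1).
#' @return Logical vector of length \code{n}; \code{TRUE} marks a producing
#'   tank. Exactly \code{min(n - 1, NV)} entries are \code{TRUE}.
#' @examples
#' assign_zones(3, 30)   # both intermediate tanks produce
#' which(assign_zones(50, 30))  # tanks 20..49
#' @export
assign_zones <- function(n, NV) {
  n <- as.integer(n)
  NV <- as.integer(NV)
  if (n < 2L) stop("a hypha must contain at least 2 tanks", call. = FALSE)
  if (NV < 1L) stop("NV must be a positive integer", call. = FALSE)
  producing <- rep(FALSE, n)
  np <- min(n - 1L, NV)
  producing[(n - np):(n - 1L)] <- TRUE
  producing
}

#' Divide a double-sized tip-tank
#'
#' When the tip-tank has grown to twice the normal tank length it is split
#' into two tanks of normal size. Both daughters inherit the mother tank's
#' nutrient and vesicle concentrations, the distal daughter becomes the new
#' tip-tank, and the proximal daughter becomes a vesicle-producing
#' intermediate tank. Total length and total nutrient/vesicle mass are
#' conserved exactly.
#'
#' @param state a \code{\link{hypha_state}} with \code{L} at (or within
#'   \code{tol} of) \code{2 * dx}.
#' @param tol relative tolerance on the division condition.
#' @return The post-division \code{\link{hypha_state}} with \code{n + 1}
#'   tanks and tip length \code{L - dx} (= \code{dx} when the event is hit
#'   exactly).
#' @export
divide_tip <- function(state, tol = 1e-6) {
  dx <- state$dx
  if (state$L < 2 * dx * (1 - tol))
    stop("divide_tip called with L = ", state$L,
         " below the division length 2 dx = ", 2 * dx, call. = FALSE)
  state$omega <- c(state$omega, state$omega[state$n])
  state$phi <- c(state$phi, state$phi[state$n])
  state$L <- state$L - dx
  state$n <- state$n + 1L
  state
}
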