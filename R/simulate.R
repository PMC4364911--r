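#' Simulate hyphal extension
#'
#' Event-driven integration of the tanks-in-series model. Between division
#' events the ODE system is integrated with \code{\link[deSolve]{lsodar}}
#' (adaptive BDF for this stiff system, with a banded numerically generated
#' Jacobian) while root-finding monitors the tip-tank length. When
#' \code{L} reaches \code{2 * dx} the integration stops exactly at the
#' event, \code{\link{divide_tip}} re-dimensions the state, and a fresh
#' solver segment starts from the post-division state. The trajectory is
#' sampled on \code{sample_times}; every division time is also recorded as
#' a sample.
#'
#' After the run, the extension-rate audit
#' (\code{\link{audit_extension_vs_convection}}) checks the model
#' assumption that cytoplasmic streaming is fast enough to fill the
#' extending tip: the observed extension rate must stay below the
#' convective velocity \code{v}.
#'
#' @param params a \code{\link{hypha_params}} object.
#' @param init initial \code{\link{hypha_state}}; default a fresh 3-tank
#'   hypha with zero internal concentrations and \code{L = dx}.
#' @param t_end simulation horizon, h.
#' @param sample_times output times, h (default hourly from 0 to
#'   \code{t_end}).
#' @param rel_tol,abs_tol integrator tolerances.
#' @param max_step optional bound on the internal step size, h.
#' @param engine \code{"compiled"} (C right-hand side, default) or
#'   \code{"reference"} (the R implementation in \code{\link{hypha_rhs}};
#'   identical equations, used for cross-checking).
#' @param max_tanks safety bound on the number of tanks.
#' @return An object of class \code{"hypha_trajectory"}: a list with
#'   \describe{
#'     \item{series}{data frame with columns \code{t_h}, \code{n_tanks},
#'       \code{tip_length_um}, \code{total_length_um}, \code{extension_um},
#'       \code{tip_nutrient_g_dm3}, \code{tip_vesicles_g_dm3},
#'       \code{source_nutrient_g_dm3} (lengths in micrometres,
#'       concentrations in g dm^-3).}
#'     \item{states}{list of \code{\link{hypha_state}} snapshots, one per
#'       series row.}
#'     \item{divisions}{times of the tip-division events, h.}
#'     \item{sample_times}{the requested sample grid.}
#'     \item{audit}{list \code{passed} / \code{max_ratio}, see
#'       \code{\link{audit_extension_vs_convection}}.}
#'     \item{params, init, settings}{inputs, echoed.}
#'   }
#' @examples
#' sc <- hypha_preset("rhizopus_oligosporus")
#' traj <- simulate_hypha(sc$params, t_end = 2)
#' tail(traj$series, 1)
#' @export
simulate_hypha <- function(params, init = NULL, t_end,
                           sample_times = NULL,
                           rel_tol = 1e-8, abs_tol = 1e-12,
                           max_step = Inf,
                           engine = c("compiled", "reference"),
                           max_tanks = 10000L) {
  engine <- match.arg(engine)
  assert_params(params)
  if (is.null(init)) init <- hypha_state(params)
  assert_state(init)
  if (!is.numeric(t_end) || t_end < 0)
    stop("t_end must be a nonnegative time in hours", call. = FALSE)
  if (is.null(sample_times))
    sample_times <- unique(c(seq(init$t, init$t + t_end, by = 1),
                             init$t + t_end))
  sample_times <- sort(unique(sample_times))
  if (any(sample_times < init$t - 1e-12) ||
      any(sample_times > init$t + t_end + 1e-12))
    stop("sample_times must lie in [t0, t0 + t_end]", call. = FALSE)
  if (rel_tol <= 0 || abs_tol <= 0)
    stop("tolerances must be positive", call. = FALSE)

  dx <- params$dx
  t0 <- init$t
  tstop <- t0 + t_end
  state <- init
  len0 <- total_length(init)

  snaps <- list(state)
  divisions <- numeric(0)
  teps <- max(1e-10, 1e-10 * max(1, tstop))

  while (state$t < tstop - teps) {
    if (state$n > max_tanks)
      stop("hypha exceeded max_tanks = ", max_tanks, call. = FALSE)
    n <- state$n
    y0 <- pack_state(state)
    times <- unique(sort(c(state$t,
                           sample_times[sample_times > state$t + teps &
                                        sample_times < tstop - teps],
                           tstop)))
    hmax <- if (is.finite(max_step)) max_step else NULL
    sol <- if (engine == "compiled") {
      deSolve::lsodar(y0, times, func = "hypha_derivs",
                      parms = pack_parms(params, n),
                      dllname = "hyphasim", initfunc = "hypha_initmod",
                      rootfunc = "hypha_root", nroot = 1,
                      rtol = rel_tol, atol = abs_tol, hmax = hmax,
                      jactype = "bandint", bandup = 2, banddown = 2,
                      maxsteps = 100000)
    } else {
      producing <- assign_zones(n, params$NV)
      fn <- function(t, y, p) {
        s <- unpack_state(y, n, dx, t)
        d <- hypha_rhs_core(s, params, producing)
        dy <- numeric(2L * n + 2L)
        dy[1L] <- d$domega_source
        dy[seq.int(2L, 2L * n, 2L)] <- d$domega
        dy[seq.int(3L, 2L * n + 1L, 2L)] <- d$dphi
        dy[2L * n + 2L] <- d$dL
        list(dy)
      }
      deSolve::lsodar(y0, times, fn, parms = NULL,
                      rootfunc = function(t, y, p) y[2L * n + 2L] - 2 * dx,
                      rtol = rel_tol, atol = abs_tol, hmax = hmax,
                      jactype = "bandint", bandup = 2, banddown = 2,
                      maxsteps = 100000)
    }
    istate <- attr(sol, "istate")
    if (!is.null(istate) && istate[1L] < 0)
      stop("integrator failure (istate = ", istate[1L], ") at t = ",
           sol[nrow(sol), 1L], " h with ", n, " tanks", call. = FALSE)

    tt <- sol[, 1L]
    for (r in seq_len(nrow(sol))[-1L]) {
      if (any(abs(tt[r] - sample_times) < teps))
        snaps[[length(snaps) + 1L]] <-
          unpack_state(sol[r, -1L], n, dx, tt[r])
    }
    state <- unpack_state(sol[nrow(sol), -1L], n, dx, tt[length(tt)])
    if (any(!is.finite(unlist(state[c("omega", "phi", "L")]))))
      stop("non-finite state at t = ", state$t, call. = FALSE)

    if (state$L >= 2 * dx * (1 - 1e-6) && state$t < tstop - teps) {
      divisions <- c(divisions, state$t)
      state <- divide_tip(state)
      if (!any(abs(state$t - sample_times) < teps))
        snaps[[length(snaps) + 1L]] <- state
    } else if (state$L > 2 * dx * (1 + 1e-6)) {
      stop("tip-tank length overshot the division event (L = ", state$L,
           ")", call. = FALSE)
    }
  }
  if (!any(abs(state$t - vapply(snaps, `[[`, numeric(1), "t")) < teps))
    snaps[[length(snaps) + 1L]] <- state

  ord <- order(vapply(snaps, `[[`, numeric(1), "t"))
  snaps <- snaps[ord]
  series <- do.call(rbind, lapply(snaps, function(s) {
    data.frame(t_h = s$t, n_tanks = s$n, tip_length_um = s$L * 1e5,
               total_length_um = total_length(s) * 1e5,
               extension_um = (total_length(s) - len0) * 1e5,
               tip_nutrient_g_dm3 = s$omega[s$n],
               tip_vesicles_g_dm3 = s$phi[s$n],
               source_nutrient_g_dm3 = s$omega_source)
  }))
  rownames(series) <- NULL

  traj <- structure(list(series = series, states = snaps,
                         divisions = divisions,
                         sample_times = sample_times,
                         params = params, init = init,
                         settings = list(t_end = t_end,
                                         rel_tol = rel_tol,
                                         abs_tol = abs_tol,
                                         max_step = max_step,
                                         engine = engine),
                         audit = NULL),
                    class = "hypha_trajectory")
  traj$audit <- audit_extension_vs_convection(traj, params)
  traj
}

#' @export
print.hypha_trajectory <- function(x, ...) {
  last <- x$series[nrow(x$series), ]
  cat(sprintf("Hypha trajectory: %g h, %d division events\n",
              last$t_h - x$series$t_h[1L], length(x$divisions)))
  cat(sprintf("  final: %d tanks, total length %.4g um, extension %.4g um\n",
              last$n_tanks, last$total_length_um, last$extension_um))
  cat(sprintf("  extension-rate audit: %s (max rate / v = %.3g)\n",
              if (isTRUE(x$audit$passed)) "passed" else "FAILED",
              x$audit$max_ratio))
  invisible(x)
}

#' Extension of a trajectory at a given time
#'
#' Total length minus initial total length, interpolated linearly between
#' samples, in micrometres.
#'
#' @param traj a \code{\link{simulate_hypha}} trajectory.
#' @param time time, h; default the last sample.
#' @return Extension in micrometres.
#' @export
extension_at <- function(traj, time = NULL) {
  s <- traj$series
  if (is.null(time)) return(s$extension_um[nrow(s)])
  if (time < min(s$t_h) - 1e-9 || time > max(s$t_h) + 1e-9)
    stop("time outside the trajectory span", call. = FALSE)
  approx(s$t_h, s$extension_um, xout = time, ties = "ordered")$y
}

#' Check extension rate against the convective velocity
#'
#' The model assumes that the intracellular convective flow supplies the
#' water that fills the extending tip, which requires the hyphal extension
#' rate to stay below the convective velocity \code{v}. This audit computes
#' the maximum extension rate over the sampled intervals of a trajectory
#' and compares it with \code{v}.
#'
#' @param traj a \code{\link{simulate_hypha}} trajectory.
#' @param params the \code{\link{hypha_params}} used for the run.
#' @return List with \code{passed} (\code{TRUE} iff the maximum observed
#'   extension rate is below \code{v}), \code{max_rate_dm_h}, and
#'   \code{max_ratio} (\code{max rate / v}; \code{Inf} when \code{v = 0}
#'   and the hypha extends).
#' @export
audit_extension_vs_convection <- function(traj, params) {
  s <- traj$series
  if (nrow(s) < 1L) stop("empty trajectory", call. = FALSE)
  if (nrow(s) == 1L) {
    rate <- 0
  } else {
    dt <- diff(s$t_h)
    dl <- diff(s$total_length_um) * 1e-5
    ok <- dt > 1e-12
    rate <- if (any(ok)) max(dl[ok] / dt[ok]) else 0
  }
  ratio <- if (params$v > 0) rate / params$v else if (rate > 0) Inf else 0
  list(passed = rate < params$v, max_rate_dm_h = rate, max_ratio = ratio)
}

#' Fixed-step verification integrator
#'
#' Integrates the same model with a fixed-step classical Runge-Kutta
#' scheme and a per-step division check, entirely independently of the
#' adaptive event-driven path used by \code{\link{simulate_hypha}}. Used in
#' the test suite to verify the production integrator; the step size must
#' be small enough for explicit stability (the stiffest time scale is the
#' inter-tank diffusive exchange, about \code{dx^2 / (4 D)} hours; the
#' default suits the smallest-tank preset).
#'
#' @param params a \code{\link{hypha_params}}.
#' @param init initial \code{\link{hypha_state}} (default fresh 3-tank
#'   hypha).
#' @param dt fixed step, h.
#' @param t_end horizon, h.
#' @param sample_every spacing of recorded samples, h.
#' @return A list with \code{series} (data frame \code{t_h},
#'   \code{total_length_um}, \code{extension_um}), \code{state} (final
#'   \code{\link{hypha_state}}), \code{extension_um} and
#'   \code{divisions}.
#' @export
oracle_simulate <- function(params, init = NULL, dt = 2e-5, t_end,
                            sample_every = 0.25) {
  assert_params(params)
  if (is.null(init)) init <- hypha_state(params)
  assert_state(init)
  s <- init
  dx <- params$dx
  len0 <- total_length(s)
  nstep <- ceiling(t_end / dt)
  producing <- assign_zones(s$n, params$NV)
  divisions <- numeric(0)
  out_t <- s$t
  out_len <- len0
  next_sample <- s$t + sample_every

  deriv <- function(st) hypha_rhs_core(st, params, producing)
  advance <- function(st, d, h) {
    st$omega <- st$omega + h * d$domega
    st$phi <- st$phi + h * d$dphi
    st$L <- st$L + h * d$dL
    st$omega_source <- st$omega_source + h * d$domega_source
    st
  }
  for (k in seq_len(nstep)) {
    h <- min(dt, t_end - (k - 1) * dt)
    k1 <- deriv(s)
    k2 <- deriv(advance(s, k1, h / 2))
    k3 <- deriv(advance(s, k2, h / 2))
    k4 <- deriv(advance(s, k3, h))
    s$omega <- s$omega + h / 6 *
      (k1$domega + 2 * k2$domega + 2 * k3$domega + k4$domega)
    s$phi <- s$phi + h / 6 *
      (k1$dphi + 2 * k2$dphi + 2 * k3$dphi + k4$dphi)
    s$L <- s$L + h / 6 * (k1$dL + 2 * k2$dL + 2 * k3$dL + k4$dL)
    s$omega_source <- s$omega_source + h / 6 *
      (k1$domega_source + 2 * k2$domega_source + 2 * k3$domega_source +
         k4$domega_source)
    s$t <- s$t + h
    if (max(abs(s$omega), abs(s$phi)) > 1e12)
      stop("oracle integrator unstable: reduce dt", call. = FALSE)
    if (s$L >= 2 * dx) {
      divisions <- c(divisions, s$t)
      s <- divide_tip(s)
      producing <- assign_zones(s$n, params$NV)
    }
    if (s$t >= next_sample - 1e-12 || k == nstep) {
      out_t <- c(out_t, s$t)
      out_len <- c(out_len, total_length(s))
      next_sample <- next_sample + sample_every
    }
  }
  list(series = data.frame(t_h = out_t,
                           total_length_um = out_len * 1e5,
                           extension_um = (out_len - len0) * 1e5),
       state = s,
       extension_um = (total_length(s) - len0) * 1e5,
       divisions = divisions)
}
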