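#' Michaelis-Menten rate law
#'
#' \code{rmax * c / (K + c)}, with the concentration clamped at zero from
#' below so that transient small negative excursions produced by the
#' integrator never yield a negative rate.
#'
#' @param c substrate concentration, g dm^-3 (clamped to \code{max(c, 0)}).
#' @param rmax maximum rate (any rate unit).
#' @param K half-saturation constant, g dm^-3 (> 0).
#' @return The rate, in the units of \code{rmax}; bounded in
#'   \code{[0, rmax)} and nondecreasing in \code{c}.
#' @examples
#' michaelis_menten(10, 1000, 10)  # half saturation: 500
#' @export
michaelis_menten <- function(c, rmax, K) {
  if (!is.numeric(K) || any(K <= 0))
    stop("saturation constant K must be strictly positive", call. = FALSE)
  c <- pmax(c, 0)
  rmax * c / (K + c)
}

#' Maximum possible tip extension rate
#'
#' The supremum of \code{dL/dt = YL * kc * phi / (KC + phi)} over all tip
#' vesicle concentrations, namely \code{YL * kc}.
#'
#' @param params a \code{\link{hypha_params}} object.
#' @return Rate in dm h^-1.
#' @export
max_extension_rate <- function(params) params$YL * params$kc

# The maintenance sink switches off as a tank runs out of nutrient. A hard
# on/off switch at zero makes the integrator chatter, so the shutoff is
# regularized with a saturating gate omega / (omega + eps); the
# half-saturation point sits orders of magnitude below physiological
# nutrient concentrations, so the bias is negligible and starved tanks
# settle at a small positive equilibrium instead of crossing zero.
# Must match MAINT_EPS in src/hypha.c.
.maint_eps <- 1e-4

maintenance_gate <- function(omega) {
  o <- pmax(omega, 0)
  o / (o + .maint_eps)
}

#' Time derivatives of the hypha state
#'
#' Assembles the full right-hand side of the model for a given state: the
#' nutrient and vesicle balances of every tank, the tip extension rate, and
#' (in depleting-source mode) the source-tank balance. This is the reference
#' R implementation; \code{\link{simulate_hypha}} uses an equivalent
#' compiled version by default and the two are cross-checked in the test
#' suite.
#'
#' The balances are: upwind convection of nutrient at velocity \code{v} and
#' Fickian diffusion between neighbouring tank centres; Michaelis-Menten
#' vesicle production (nutrient sink scaled by \code{1/Yphi}) in the tanks
#' flagged by \code{\link{assign_zones}}; a constant maintenance sink
#' \code{m * rhoX} that switches off smoothly as a tank's nutrient is
#' exhausted; upwind active transport of vesicles at velocity \code{psi}
#' (no vesicle diffusion); and, in the tip-tank, dilution terms
#' \code{-(x/L) dL/dt} that account for its growing volume, a
#' centre-to-centre spacing of \code{(L + dx)/2} on both sides of the last
#' interface (so the pairwise diffusive fluxes balance exactly), and
#' Michaelis-Menten vesicle consumption driving extension.
#'
#' @param state a \code{\link{hypha_state}}.
#' @param params a \code{\link{hypha_params}}.
#' @return A list with elements \code{domega}, \code{dphi} (length-n
#'   vectors, g dm^-3 h^-1), \code{dL} (dm h^-1) and \code{domega_source}
#'   (g dm^-3 h^-1; zero in constant-source mode).
#' @export
hypha_rhs <- function(state, params) {
  assert_state(state)
  producing <- assign_zones(state$n, params$NV)
  d <- hypha_rhs_core(state, params, producing)
  bad <- c(which(!is.finite(d$domega)), which(!is.finite(d$dphi)))
  if (length(bad) || !is.finite(d$dL) || !is.finite(d$domega_source))
    stop("non-finite derivative",
         if (length(bad)) paste0(" in tank ", bad[1L]), call. = FALSE)
  d
}

# unchecked work-horse shared by hypha_rhs, the reference solver engine and
# the fixed-step oracle
hypha_rhs_core <- function(state, params, producing) {
  n <- state$n
  om <- state$omega
  ph <- state$phi
  L <- state$L
  om0 <- state$omega_source
  dx <- params$dx

  omc <- pmax(om, 0)
  prod <- numeric(n)
  prod[producing] <- michaelis_menten(omc[producing], params$kp, params$KP)
  maint <- params$m * params$rhoX * maintenance_gate(om)

  dom <- numeric(n)
  dph <- numeric(n)
  up_om <- c(om0, om[-n])
  up_ph <- c(0, ph[-n])
  j <- seq_len(n - 1L)
  hgap <- (L + dx) / 2

  dom[j] <- (params$v / dx + params$D / dx^2) * (up_om[j] - om[j]) -
    prod[j] / params$Yphi - maint[j]
  if (n > 2L) {
    k <- seq_len(n - 2L)
    dom[k] <- dom[k] - (params$D / dx^2) * (om[k] - om[k + 1L])
  }
  dom[n - 1L] <- dom[n - 1L] -
    params$D / (dx * hgap) * (om[n - 1L] - om[n])
  dph[j] <- (params$psi / dx) * (up_ph[j] - ph[j]) + prod[j]

  dL <- michaelis_menten(ph[n], max_extension_rate(params), params$KC)
  dom[n] <- -(om[n] / L) * dL + (params$v / L) * om[n - 1L] +
    params$D / (L * hgap) * (om[n - 1L] - om[n]) - maint[n]
  dph[n] <- -(ph[n] / L) * dL + (params$psi / L) * ph[n - 1L] -
    michaelis_menten(ph[n], params$kc, params$KC) / (params$A * L)

  dom0 <- if (params$source_mode == "depleting") {
    -(params$A / (params$A0 * dx)) *
      (params$v * om0 + (params$D / dx) * (om0 - om[1L]))
  } else 0

  list(domega = dom, dphi = dph, dL = dL, domega_source = dom0)
}

# --- packing between a hypha_state and the solver vector ------------------
# layout (1-based): y[1] = omega_source; y[2i], y[2i+1] = omega_i, phi_i for
# i = 1..n; y[2n+2] = L. Interleaving keeps the Jacobian banded (half
# bandwidth 2), so the solver only needs a handful of rhs calls per
# numerical Jacobian regardless of the number of tanks.

pack_state <- function(state) {
  n <- state$n
  y <- numeric(2L * n + 2L)
  y[1L] <- state$omega_source
  y[seq.int(2L, 2L * n, 2L)] <- state$omega
  y[seq.int(3L, 2L * n + 1L, 2L)] <- state$phi
  y[2L * n + 2L] <- state$L
  y
}

unpack_state <- function(y, n, dx, t) {
  y <- unname(y)
  structure(list(t = t, n = n,
                 omega = y[seq.int(2L, 2L * n, 2L)],
                 phi = y[seq.int(3L, 2L * n + 1L, 2L)],
                 L = y[2L * n + 2L],
                 omega_source = y[1L],
                 dx = dx),
            class = "hypha_state")
}

# parameter vector for the compiled right-hand side (order fixed by
# src/hypha.c)
pack_parms <- function(params, n) {
  nprod <- min(n - 1L, params$NV)
  depleting <- params$source_mode == "depleting"
  c(n, nprod, params$dx, params$v, params$D, params$kp, params$KP,
    params$Yphi, params$m, params$rhoX, params$psi, params$YL, params$kc,
    params$KC, params$A, as.numeric(depleting),
    if (depleting) params$A0 else 1)
}
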