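# Shared fixtures and a memo cache so that expensive simulations run once
# per test session.

# run every file to completion even when several quantitative targets miss
testthat::set_max_fails(Inf)

.hs_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .hs_cache, inherits = FALSE))
    assign(key, force(expr), envir = .hs_cache)
  get(key, envir = .hs_cache, inherits = FALSE)
}

# the calibrated aerial-hypha parameter set, constructed directly (tests of
# the preset files compare against these values)
base_params <- function(...) {
  p <- hypha_params(A = 1e-8, D = 2.48e-4, kc = 2e-8, KC = 400, kp = 1000,
                    KP = 10, m = 1.8e-3, omega0 = 5, v = 0.026, YL = 1e6,
                    Yphi = 0.5, dx = 1e-4, NV = 30, rhoX = 100, psi = 0.05)
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  assert_params(p)
  p
}

# a random valid state for property tests (concentrations on physiological
# scales, tip length anywhere in its admissible interval)
random_state <- function(params, n = NULL) {
  if (is.null(n)) n <- sample(2:40, 1L)
  hypha_state(params, n = n,
              omega = runif(n, 0, 2 * params$omega0 + 1),
              phi = runif(n, 0, 50),
              L = runif(1, params$dx, 2 * params$dx),
              omega_source = params$omega0)
}

# full 24 h calibrated run, shared by the acceptance and analysis tests
base_run_24h <- function() {
  cached("base24", {
    sc <- hypha_preset("rhizopus_oligosporus")
    simulate_hypha(sc$params, init = sc$init, t_end = 24)
  })
}

scenario_rhizopus <- function() {
  cached("sc_rhizopus", hypha_preset("rhizopus_oligosporus"))
}

# 6 h calibrated run, shared by the analysis tests
rhiz_run_6h <- function() {
  cached("rhiz6h", {
    sc <- scenario_rhizopus()
    simulate_hypha(sc$params, init = sc$init, t_end = 6)
  })
}

v0_run_24h <- function() {
  cached("v0_24", {
    sc <- scenario_rhizopus()
    p <- sc$params
    p$v <- 0
    simulate_hypha(p, init = hypha_state(p, n = sc$init$n), t_end = 24)
  })
}

aspergillus_run <- function() {
  cached("asp_full", {
    sc <- hypha_preset("aspergillus_giganteus")
    simulate_hypha(sc$params, init = sc$init, t_end = sc$t_end_default)
  })
}

phycomyces_run <- function() {
  cached("phy_full", {
    sc <- hypha_preset("phycomyces_blakesleeanus")
    simulate_hypha(sc$params, init = sc$init, t_end = sc$t_end_default)
  })
}

# cached sensitivity result over the default interval for one parameter;
# slightly loosened tolerances keep the full table within the time budget
# (the F statistics change by far less than the acceptance margins, as the
# tolerance-tightening test in test-simulate.R quantifies)
cached_sensitivity <- function(parameter, grid_size = 9L) {
  iv <- sensitivity_intervals()
  row <- iv[iv$parameter == parameter, ]
  cached(paste0("sens_", parameter, "_", grid_size),
         sensitivity_F(scenario_rhizopus(), parameter, row$low, row$high,
                       grid_size = grid_size,
                       rel_tol = 1e-6, abs_tol = 1e-10))
}

# mass-balance residuals of the right-hand side on one state: the rate of
# change of total nutrient / vesicle mass must equal boundary influx minus
# reaction sinks (the internal transport fluxes telescope away)
mass_balance_residuals <- function(state, params) {
  d <- hypha_rhs(state, params)
  n <- state$n
  A <- params$A
  vol <- rep(A * params$dx, n)
  vol[n] <- A * state$L
  producing <- assign_zones(n, params$NV)
  prod <- numeric(n)
  prod[producing] <- michaelis_menten(pmax(state$omega[producing], 0),
                                      params$kp, params$KP)
  maint <- params$m * params$rhoX *
    hyphasim:::maintenance_gate(state$omega)
  influx <- A * (params$v * state$omega_source +
                 (params$D / params$dx) *
                   (state$omega_source - state$omega[1L]))
  cons <- michaelis_menten(state$phi[n], params$kc, params$KC)

  dmass_om <- sum(vol * d$domega) + A * d$dL * state$omega[n]
  dmass_ph <- sum(vol * d$dphi) + A * d$dL * state$phi[n]
  list(
    nutrient = dmass_om -
      (influx - sum(vol * (prod / params$Yphi + maint))),
    vesicle = dmass_ph - (sum(vol * prod) - cons))
}
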