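test_that("michaelis_menten matches hand-evaluated values", {
  expect_equal(michaelis_menten(0, 1000, 10), 0)
  expect_equal(michaelis_menten(10, 1000, 10), 500)   # half saturation
  expect_equal(michaelis_menten(30, 1000, 10), 750)
  # clamped below zero, bounded by rmax, nondecreasing
  expect_equal(michaelis_menten(-5, 1000, 10), 0)
  cc <- seq(0, 1e4, length.out = 200)
  r <- michaelis_menten(cc, 1000, 10)
  expect_true(all(r >= 0 & r < 1000))
  expect_true(all(diff(r) >= 0))
  expect_error(michaelis_menten(1, 1000, 0), "strictly positive")
})

test_that("maximum extension rate is YL * kc", {
  expect_equal(max_extension_rate(base_params()), 0.02)  # dm/h
})

test_that("tank-1 derivative from the all-zero state matches hand value", {
  # all concentrations zero, calibrated parameters: tank 1 only receives
  # convection + diffusion from the source, v/dx * w0 + D/dx^2 * w0
  #   = 260 * 5 + 24800 * 5 = 125300 g dm^-3 h^-1
  p <- base_params()
  s <- hypha_state(p, n = 3L)
  d <- hypha_rhs(s, p)
  expect_equal(d$domega[1], 125300, tolerance = 1e-10)
  # no vesicles anywhere yet, tip does not extend
  expect_equal(d$dphi, rep(0, 3))
  expect_equal(d$dL, 0)
  expect_equal(d$domega_source, 0)
})

test_that("uniform nutrient with no sinks is stationary away from the tip", {
  # with production and maintenance switched off, a uniform nutrient
  # profile has zero net transport into every non-tip tank; the tip-tank
  # still gains mass through convective inflow (no convective outflow), so
  # it is only stationary when v = 0
  p <- base_params(kp = 0, m = 0)
  s <- hypha_state(p, n = 10L, omega = rep(5, 10), L = 1.3 * p$dx)
  d <- hypha_rhs(s, p)
  expect_equal(d$domega[1:9], rep(0, 9), tolerance = 1e-12)
  expect_gt(d$domega[10], 0)
  expect_equal(d$domega[10], p$v / s$L * 5, tolerance = 1e-12)

  p0 <- base_params(kp = 0, m = 0, v = 0)
  d0 <- hypha_rhs(s, p0)
  expect_equal(d0$domega, rep(0, 10), tolerance = 1e-12)
})

test_that("production is confined to the producing zone", {
  p <- base_params(NV = 5L)
  n <- 20L
  s <- hypha_state(p, n = n, omega = rep(5, n), L = p$dx)
  d <- hypha_rhs(s, p)
  # producing tanks 15..19 gain vesicles; silent interior tanks do not
  expect_true(all(d$dphi[15:19] > 0))
  expect_equal(d$dphi[2:14], rep(0, 13))
})

test_that("rhs conserves mass up to boundary flux and reaction terms", {
  set.seed(7)
  for (mode in c("constant", "depleting")) {
    p <- base_params()
    if (mode == "depleting") {
      p$source_mode <- "depleting"
      p$A0 <- 0.025
    }
    for (rep in 1:20) {
      s <- random_state(p)
      res <- mass_balance_residuals(s, p)
      scale <- p$A * total_length(s) * 100  # typical mass-rate magnitude
      expect_lt(abs(res$nutrient), 1e-10 * scale)
      expect_lt(abs(res$vesicle), 1e-10 * scale)
    }
  }
})

test_that("depleting source loses exactly the mass exported to tank 1", {
  p <- base_params()
  p$source_mode <- "depleting"
  p$A0 <- 0.025
  set.seed(11)
  s <- random_state(p, n = 8L)
  d <- hypha_rhs(s, p)
  outflux <- p$A * (p$v * s$omega_source +
                    (p$D / p$dx) * (s$omega_source - s$omega[1]))
  expect_equal(d$domega_source * p$A0 * p$dx, -outflux, tolerance = 1e-12)
})

test_that("compiled and reference engines agree on a growing hypha", {
  p <- base_params()
  tc <- simulate_hypha(p, t_end = 3, sample_times = 0:3,
                       engine = "compiled")
  tr <- simulate_hypha(p, t_end = 3, sample_times = 0:3,
                       engine = "reference")
  expect_equal(tc$series$extension_um, tr$series$extension_um,
               tolerance = 1e-6)
  expect_identical(length(tc$divisions), length(tr$divisions))
  sc <- tc$states[[length(tc$states)]]
  sr <- tr$states[[length(tr$states)]]
  expect_equal(sc$omega, sr$omega, tolerance = 1e-6)
  expect_equal(sc$phi, sr$phi, tolerance = 1e-6)
})

test_that("rhs errors name the offending tank on non-finite input", {
  p <- base_params()
  s <- hypha_state(p, n = 4L, omega = c(1, 1, 1, 1))
  s$omega[2] <- Inf
  expect_error(hypha_rhs(s, p), "non-finite")
})

test_that("state packing round-trips", {
  p <- base_params()
  set.seed(3)
  s <- random_state(p, n = 12L)
  y <- hyphasim:::pack_state(s)
  expect_length(y, 2 * 12 + 2)
  s2 <- hyphasim:::unpack_state(y, s$n, s$dx, s$t)
  expect_equal(s2[c("omega", "phi", "L", "omega_source")],
               s[c("omega", "phi", "L", "omega_source")])
})
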