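test_that("spatial_profile at t = 0 is the zero initial condition", {
  p <- base_params()
  traj <- simulate_hypha(p, t_end = 2, sample_times = c(0, 1, 2))
  pr <- spatial_profile(traj, 0)
  expect_identical(nrow(pr), 3L)
  expect_equal(pr$nutrient_g_dm3, rep(0, 3))
  expect_equal(pr$vesicles_g_dm3, rep(0, 3))
  # tank centres at 5, 15 um; tip centre at 20 + L/2 = 25 um
  expect_equal(pr$position_um, c(5, 15, 25))
  expect_error(spatial_profile(traj, 3), "outside")
})

test_that("profile positions are base-anchored and ordered", {
  traj <- rhiz_run_6h()
  pr <- spatial_profile(traj, 6)
  expect_true(all(diff(pr$position_um) > 0))
  expect_identical(nrow(pr), attr(pr, "n_tanks"))
  s <- traj$series
  expect_equal(max(pr$position_um),
               s$total_length_um[nrow(s)] - s$tip_length_um[nrow(s)] / 2)
})

test_that("nutrient decreases from base towards the tip", {
  # monotone nonincreasing along the normal tanks; the tip-tank itself can
  # sit marginally above its neighbour (it has convective inflow but no
  # convective outflow), so it is only required to stay below the base
  traj <- rhiz_run_6h()
  for (tm in c(2, 4, 6)) {
    pr <- spatial_profile(traj, tm)
    w <- pr$nutrient_g_dm3
    n <- length(w)
    # strictly nonincreasing over the bulk of the chain
    expect_true(all(diff(w[1:floor(0.9 * n)]) <= 1e-9),
                info = paste("t =", tm))
    # the tip coupling may lift the last tanks by well under a percent
    expect_true(all(diff(w) <= 2e-3 * max(w)), info = paste("t =", tm))
    expect_lt(w[n], w[1])
  }
})

test_that("vesicles vanish behind the producing zone", {
  traj <- rhiz_run_6h()
  p <- traj$params
  pr <- spatial_profile(traj, 6)
  behind <- max(pr$position_um) - pr$position_um  # um behind tip centre
  far <- behind > (zone_length(p) + p$dx) * 1e5
  expect_true(any(far))
  expect_true(all(pr$vesicles_g_dm3[far] < 1e-6 * max(pr$vesicles_g_dm3)))
})

test_that("vesicle fractions: tip-only state gives fraction 1", {
  p <- base_params()
  s <- hypha_state(p, n = 5L, phi = c(0, 0, 0, 0, 10), L = 1.2 * p$dx)
  fake <- list(states = list(s), sample_times = 0, params = p)
  fr <- tip_vesicle_fractions(fake, n_bins = 3L, times = 0)
  expect_equal(fr$fraction[fr$bin == 1], 1)
  expect_equal(fr$fraction[fr$bin %in% 2:3], c(0, 0))
  expect_equal(fr$distance_behind_tip_um, c(0, 10, 20))
})

test_that("vesicle fractions sum to one over all tanks", {
  traj <- rhiz_run_6h()
  fr <- tip_vesicle_fractions(traj, n_bins = 10000L)
  sums <- as.vector(tapply(fr$fraction, fr$t_h, sum))
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-9)
  expect_true(all(fr$fraction >= 0 & fr$fraction <= 1))
})

test_that("zero-mass samples are skipped", {
  traj <- rhiz_run_6h()
  fr <- tip_vesicle_fractions(traj)  # t = 0 has no vesicles anywhere
  expect_false(0 %in% fr$t_h)
  expect_error(tip_vesicle_fractions(list(states = list())), "empty")
})

test_that("sweep grids: spacing rules and degenerate interval", {
  g <- hyphasim:::sweep_grid("omega0", 1, 15, 9)
  expect_equal(g, seq(1, 15, length.out = 9))
  gl <- hyphasim:::sweep_grid("kp", 10, 2000, 9)
  expect_equal(diff(log(gl)), rep(diff(log(c(10, 2000))) / 8, 8))
  expect_equal(range(gl), c(10, 2000))
  expect_equal(hyphasim:::sweep_grid("v", 0.02, 0.02, 9), rep(0.02, 9))
  expect_error(hyphasim:::sweep_grid("v", 1, 0, 9), "must not exceed")
  expect_error(hyphasim:::sweep_grid("kp", 0, 10, 9), "low > 0")
})

test_that("lambda sweeps move in whole-tank increments", {
  p <- base_params()
  p2 <- hyphasim:::apply_sweep_value(p, "lambda", 20e-4)
  expect_identical(p2$NV, 20L)
  expect_error(hyphasim:::apply_sweep_value(p, "lambda", 2.05e-3),
               "whole number of tanks")
  p3 <- hyphasim:::apply_sweep_value(p, "v", 0)
  expect_equal(p3$v, 0)
  expect_error(hyphasim:::apply_sweep_value(p, "KC", -1),
               "strictly positive")
})

test_that("sweep_curve rejects unknown parameters and reports failures", {
  sc <- scenario_rhizopus()
  expect_error(sweep_curve(sc, "YL", 1), "must be one of")
  expect_error(
    suppressWarnings(sweep_curve(sc, "kp", 2000, t_end = 2,
                                 max_tanks = 4L)),
    "simulation failed at kp = 2000")
})

test_that("degenerate sensitivity interval gives F = 0", {
  sc <- scenario_rhizopus()
  res <- sensitivity_F(sc, "v", 0.026, 0.026, t_end = 0.5)
  expect_equal(res$F_percent, 0)
  expect_length(res$grid, 1L)
})

test_that("sensitivity intervals table covers the nine parameters", {
  iv <- sensitivity_intervals()
  expect_setequal(iv$parameter, hyphasim:::.sweepable)
  expect_true(all(iv$low < iv$high))
})
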