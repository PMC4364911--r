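test_that("t_end = 0 returns the initial state only", {
  p <- base_params()
  traj <- simulate_hypha(p, t_end = 0, sample_times = 0)
  expect_identical(nrow(traj$series), 1L)
  expect_equal(traj$series$extension_um, 0)
  expect_length(traj$divisions, 0)
})

test_that("input validation", {
  p <- base_params()
  expect_error(simulate_hypha(p, t_end = -1), "nonnegative")
  expect_error(simulate_hypha(p, t_end = 1, sample_times = c(0, 2)),
               "sample_times")
  expect_error(simulate_hypha(p, t_end = 1, rel_tol = 0), "positive")
})

test_that("short run: divisions re-dimension the state and keep invariants", {
  p <- base_params()
  traj <- simulate_hypha(p, t_end = 6)
  s <- traj$series
  expect_gt(length(traj$divisions), 0)
  # one more tank per division
  expect_identical(s$n_tanks[nrow(s)], 3L + length(traj$divisions))
  # L stays within [dx, 2 dx] at every snapshot (relative slack for the
  # root-finding tolerance)
  for (st in traj$states) {
    expect_gte(st$L, p$dx * (1 - 1e-6))
    expect_lte(st$L, 2 * p$dx * (1 + 1e-6))
  }
  # total length never decreases
  expect_true(all(diff(s$total_length_um) >= -1e-9))
  # total length is consistent with tank count and tip length
  expect_equal(s$total_length_um,
               (s$n_tanks - 1) * p$dx * 1e5 + s$tip_length_um)
  # division times recorded as snapshots
  expect_true(all(vapply(traj$divisions, function(td)
    any(abs(s$t_h - td) < 1e-9), logical(1))))
})

test_that("division snapshots conserve length across the event", {
  p <- base_params()
  traj <- simulate_hypha(p, t_end = 4)
  ts <- vapply(traj$states, `[[`, numeric(1), "t")
  for (td in traj$divisions) {
    idx <- which(abs(ts - td) < 1e-12)
    # the post-division snapshot has tip length ~ dx
    post <- traj$states[[idx[length(idx)]]]
    expect_equal(post$L, p$dx, tolerance = 1e-5)
  }
})

test_that("fixed-step oracle agrees with the adaptive integrator", {
  p <- base_params()
  adaptive <- simulate_hypha(p, t_end = 2, sample_times = c(0, 2))
  oracle <- oracle_simulate(p, dt = 2e-5, t_end = 2)
  expect_lt(abs(extension_at(adaptive, 2) - oracle$extension_um) /
              oracle$extension_um, 0.005)
  expect_identical(length(adaptive$divisions), length(oracle$divisions))
})

test_that("solution is insensitive to tolerance tightening", {
  p <- base_params()
  loose <- simulate_hypha(p, t_end = 6, sample_times = c(0, 6),
                          rel_tol = 1e-6, abs_tol = 1e-10)
  tight <- simulate_hypha(p, t_end = 6, sample_times = c(0, 6))
  e1 <- extension_at(loose, 6)
  e2 <- extension_at(tight, 6)
  expect_lt(abs(e1 - e2) / e2, 1e-3)
})

test_that("trajectory restarts compose: 3 h + 3 h equals 6 h", {
  p <- base_params()
  whole <- simulate_hypha(p, t_end = 6, sample_times = c(0, 3, 6))
  first <- simulate_hypha(p, t_end = 3, sample_times = c(0, 3))
  mid <- first$states[[length(first$states)]]
  second <- simulate_hypha(p, init = mid, t_end = 3,
                           sample_times = mid$t + c(0, 3))
  lw <- whole$series$total_length_um[whole$series$t_h == 6]
  ls <- second$series$total_length_um[nrow(second$series)]
  expect_lt(abs(lw - ls) / lw, 1e-5)
})

test_that("depleting source is monotone decreasing and reaches the chain", {
  p <- base_params()
  p$source_mode <- "depleting"
  p$A0 <- 1e-6  # small reservoir so depletion is visible quickly
  traj <- simulate_hypha(p, t_end = 4)
  src <- traj$series$source_nutrient_g_dm3
  expect_true(all(diff(src) <= 1e-12))
  expect_lt(src[length(src)], p$omega0)
  expect_gte(min(src), -1e-8)
})

test_that("extension-rate audit compares growth with convection", {
  p <- base_params()
  traj <- simulate_hypha(p, t_end = 6)
  expect_true(traj$audit$passed)
  expect_lt(traj$audit$max_ratio, 1)
  # with v = 0 any growth must fail the audit
  p0 <- base_params(v = 0)
  tr0 <- simulate_hypha(p0, t_end = 6)
  expect_false(tr0$audit$passed)
  expect_identical(tr0$audit$max_ratio, Inf)
})

test_that("extension_at interpolates within the sampled span", {
  p <- base_params()
  traj <- simulate_hypha(p, t_end = 4)
  e2 <- extension_at(traj, 2)
  expect_gt(e2, 0)
  expect_lt(e2, extension_at(traj, 4))
  expect_equal(extension_at(traj), extension_at(traj, 4))
  expect_error(extension_at(traj, 5), "outside")
})

test_that("max_tanks guard stops runaway growth", {
  p <- base_params()
  expect_error(simulate_hypha(p, t_end = 6, max_tanks = 5L), "max_tanks")
})
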