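test_that("per-event released heat follows gamma*dA - delta_epsilon", {
  pp <- channel_params(energy_mode = "as_printed")
  expect_equal(event_heat_released(pp, 2.5, "opening"), 12 * 2.5 - 22)
  expect_equal(event_heat_released(pp, 2.5, "opening"), 8)
  expect_equal(event_heat_released(pp, 2.5, "closing"), -8)
  expect_equal(event_heat_released(pp, 22 / 12, "opening"), 0,
               tolerance = 1e-12)
  pk <- default_params()
  expect_equal(event_heat_released(pk, 2.3, 1L),
               12 * 2.3 - log(9897 / 4e-6), tolerance = 1e-12)
  expect_equal(event_heat_released(pk, 2.3, 1L), 5.97079684, tolerance = 1e-6)
})

test_that("trajectory heat sums scored events; flicker pairs lose delta_eps", {
  pp <- channel_params(energy_mode = "as_printed")
  pr <- make_erasure_ramp(1.9, 3, 1)
  tr <- manual_trajectory(pr, times = c(0.2, 0.6), directions = c(1L, -1L))
  g <- tension_at(pr, c(0.2, 0.6))
  expect_equal(trajectory_heat(pp, tr), 12 * (g[1] - g[2]))
  # the pair heat is independent of delta_epsilon
  pk <- default_params()
  expect_equal(trajectory_heat(pk, tr), trajectory_heat(pp, tr))
  empty <- manual_trajectory(pr, numeric(0), integer(0))
  expect_equal(trajectory_heat(pp, empty), 0)
  one <- manual_trajectory(pr, 0.5, 1L)
  expect_equal(trajectory_heat(pp, one), 12 * tension_at(pr, 0.5) - 22)
})

test_that("trajectory work integrates -dA * sigma dgamma over open stretches", {
  pp <- channel_params(energy_mode = "as_printed")
  pr <- make_erasure_ramp(1.9, 3, 1)
  closed <- manual_trajectory(pr, numeric(0), integer(0), initial_state = 0L)
  expect_equal(trajectory_work(pp, closed), 0)
  open_all <- manual_trajectory(pr, numeric(0), integer(0), initial_state = 1L)
  expect_equal(trajectory_work(pp, open_all), -12 * 1.1)
  expect_equal(trajectory_work(pp, open_all), -13.2)
  # open only over a gamma sub-interval of width 0.5
  t1 <- (2.0 - 1.9) / 1.1
  t2 <- (2.5 - 1.9) / 1.1
  sub <- manual_trajectory(pr, c(t1, t2), c(1L, -1L))
  expect_equal(trajectory_work(pp, sub), -12 * 0.5, tolerance = 1e-9)
})

test_that("energy change reflects endpoint states and tensions", {
  pp <- channel_params(energy_mode = "as_printed")
  pr <- make_erasure_ramp(1.9, 3, 1)
  closed <- manual_trajectory(pr, numeric(0), integer(0))
  expect_equal(trajectory_delta_H(pp, closed), 0)
  opens <- manual_trajectory(pr, 0.5, 1L)
  expect_equal(trajectory_delta_H(pp, opens), 22 - 36)
  open_all <- manual_trajectory(pr, numeric(0), integer(0), initial_state = 1L)
  expect_equal(trajectory_delta_H(pp, open_all), -12 * 1.1)
})

test_that("first law holds exactly for simulated trajectories and flags
           corrupted records", {
  p <- default_params()
  pr <- make_restore_to_open(midpoint_tension(p), 3, erase_s = 1)
  set.seed(21)
  ens <- simulate_ensemble(p, pr, 200, init_mode = "fixed_closed")
  res <- vapply(ens, function(tr) first_law_residual(thermo_record(p, tr)),
                numeric(1))
  expect_true(all(res < 1e-9))
  rec <- thermo_record(p, ens[[1]])
  expect_equal(rec$heat_released, sum(rec$event_heats))
  rec$work <- rec$work + 0.5
  expect_gt(first_law_residual(rec), 0.4)
  empty <- manual_trajectory(pr, numeric(0), integer(0))
  expect_equal(first_law_residual(thermo_record(p, empty)), 0)
})

test_that("binary Shannon entropy has the one-bit endpoints", {
  expect_equal(shannon_entropy(0.5), log(2))
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(0), 0)
  expect_equal(shannon_entropy(0.25), 0.562335144618808, tolerance = 1e-12)
  expect_equal(shannon_entropy(0.3), shannon_entropy(0.7))
  expect_error(shannon_entropy(1.2), "probability")
})

test_that("ensemble summaries report both averaging conventions coherently", {
  pp <- channel_params(energy_mode = "as_printed")
  pr <- make_erasure_ramp(1.9, 3, 1)
  tr <- manual_trajectory(pr, 0.5, 1L)
  s <- summarize_ensemble(pp, list(tr, tr, tr))
  expect_equal(s$sem_heat, 0)
  expect_equal(s$n_events, 3)
  expect_equal(s$mean_heat_released, s$mean_heat_per_event)
  expect_equal(sum(s$heat_histogram$counts), s$n_realizations)
  expect_equal(sum(s$event_heat_histogram$counts), s$n_events)
  expect_equal(s$erase_duration, 1)
  # bound from equilibrium endpoint occupancies, below the idealized ln 2
  expect_lt(s$landauer_bound, log(2))
  expect_equal(s$landauer_bound,
               shannon_entropy(equilibrium_popen(pp, 1.9)) -
                 shannon_entropy(equilibrium_popen(pp, 3)))
  empty <- manual_trajectory(pr, numeric(0), integer(0))
  s0 <- summarize_ensemble(pp, list(empty))
  expect_equal(s0$n_events, 0)
  expect_equal(s0$mean_heat_released, 0)
  expect_true(is.na(s0$sem_heat))
})

test_that("finite-time constant fit recovers planted ln2 + C/tau laws", {
  mk <- function(tau, heat) {
    s <- list(erase_duration = tau, mean_heat_released = heat)
    class(s) <- "ensemble_summary"
    s
  }
  taus <- c(0.25, 1, 5, 10, 100)
  exact <- lapply(taus, function(t) mk(t, log(2) + 2 / t))
  fit <- fit_finite_time_constant(exact)
  expect_equal(fit$C, 2, tolerance = 1e-12)
  expect_true(all(abs(fit$residuals) < 1e-12))
  flat <- lapply(taus, function(t) mk(t, log(2)))
  expect_equal(fit_finite_time_constant(flat)$C, 0)
})
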