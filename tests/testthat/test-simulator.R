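test_that("constant-rate inversion returns E/k on a hold segment", {
  p <- default_params()
  pr <- tension_protocol(data.frame(duration = 10, start = 1.9, end = 1.9))
  seg <- pr$segments[1, ]
  k <- opening_rate(p, 1.9)
  expect_equal(sample_transition_time(p, 0, seg, 0, exp_draw = k * 0.4), 0.4)
  # survival: draw beyond the segment hazard
  expect_true(is.na(sample_transition_time(p, 0, seg, 0,
                                           exp_draw = k * 10 + 1)))
  expect_error(sample_transition_time(p, 0, seg, 11), "within the segment")
})

test_that("bounded hazard on a falling rate means guaranteed survival", {
  p <- default_params()
  # open state on a rising ramp: closing rate decays, hazard is bounded
  pr <- make_erasure_ramp(1.8, 3, 1)
  seg <- pr$segments[1, ]
  A <- closing_rate(p, 1.8)
  B <- p$area_open_to_barrier * seg$slope
  expect_true(is.na(sample_transition_time(p, 1, seg, 0,
                                           exp_draw = A / abs(B) + 0.01)))
})

test_that("first-opening tension quantiles match the integrated-hazard oracle", {
  p <- default_params()
  gmid <- midpoint_tension(p)
  pr <- make_erasure_ramp(gmid, 3, 0.25)
  med_oracle <- ramp_first_transition_quantile(p, 0, gmid, 3, 0.25, 0.5)
  expect_equal(med_oracle, 2.23225868291894, tolerance = 1e-10)
  set.seed(42)
  ens <- simulate_ensemble(p, pr, 4000, init_mode = "fixed_closed")
  first <- vapply(ens, function(tr) tr$tensions[1], numeric(1))
  expect_lt(abs(stats::median(first) - med_oracle), 0.02)
  q90 <- ramp_first_transition_quantile(p, 0, gmid, 3, 0.25, 0.9)
  expect_lt(abs(stats::quantile(first, 0.9) - q90), 0.03)
})

test_that("trajectories alternate states and carry consistent tensions", {
  p <- default_params()
  pr <- make_restore_to_open(midpoint_tension(p), 3, erase_s = 1)
  set.seed(3)
  ens <- simulate_ensemble(p, pr, 50, init_mode = "fixed_closed")
  for (tr in ens) {
    expect_true(all(diff(tr$times) > 0))
    if (length(tr$directions)) {
      expect_equal(tr$directions[1], 1L)  # closed channel opens first
      expect_true(all(abs(diff(tr$directions)) == 2))
      expect_equal(tr$tensions, tension_at(pr, tr$times), tolerance = 1e-12)
    }
  }
})

test_that("zero rates yield an event-free trajectory", {
  p <- channel_params(k_open_0 = 1e-300, k_close_0 = 1e-300,
                      delta_epsilon = 0)
  pr <- make_erasure_ramp(1.8, 3, 1)
  set.seed(1)
  tr <- simulate_trajectory(p, pr, 0L)
  expect_length(tr$times, 0)
})

test_that("hold-protocol occupancy matches the Boltzmann equilibrium", {
  p <- default_params()
  g <- 2.0
  pr <- tension_protocol(data.frame(duration = 40, start = g, end = g))
  set.seed(7)
  ens <- simulate_ensemble(p, pr, 400, init_mode = "equilibrium_at_start")
  # fraction of time open, pooled across channels
  fro <- vapply(ens, function(tr) {
    bnd <- c(0, tr$times, 40)
    st <- (tr$initial_state + seq(0, length(tr$times))) %% 2
    sum(diff(bnd)[st == 1]) / 40
  }, numeric(1))
  peq <- equilibrium_popen(p, g)
  se <- stats::sd(fro) / sqrt(length(fro))
  expect_lt(abs(mean(fro) - peq), 3 * se + 1e-3)
})

test_that("waiting times on a hold are exponential with the stated rate", {
  p <- default_params()
  gmid <- midpoint_tension(p)
  pr <- tension_protocol(data.frame(duration = 200, start = gmid, end = gmid))
  set.seed(5)
  tr <- simulate_trajectory(p, pr, 0L)
  ev <- gating_events(tr)
  open_sojourn <- diff(tr$times)[tr$directions[-length(tr$times)] == 1L]
  ks <- suppressWarnings(
    stats::ks.test(open_sojourn, "pexp", rate = closing_rate(p, gmid)))
  expect_gt(ks$p.value, 0.01)
})

test_that("occupancy relaxation after a tension step follows the two-state law", {
  p <- default_params()
  g0 <- midpoint_tension(p)
  g1 <- 2.1
  # near-instantaneous (1 ms) ramp to g1, then a hold: a tension step
  pr <- tension_protocol(data.frame(duration = c(0.001, 3),
                                    start = c(g0, g1), end = c(g1, g1)))
  set.seed(9)
  ens <- simulate_ensemble(p, pr, 1500, init_mode = "bernoulli", p = 0.5)
  tg <- seq(0.05, 2.5, by = 0.05)
  occ <- mean_occupancy(ens, tg)
  ko <- opening_rate(p, g1); kc <- closing_rate(p, g1)
  peq <- ko / (ko + kc)
  pred <- peq + (0.5 - peq) * exp(-(ko + kc) * (tg - 0.001))
  se <- sqrt(pred * (1 - pred) / length(ens))
  expect_true(all(abs(occ - pred) < 3.5 * se + 0.01))
})

test_that("ensembles are reproducible and draw the maximal-uncertainty bit", {
  p <- default_params()
  pr <- make_erasure_ramp(midpoint_tension(p), 3, 0.25)
  e1 <- simulate_ensemble(p, pr, 300, seed = 123)
  e2 <- simulate_ensemble(p, pr, 300, seed = 123)
  expect_identical(lapply(e1, `[[`, "times"), lapply(e2, `[[`, "times"))
  init <- vapply(e1, `[[`, integer(1), "initial_state")
  expect_lt(abs(mean(init) - 0.5), 3 * sqrt(0.25 / 300) + 0.01)
  expect_error(simulate_ensemble(p, pr, 10, init_mode = "bernoulli", p = 2),
               "p in")
})

test_that("mean occupancy tracks equilibrium under quasi-static driving", {
  p <- default_params()
  pr <- make_erasure_ramp(midpoint_tension(p), 3, 50)
  set.seed(13)
  ens <- simulate_ensemble(p, pr, 500, init_mode = "equilibrium_at_start")
  tg <- seq(0, 50, by = 2.5)
  occ <- mean_occupancy(ens, tg)
  peq <- equilibrium_popen(p, tension_at(pr, tg))
  expect_true(all(abs(occ - peq) < 3 * sqrt(peq * (1 - peq) / 500) + 0.02))
  one <- mean_occupancy(ens[1], tg)
  expect_true(all(one %in% c(0, 1)))
  expect_error(mean_occupancy(list(), tg), "empty")
})
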