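# Independent oracles and hand-built fixtures used across the suite.

default_params <- function(...) channel_params(...)

# Quantile of the first-transition tension on a single linear ramp,
# obtained by numerically inverting the integrated hazard
# Lambda(t) = A*(exp(B*t)-1)/B (independent of the closed-form sampler).
ramp_first_transition_quantile <- function(params, state, gamma_start,
                                           gamma_end, ramp_s, q) {
  slope <- (gamma_end - gamma_start) / ramp_s
  if (state == 0) {
    a <- params$area_closed_to_barrier; k0 <- params$k_open_0
  } else {
    a <- params$area_open_to_barrier; k0 <- params$k_close_0
  }
  A <- k0 * exp(a * gamma_start)
  B <- a * slope
  target <- -log(1 - q)
  f <- function(t) A * expm1(B * t) / B - target
  t_q <- stats::uniroot(f, c(0, ramp_s), tol = 1e-14)$root
  gamma_start + slope * t_q
}

# Fine-grained Bernoulli-chain oracle for the first-opening tension on a
# ramp: the per-step transition probabilities k(t_i)*dt define a discrete
# first-passage distribution that is sampled exactly (categorical draw),
# which is equivalent to stepping the chain at resolution dt.
discretized_first_opening_sample <- function(params, gamma_start, gamma_end,
                                             ramp_s, dt, n) {
  tgrid <- seq(0, ramp_s - dt, by = dt)
  gam <- gamma_start + (gamma_end - gamma_start) * tgrid / ramp_s
  prob <- pmin(1, opening_rate(params, gam) * dt)
  surv <- cumprod(1 - prob)
  pmf <- prob * c(1, surv[-length(surv)])
  cdf <- cumsum(pmf)
  u <- stats::runif(n) * cdf[length(cdf)]  # condition on opening in-ramp
  idx <- findInterval(u, cdf) + 1L
  gam[idx] + (gamma_end - gamma_start) / ramp_s * dt  # tension at step end
}

# Hand-built trajectory with prescribed events, for deterministic
# thermodynamics fixtures.
manual_trajectory <- function(protocol, times, directions, initial_state = 0L) {
  structure(list(initial_state = as.integer(initial_state),
                 times = times,
                 directions = as.integer(directions),
                 tensions = if (length(times)) tension_at(protocol, times)
                            else numeric(0),
                 protocol = protocol),
            class = "trajectory")
}

# Evenly spaced alternating staircase events for detector benchmarks.
alternating_trajectory <- function(protocol, n_events, t_start, t_end,
                                   jitter_sd = 0, initial_state = 0L) {
  times <- seq(t_start, t_end, length.out = n_events)
  if (jitter_sd > 0) times <- sort(times + stats::rnorm(n_events, 0, jitter_sd))
  dirs <- rep_len(if (initial_state == 0L) c(1L, -1L) else c(-1L, 1L),
                  n_events)
  manual_trajectory(protocol, times, dirs, initial_state)
}
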