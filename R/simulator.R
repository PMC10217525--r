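#' Exact first-transition sampling on one linear tension segment
#'
#' On a linear segment gamma(t) = gamma(t0) + c*(t - t0) the active
#' Arrhenius rate is A*exp(B*(t - t0)) with A the rate at t0 and
#' B = dA_B * c. The integrated hazard is Lambda(dt) = A*(exp(B*dt)-1)/B
#' (A*dt when B = 0), which inverts in closed form:
#' dt = log1p(B*E/A)/B. For B < 0 the hazard is bounded by A/|B|, and an
#' exponential draw above the bound means guaranteed survival of the
#' segment. No time discretisation enters, so heat estimates carry no
#' time-step bias.
#'
#' @param params A [channel_params()] object.
#' @param state Current state: 0 (closed) or 1 (open).
#' @param segment One-row data.frame with columns `t0`, `t1`, `start`,
#'   `slope` (as in `protocol$segments`).
#' @param t0 Entry time into the segment's remaining portion, s.
#' @param exp_draw Optional unit-exponential variate (drawn internally
#'   when `NULL`); exposed for deterministic testing.
#' @return Absolute transition time in s, or `NA_real_` if the channel
#'   survives to the segment end.
#' @export
sample_transition_time <- function(params, state, segment, t0,
                                   exp_draw = NULL) {
  stopifnot(state %in% c(0, 1))
  if (segment$t1 - segment$t0 <= 0) stop("zero-length segment")
  if (t0 < segment$t0 - 1e-12 || t0 > segment$t1 + 1e-12)
    stop("t0 must lie within the segment")
  if (is.null(exp_draw)) exp_draw <- stats::rexp(1)
  g0 <- segment$start + segment$slope * (t0 - segment$t0)
  if (state == 0) {
    a <- params$area_closed_to_barrier; k0 <- params$k_open_0
  } else {
    a <- params$area_open_to_barrier; k0 <- params$k_close_0
  }
  A <- k0 * exp(a * g0)
  B <- a * segment$slope
  rem <- segment$t1 - t0
  if (B == 0) {
    dt <- exp_draw / A
  } else {
    z <- B * exp_draw / A
    if (z <= -1) return(NA_real_)   # bounded hazard: guaranteed survival
    dt <- log1p(z) / B
  }
  if (dt > rem) NA_real_ else t0 + dt
}

#' Simulate one gating trajectory under a tension protocol
#'
#' Exact stochastic simulation of the driven two-state channel: the
#' channel alternates between closed (0) and open (1), with each sojourn
#' ended by inverting the closed-form integrated hazard of the active
#' Arrhenius rate (see [sample_transition_time()]). Hazard accumulates
#' seamlessly across segment boundaries (a single exponential draw is
#' spent across segments), so the sampler is exact for the whole
#' piecewise-linear protocol.
#'
#' @param params A [channel_params()] object.
#' @param protocol A [tension_protocol()].
#' @param initial_state 0 (closed) or 1 (open) at t = 0.
#' @return An object of class `trajectory`: list with `initial_state`,
#'   `times` (event times, s), `directions` (+1 opening, -1 closing),
#'   `tensions` (tension at each event, kBT/nm^2) and `protocol`.
#' @export
simulate_trajectory <- function(params, protocol, initial_state = 0L) {
  seg <- protocol$segments
  ns <- nrow(seg)
  st0 <- seg$t0; st1 <- seg$t1; sstart <- seg$start; sslope <- seg$slope
  a_cb <- params$area_closed_to_barrier
  a_ob <- params$area_open_to_barrier
  ko0 <- params$k_open_0
  kc0 <- params$k_close_0

  state <- as.integer(initial_state)
  t <- 0
  i <- 1L
  cap <- 64L
  times <- numeric(cap)
  dirs <- integer(cap)
  nev <- 0L

  repeat {
    if (state == 0L) { a <- a_cb; k0 <- ko0 } else { a <- a_ob; k0 <- kc0 }
    E <- stats::rexp(1)
    t_event <- NA_real_
    j <- i
    tt <- t
    while (j <= ns) {
      g0 <- sstart[j] + sslope[j] * (tt - st0[j])
      A <- k0 * exp(a * g0)
      B <- a * sslope[j]
      rem <- st1[j] - tt
      if (B == 0) {
        lam <- A * rem
        if (lam >= E) { t_event <- tt + E / A; break }
      } else {
        lam <- A * expm1(B * rem) / B
        if (lam >= E) { t_event <- tt + log1p(B * E / A) / B; break }
      }
      E <- E - lam
      j <- j + 1L
      if (j <= ns) tt <- st0[j]
    }
    if (is.na(t_event)) break
    nev <- nev + 1L
    if (nev > cap) {
      cap <- cap * 2L
      length(times) <- cap
      length(dirs) <- cap
    }
    times[nev] <- t_event
    dirs[nev] <- if (state == 0L) 1L else -1L
    state <- 1L - state
    t <- t_event
    i <- j
  }

  times <- times[seq_len(nev)]
  dirs <- dirs[seq_len(nev)]
  structure(list(initial_state = as.integer(initial_state),
                 times = times,
                 directions = dirs,
                 tensions = if (nev) tension_at(protocol, times) else numeric(0),
                 protocol = protocol),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Gating trajectory: initial state",
      if (x$initial_state == 1L) "open" else "closed",
      "-", length(x$times), "event(s)\n")
  invisible(x)
}

#' Gating events of a trajectory as a data frame
#'
#' @param trajectory A `trajectory` object.
#' @return data.frame with columns `time` (s), `direction` (`"opening"` /
#'   `"closing"`) and `tension` (kBT/nm^2).
#' @export
gating_events <- function(trajectory) {
  data.frame(time = trajectory$times,
             direction = ifelse(trajectory$directions > 0, "opening", "closing"),
             tension = trajectory$tensions)
}

#' Channel state of a trajectory at given times
#'
#' @param trajectory A `trajectory` object.
#' @param t Times, s.
#' @return Integer 0/1 state(s); events are effective immediately (state
#'   at an event time is the post-transition state).
#' @export
state_at <- function(trajectory, t) {
  nflip <- findInterval(t, trajectory$times)
  (trajectory$initial_state + nflip) %% 2L
}

#' Simulate an ensemble of independent channels
#'
#' `n` independent trajectories drawn from one seeded RNG stream
#' (sequentially; re-running with the same seed reproduces the ensemble
#' exactly). Channels are independent — no cooperativity.
#'
#' @param params A [channel_params()] object.
#' @param protocol A [tension_protocol()].
#' @param n Ensemble size (>= 1).
#' @param init_mode Initial-state rule: `"equilibrium_at_start"` draws
#'   Bernoulli(equilibrium_popen at the protocol's starting tension) — at
#'   the midpoint this is the maximal-uncertainty Bernoulli(0.5) bit;
#'   `"fixed_closed"` / `"fixed_open"` start every channel in one state;
#'   `"bernoulli"` uses probability `p`.
#' @param p Open-state probability for `init_mode = "bernoulli"`.
#' @param seed Optional integer seed (set once for the whole ensemble).
#' @return List of `trajectory` objects (class `trajectory_ensemble`).
#' @export
simulate_ensemble <- function(params, protocol, n,
                              init_mode = c("equilibrium_at_start",
                                            "fixed_closed", "fixed_open",
                                            "bernoulli"),
                              p = NULL, seed = NULL) {
  init_mode <- match.arg(init_mode)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  p0 <- switch(init_mode,
               equilibrium_at_start =
                 equilibrium_popen(params, tension_at(protocol, 0)),
               fixed_closed = 0,
               fixed_open = 1,
               bernoulli = {
                 if (is.null(p) || p < 0 || p > 1)
                   stop("init_mode 'bernoulli' needs p in [0, 1]")
                 p
               })
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s0 <- if (p0 == 0) 0L else if (p0 == 1) 1L
          else as.integer(stats::runif(1) < p0)
    out[[i]] <- simulate_trajectory(params, protocol, s0)
  }
  class(out) <- c("trajectory_ensemble", "list")
  out
}

#' Ensemble mean occupancy over a time grid
#'
#' @param trajectories List of `trajectory` objects sharing one protocol.
#' @param time_grid Times, s.
#' @return Numeric vector of the fraction of open channels at each grid
#'   point (in `[0, 1]`).
#' @export
mean_occupancy <- function(trajectories, time_grid) {
  if (length(trajectories) == 0L) stop("empty ensemble")
  acc <- numeric(length(time_grid))
  for (tr in trajectories) acc <- acc + state_at(tr, time_grid)
  acc / length(trajectories)
}

#' Export an ensemble's events as a TSV table
#'
#' One row per gating event: `trajectory_id`, `event_time_s`, `direction`,
#' `tension_kBT_per_nm2`.
#'
#' @param trajectories List of `trajectory` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(trajectories, path) {
  rows <- lapply(seq_along(trajectories), function(i) {
    ev <- gating_events(trajectories[[i]])
    if (nrow(ev) == 0L) return(NULL)
    cbind(trajectory_id = i, ev)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(trajectory_id = integer(0), time = numeric(0),
                      direction = character(0), tension = numeric(0))
  names(tab) <- c("trajectory_id", "event_time_s", "direction",
                  "tension_kBT_per_nm2")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
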