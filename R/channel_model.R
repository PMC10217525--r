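#' Two-state channel parameters
#'
#' Energetic and kinetic description of a single tension-gated two-state
#' channel. The closed state is the energy reference (epsilon_closed = 0);
#' all energies are in units of kBT (beta = 1), areas in nm^2, tension in
#' kBT/nm^2 (1 kBT/nm^2 = 4.114 mN/m at room temperature) and rates in 1/s.
#'
#' Gating kinetics follow the Arrhenius-type tension dependence
#' k(gamma) = k0 * exp(gamma * dA_B), where dA_B is the in-plane expansion
#' area from the departing state to the transition barrier. The defaults
#' describe MscS: intrinsic opening rate 4e-6 1/s, intrinsic closing rate
#' 9897 1/s, closed-to-barrier expansion +7 nm^2, open-to-barrier
#' expansion -5 nm^2 (negative: the open state lies beyond the barrier, so
#' tension slows closing), total area change 12 nm^2 and an energy gap of
#' about 22 kBT between open and closed.
#'
#' The printed energy gap (22 kBT) and the gap implied by the intrinsic
#' rates (ln(k_close_0/k_open_0) = 21.63 kBT) differ slightly.
#' `energy_mode` selects which gap the thermodynamic bookkeeping uses:
#' `"kinetic_consistent"` (default) uses the rate-implied gap, so that the
#' Boltzmann midpoint and the kinetic midpoint coincide and quasi-static
#' simulations provably attain the Landauer bound; `"as_printed"` uses the
#' literal 22 kBT.
#'
#' @param delta_epsilon Energy difference epsilon_open - epsilon_closed, kBT.
#' @param delta_area In-plane area difference open minus closed, nm^2.
#' @param k_open_0 Intrinsic closed-to-open rate at zero tension, 1/s.
#' @param k_close_0 Intrinsic open-to-closed rate at zero tension, 1/s.
#' @param area_closed_to_barrier Expansion area closed -> barrier, nm^2 (> 0).
#' @param area_open_to_barrier Expansion area open -> barrier, nm^2 (< 0 by
#'   convention).
#' @param energy_mode `"kinetic_consistent"` or `"as_printed"`; see Details.
#' @return An object of class `channel_params`.
#' @examples
#' p <- channel_params()
#' opening_rate(p, 0)      # intrinsic opening rate
#' midpoint_tension(p)     # ~1.80 kBT/nm^2
#' @export
channel_params <- function(delta_epsilon = 22,
                           delta_area = 12,
                           k_open_0 = 4e-6,
                           k_close_0 = 9897,
                           area_closed_to_barrier = 7,
                           area_open_to_barrier = -5,
                           energy_mode = c("kinetic_consistent", "as_printed")) {
  energy_mode <- match.arg(energy_mode)
  stopifnot(is.numeric(delta_epsilon), length(delta_epsilon) == 1L,
            is.numeric(delta_area), length(delta_area) == 1L)
  if (!(k_open_0 > 0) || !(k_close_0 > 0))
    stop("intrinsic rates must be strictly positive")
  if (!(delta_area > 0))
    stop("delta_area must be strictly positive")
  if (abs(delta_area - (area_closed_to_barrier - area_open_to_barrier)) > 1e-9)
    stop("delta_area must equal area_closed_to_barrier - area_open_to_barrier")
  structure(
    list(delta_epsilon = delta_epsilon,
         delta_area = delta_area,
         k_open_0 = k_open_0,
         k_close_0 = k_close_0,
         area_closed_to_barrier = area_closed_to_barrier,
         area_open_to_barrier = area_open_to_barrier,
         energy_mode = energy_mode),
    class = "channel_params")
}

#' @export
print.channel_params <- function(x, ...) {
  cat("Two-state channel parameters (", x$energy_mode, " mode)\n", sep = "")
  cat(sprintf("  delta_epsilon: %.4g kBT (effective: %.4f kBT)\n",
              x$delta_epsilon, delta_epsilon_eff(x)))
  cat(sprintf("  delta_area:    %.4g nm^2 (dA_cB = %.4g, dA_oB = %.4g)\n",
              x$delta_area, x$area_closed_to_barrier, x$area_open_to_barrier))
  cat(sprintf("  k_open_0:      %.4g 1/s\n  k_close_0:     %.4g 1/s\n",
              x$k_open_0, x$k_close_0))
  cat(sprintf("  midpoint:      %.4f kBT/nm^2\n", midpoint_tension(x)))
  invisible(x)
}

#' Effective energy gap used by the thermodynamic bookkeeping
#'
#' In `kinetic_consistent` mode this is `log(k_close_0 / k_open_0)` (kBT),
#' the gap implied by detailed balance at zero tension; in `as_printed`
#' mode it is the literal `delta_epsilon` field.
#'
#' @param params A [channel_params()] object.
#' @return Energy gap in kBT.
#' @export
delta_epsilon_eff <- function(params) {
  if (params$energy_mode == "kinetic_consistent")
    log(params$k_close_0 / params$k_open_0)
  else
    params$delta_epsilon
}

check_tension <- function(gamma) {
  if (any(!is.finite(gamma)) || any(gamma < 0))
    stop("tension must be finite and non-negative (kBT/nm^2)")
  gamma
}

#' Tension-dependent gating rates
#'
#' Arrhenius rates `k_open(gamma) = k_open_0 * exp(gamma * dA_cB)` and
#' `k_close(gamma) = k_close_0 * exp(gamma * dA_oB)` with beta = 1 in kBT
#' units. With the default sign convention (`dA_cB > 0`, `dA_oB < 0`)
#' opening accelerates and closing slows with tension.
#'
#' @param params A [channel_params()] object.
#' @param gamma Membrane tension, kBT/nm^2 (vectorised, must be >= 0).
#' @return Rate(s) in 1/s.
#' @export
opening_rate <- function(params, gamma) {
  check_tension(gamma)
  params$k_open_0 * exp(gamma * params$area_closed_to_barrier)
}

#' @rdname opening_rate
#' @export
closing_rate <- function(params, gamma) {
  check_tension(gamma)
  params$k_close_0 * exp(gamma * params$area_open_to_barrier)
}

#' Equilibrium open probability
#'
#' Boltzmann occupancy of the open state,
#' `1 / (1 + exp(delta_epsilon_eff - gamma * delta_area))`. By detailed
#' balance this equals `k_open / (k_open + k_close)` in
#' `kinetic_consistent` mode.
#'
#' @inheritParams opening_rate
#' @return Probability in `[0, 1]` (vectorised over `gamma`).
#' @export
equilibrium_popen <- function(params, gamma) {
  check_tension(gamma)
  stats::plogis(gamma * params$delta_area - delta_epsilon_eff(params))
}

#' Midpoint (half-activation) tension
#'
#' The tension at which the open and closed states are equiprobable —
#' the maximal-entropy, one-bit condition. Closed form from detailed
#' balance: `delta_epsilon_eff / delta_area`.
#'
#' @inheritParams opening_rate
#' @return Tension in kBT/nm^2.
#' @export
midpoint_tension <- function(params) {
  delta_epsilon_eff(params) / params$delta_area
}

#' System energy of an ensemble of channels under tension
#'
#' `H(sigma_bar, gamma) = N * sigma_bar * (delta_epsilon_eff - gamma *
#' delta_area)` with the closed state as the zero of energy. The
#' `-gamma * A` term is the membrane-energy decrease gained when channels
#' expand in the plane of a tensed membrane.
#'
#' @inheritParams opening_rate
#' @param sigma_bar Mean open-state occupancy in `[0, 1]`.
#' @param n_channels Number of channels N (>= 1).
#' @return Energy in kBT.
#' @export
hamiltonian <- function(params, sigma_bar, gamma, n_channels = 1L) {
  if (any(sigma_bar < 0 | sigma_bar > 1))
    stop("occupancy must lie in [0, 1]")
  stopifnot(n_channels >= 1)
  n_channels * sigma_bar * (delta_epsilon_eff(params) - gamma * params$delta_area)
}

#' Read / write channel parameters as JSON
#'
#' Parameters serialise to a flat JSON object whose keys mirror the
#' `channel_params` field names. A packaged default file with the MscS
#' values ships in `system.file("extdata", "mscs_default_params.json",
#' package = "thermogate")`.
#'
#' @param path File path.
#' @param params A [channel_params()] object.
#' @return `read_channel_params` returns a [channel_params()] object;
#'   `write_channel_params` returns `path` invisibly.
#' @export
read_channel_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(channel_params, x)
}

#' @rdname read_channel_params
#' @export
write_channel_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
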