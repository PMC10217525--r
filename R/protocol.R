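#' Piecewise-linear tension protocol
#'
#' A tension-versus-time stimulus made of contiguous linear segments.
#' Segments are given as a data frame with columns `duration` (s),
#' `start` and `end` (kBT/nm^2); tension must be continuous across
#' segment boundaries and non-negative throughout.
#'
#' `erasure_window` marks the time interval (usually the final ramp) over
#' which heat and work are scored; transitions outside it are simulated
#' (they set the initial condition) but not scored.
#'
#' @param segments data.frame with columns `duration`, `start`, `end`.
#' @param erasure_window Length-2 numeric `(t_start, t_end)` in seconds,
#'   or `NULL`.
#' @return An object of class `tension_protocol` with elements `segments`
#'   (with absolute `t0`/`t1` columns added), `total_duration` and
#'   `erasure_window`.
#' @seealso [make_restore_to_open()], [tension_at()]
#' @export
tension_protocol <- function(segments, erasure_window = NULL) {
  stopifnot(is.data.frame(segments),
            all(c("duration", "start", "end") %in% names(segments)),
            nrow(segments) >= 1L)
  if (any(segments$duration <= 0))
    stop("segment durations must be strictly positive")
  if (any(segments$start < 0) || any(segments$end < 0))
    stop("tensions must be non-negative")
  n <- nrow(segments)
  if (n > 1L && any(abs(segments$end[-n] - segments$start[-1L]) > 1e-12))
    stop("tension must be continuous across segment boundaries")
  t1 <- cumsum(segments$duration)
  segments$t0 <- c(0, t1[-n])
  segments$t1 <- t1
  segments$slope <- (segments$end - segments$start) / segments$duration
  total <- t1[n]
  if (!is.null(erasure_window)) {
    stopifnot(length(erasure_window) == 2L, erasure_window[1] < erasure_window[2])
    if (erasure_window[1] < -1e-12 || erasure_window[2] > total + 1e-9)
      stop("erasure_window must lie within [0, total_duration]")
  }
  structure(list(segments = segments,
                 total_duration = total,
                 erasure_window = erasure_window),
            class = "tension_protocol")
}

#' @export
print.tension_protocol <- function(x, ...) {
  cat("Tension protocol:", nrow(x$segments), "segment(s),",
      format(x$total_duration), "s total\n")
  for (i in seq_len(nrow(x$segments)))
    cat(sprintf("  [%g, %g] s: %g -> %g kBT/nm^2\n",
                x$segments$t0[i], x$segments$t1[i],
                x$segments$start[i], x$segments$end[i]))
  if (!is.null(x$erasure_window))
    cat(sprintf("  scored (erasure) window: [%g, %g] s\n",
                x$erasure_window[1], x$erasure_window[2]))
  invisible(x)
}

#' Evaluate a protocol's tension at given times
#'
#' Linear interpolation within the containing segment; continuous in `t`.
#'
#' @param protocol A [tension_protocol()].
#' @param t Time(s) in seconds, within `[0, total_duration]`.
#' @return Tension(s) in kBT/nm^2.
#' @export
tension_at <- function(protocol, t) {
  s <- protocol$segments
  if (any(t < -1e-12) || any(t > protocol$total_duration + 1e-9))
    stop("time outside the protocol range")
  idx <- findInterval(t, s$t0, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(s)] <- nrow(s)
  s$start[idx] + s$slope[idx] * (t - s$t0[idx])
}

#' Build the canonical restore-to-open (bit-erasure) protocol
#'
#' Three segments: a loading ramp from zero tension to `gamma_mid`, a hold
#' at `gamma_mid` (letting the channel thermalise into the 50/50
#' maximal-entropy state when `gamma_mid` is the midpoint), and a final
#' erasure ramp from `gamma_mid` to `gamma_max` that drives the channel
#' into the open state with certainty. The erasure window is the final
#' ramp.
#'
#' @param gamma_mid Hold tension (kBT/nm^2), usually the midpoint.
#' @param gamma_max Final tension (kBT/nm^2), must exceed `gamma_mid`.
#' @param load_s,hold_s,erase_s Segment durations in seconds.
#' @return A [tension_protocol()].
#' @examples
#' pr <- make_restore_to_open(1.9, 3, load_s = 0.25, hold_s = 3, erase_s = 1)
#' pr$total_duration      # 4.25
#' pr$erasure_window      # c(3.25, 4.25)
#' @export
make_restore_to_open <- function(gamma_mid, gamma_max,
                                 load_s = 0.25, hold_s = 3, erase_s = 1) {
  stopifnot(gamma_mid >= 0, load_s > 0, hold_s > 0, erase_s > 0)
  if (!(gamma_max > gamma_mid))
    stop("gamma_max must exceed gamma_mid (non-monotone tension request)")
  seg <- data.frame(duration = c(load_s, hold_s, erase_s),
                    start = c(0, gamma_mid, gamma_mid),
                    end = c(gamma_mid, gamma_mid, gamma_max))
  total <- load_s + hold_s + erase_s
  tension_protocol(seg, erasure_window = c(load_s + hold_s, total))
}

#' Bare erasure ramp (fast-path protocol)
#'
#' A single linear ramp `gamma_mid -> gamma_max`; the whole protocol is
#' the scored window. Used with equilibrium initial conditions as a fast
#' equivalent of the full load/hold/erase protocol (the 3 s hold at the
#' midpoint exceeds the gating relaxation time, so the state at the start
#' of the final ramp is the equilibrium Bernoulli draw either way).
#'
#' @inheritParams make_restore_to_open
#' @return A [tension_protocol()].
#' @export
make_erasure_ramp <- function(gamma_mid, gamma_max, erase_s) {
  stopifnot(gamma_mid >= 0, erase_s > 0)
  if (!(gamma_max > gamma_mid))
    stop("gamma_max must exceed gamma_mid (non-monotone tension request)")
  seg <- data.frame(duration = erase_s, start = gamma_mid, end = gamma_max)
  tension_protocol(seg, erasure_window = c(0, erase_s))
}

#' Pipette-pressure calibration parameters
#'
#' Proportional pressure-to-tension calibration: the patch's radius of
#' curvature is assumed constant over the active pressure range, so
#' `gamma = (p / p_half) * gamma_half`. `gamma_half` is given in mN/m and
#' converted to kBT/nm^2 with the room-temperature constant
#' 4.114 mN/m per kBT/nm^2.
#'
#' @param p_half Pressure at the activation midpoint, mmHg (> 0).
#' @param gamma_half Midpoint tension, mN/m (default 7.85).
#' @param conversion mN/m per kBT/nm^2 (default 4.114).
#' @return An object of class `calibration_params`.
#' @export
calibration_params <- function(p_half, gamma_half = 7.85, conversion = 4.114) {
  if (!(p_half > 0)) stop("p_half must be strictly positive")
  stopifnot(gamma_half > 0, conversion > 0)
  structure(list(p_half = p_half, gamma_half = gamma_half,
                 conversion = conversion),
            class = "calibration_params")
}

#' Convert pipette pressure to membrane tension
#'
#' @param p Pressure(s), mmHg (>= 0).
#' @param cal A [calibration_params()] object.
#' @return Tension(s) in kBT/nm^2.
#' @examples
#' cal <- calibration_params(p_half = 100)
#' pressure_to_tension(100, cal)   # ~1.908 kBT/nm^2 (= 7.85 / 4.114)
#' @export
pressure_to_tension <- function(p, cal) {
  stopifnot(inherits(cal, "calibration_params"))
  if (any(p < 0)) stop("pressure must be non-negative")
  (p / cal$p_half) * (cal$gamma_half / cal$conversion)
}

#' Sample a protocol on a regular time grid
#'
#' @param protocol A [tension_protocol()].
#' @param dt Grid spacing, s.
#' @return data.frame with columns `time_s`, `tension_kBT_per_nm2`.
#' @export
protocol_grid <- function(protocol, dt) {
  t <- seq(0, protocol$total_duration, by = dt)
  data.frame(time_s = t, tension_kBT_per_nm2 = tension_at(protocol, t))
}

#' Read / write a protocol as JSON
#'
#' @param protocol A [tension_protocol()].
#' @param path File path.
#' @return `read_protocol` returns a [tension_protocol()];
#'   `write_protocol` returns `path` invisibly.
#' @export
write_protocol <- function(protocol, path) {
  x <- list(segments = protocol$segments[c("duration", "start", "end")],
            erasure_window = protocol$erasure_window)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tension_protocol(as.data.frame(x$segments),
                   erasure_window = x$erasure_window)
}
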