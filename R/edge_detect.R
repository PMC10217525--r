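#' Detect single-channel gating steps in a current trace
#'
#' Difference-of-boxes matched filter with robust thresholding and
#' non-maximum suppression, the standard idealisation route for noisy
#' piecewise-constant single-channel records:
#' 1. the step statistic `d[i] = mean(current[(i+1)..(i+w)]) -
#'    mean(current[(i-w+1)..i])` (w = `kernel_halfwidth` samples);
#' 2. the noise scale of `d` is estimated by its median absolute
#'    deviation (MAD), robust to the steps themselves;
#' 3. candidate edges are local extrema of `|d|` exceeding
#'    `threshold_sigmas * MAD`;
#' 4. candidates closer than `min_separation` keep the larger `|d|`
#'    (exact ties keep the earlier);
#' 5. polarity is `sign(d)`; amplitude is the post-mean minus pre-mean;
#' 6. integer open-channel levels are carried by cumulative polarity from
#'    the initial level, the nearest integer of
#'    `(current - baseline) / unitary_current` at the trace start.
#'
#' @param trace A `current_trace` (uniform sampling).
#' @param kernel_halfwidth Box half-width w in samples (>= 2).
#' @param threshold_sigmas Detection threshold in MAD units.
#' @param min_separation Minimum event spacing, s.
#' @param unitary_current,baseline Override the trace config (pA); needed
#'   for traces read without metadata.
#' @return An `event_table`: data.frame with columns `time` (s),
#'   `polarity` (+1 opening / -1 closing), `amplitude` (pA),
#'   `level_before`, `level_after` (integer open-channel counts).
#' @export
detect_steps <- function(trace, kernel_halfwidth = 8, threshold_sigmas = 5,
                         min_separation = 0.002,
                         unitary_current = NULL, baseline = NULL) {
  w <- as.integer(kernel_halfwidth)
  stopifnot(w >= 2L)
  x <- trace$current
  n <- length(x)
  if (n < 4L * w) stop("trace shorter than 4 * kernel_halfwidth")
  dt <- diff(trace$time)
  if (max(abs(dt - dt[1])) > 1e-9) stop("non-uniform sampling")
  dt <- dt[1]
  if (is.null(unitary_current)) unitary_current <- trace$config$unitary_current
  if (is.null(baseline)) baseline <- trace$config$baseline

  cs <- c(0, cumsum(x))
  idx <- seq(w, n - w)                       # centres with full boxes
  pre <- (cs[idx + 1L] - cs[idx - w + 1L]) / w
  post <- (cs[idx + w + 1L] - cs[idx + 1L]) / w
  d <- post - pre
  scale <- stats::mad(d)
  if (scale == 0) scale <- .Machine$double.eps

  ad <- abs(d)
  m <- length(d)
  is_peak <- ad > threshold_sigmas * scale &
    ad >= c(-Inf, ad[-m]) & ad >= c(ad[-1], -Inf)
  cand <- which(is_peak)

  # non-maximum suppression: strongest first, earlier wins exact ties
  keep <- integer(0)
  if (length(cand)) {
    ord <- cand[order(-ad[cand], cand)]
    min_sep_samples <- max(1L, round(min_separation / dt))
    for (i in ord) {
      if (!length(keep) || all(abs(keep - i) >= min_sep_samples))
        keep <- c(keep, i)
    }
    keep <- sort(keep)
  }

  times <- trace$time[idx[keep]]
  polarity <- as.integer(sign(d[keep]))
  amplitude <- d[keep]
  level0 <- as.integer(round((mean(x[seq_len(w)]) - baseline) /
                               unitary_current))
  level_before <- level0 + c(0L, cumsum(polarity))[seq_along(keep)]
  out <- data.frame(time = times, polarity = polarity,
                    amplitude = amplitude,
                    level_before = level_before,
                    level_after = level_before + polarity)
  class(out) <- c("event_table", "data.frame")
  out
}

#' Attach transition tensions to detected events
#'
#' Maps each detected step to the protocol tension at its time, yielding
#' gating events usable by the heat bookkeeping.
#'
#' @param events An `event_table` from [detect_steps()].
#' @param protocol A [tension_protocol()].
#' @return data.frame with columns `time`, `direction` (`"opening"` /
#'   `"closing"`) and `tension` (kBT/nm^2).
#' @export
events_to_tension <- function(events, protocol) {
  if (nrow(events) &&
      (min(events$time) < 0 || max(events$time) > protocol$total_duration))
    stop("event times outside the protocol")
  data.frame(time = events$time,
             direction = ifelse(events$polarity > 0, "opening", "closing"),
             tension = tension_at(protocol, events$time))
}

#' Measured-heat pipeline: trace to dissipated-heat summary
#'
#' The measurement arm: detect steps in a (synthetic or recorded) current
#' trace, attach transition tensions, score each event's released heat,
#' and summarise. Channel identity within a multi-channel patch is
#' unobservable, so per-event heats are exact while the per-"realization"
#' heat is defined as the patch total divided by the channel count — a
#' documented approximation.
#'
#' @param trace A `current_trace`.
#' @param protocol The [tension_protocol()] that drove the recording.
#' @param params A [channel_params()] object.
#' @param window Scored window; defaults to the protocol's erasure
#'   window.
#' @param breaks Histogram rule, as in [summarize_ensemble()].
#' @param ... Detector settings passed to [detect_steps()].
#' @return An `ensemble_summary` (per-realization fields use the patch
#'   average; `n_realizations` is the channel count), plus an `events`
#'   attribute holding the annotated event table.
#' @export
measured_heat_pipeline <- function(trace, protocol, params, window = NULL,
                                   breaks = "FD", ...) {
  if (is.null(window)) window <- protocol$erasure_window
  if (is.null(window)) window <- c(0, protocol$total_duration)
  tab <- detect_steps(trace, ...)
  ann <- events_to_tension(tab, protocol)
  in_win <- ann$time > window[1] & ann$time <= window[2]
  ann <- ann[in_win, , drop = FALSE]
  heats <- if (nrow(ann))
    event_heat_released(params, ann$tension, ann$direction) else numeric(0)
  nch <- trace$config$n_channels
  per_real <- sum(heats) / nch
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  mk_hist <- function(x) heat_hist(x, breaks)
  g_ends <- tension_at(protocol, window)
  out <- structure(list(
    erase_duration = diff(window),
    n_realizations = nch,
    mean_heat_released = per_real,
    sem_heat = NA_real_,
    mean_heat_per_event = if (length(heats)) mean(heats) else NA_real_,
    sem_heat_per_event = sem(heats),
    n_events = length(heats),
    heat_histogram = NULL,
    event_heat_histogram = mk_hist(heats),
    landauer_bound = shannon_entropy(equilibrium_popen(params, g_ends[1])) -
      shannon_entropy(equilibrium_popen(params, g_ends[2])),
    landauer_ln2 = log(2)),
    class = "ensemble_summary")
  attr(out, "events") <- cbind(ann, heat_released = heats)
  out
}

#' Export an event table as TSV
#'
#' @param events An `event_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_table_tsv <- function(events, path) {
  tab <- as.data.frame(events)
  names(tab) <- c("time_s", "polarity", "amplitude_pA", "level_before",
                  "level_after")[seq_len(ncol(tab))]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
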