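#' Recording configuration for synthetic patch-clamp traces
#'
#' Describes the instrument model used to render gating trajectories into
#' a current trace: a unitary single-channel current (default 30 pA, a
#' ~1 nS channel held at 30 mV), uniform sampling, additive white
#' Gaussian noise, and an optional single-pole low-pass filter applied to
#' signal plus noise.
#'
#' @param unitary_current Single-channel current step, pA (default 30).
#' @param sampling_rate Samples per second, Hz (default 10000).
#' @param noise_sd Gaussian noise SD, pA (default 3).
#' @param filter_cutoff Single-pole low-pass cutoff, Hz, or `NULL` for no
#'   filtering. Must satisfy `sampling_rate > 2 * filter_cutoff`.
#' @param baseline Baseline (all-closed) current, pA.
#' @param baseline_drift Linear baseline drift, pA/s.
#' @param n_channels Number of channels in the patch.
#' @return An object of class `recording_config`.
#' @export
recording_config <- function(unitary_current = 30, sampling_rate = 10000,
                             noise_sd = 3, filter_cutoff = NULL,
                             baseline = 0, baseline_drift = 0,
                             n_channels = 1L) {
  stopifnot(unitary_current > 0, sampling_rate > 0, noise_sd >= 0,
            n_channels >= 1)
  if (!is.null(filter_cutoff) && sampling_rate <= 2 * filter_cutoff)
    stop("sampling_rate must exceed twice the filter cutoff")
  structure(list(unitary_current = unitary_current,
                 sampling_rate = sampling_rate,
                 noise_sd = noise_sd,
                 filter_cutoff = filter_cutoff,
                 baseline = baseline,
                 baseline_drift = baseline_drift,
                 n_channels = as.integer(n_channels)),
            class = "recording_config")
}

single_pole_lowpass <- function(x, cutoff, sampling_rate) {
  dt <- 1 / sampling_rate
  rc <- 1 / (2 * pi * cutoff)
  alpha <- dt / (rc + dt)
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                           init = x[1]))
}

#' Render gating trajectories into a synthetic current trace
#'
#' current(t) = baseline + drift*t + unitary_current * (number of open
#' channels at t) + Gaussian(0, noise_sd), then optional single-pole
#' low-pass. The true gating events of every channel ride along in the
#' `truth` slot, so detector benchmarks are self-contained.
#'
#' @param trajectories List of `trajectory` objects sharing one protocol
#'   (one per channel in the patch).
#' @param config A [recording_config()]; `n_channels` must equal the
#'   number of trajectories.
#' @param seed Optional seed for the noise draw.
#' @return An object of class `current_trace`: list with `time` (s,
#'   uniform grid), `current` (pA), `truth` (list of per-channel event
#'   data frames), `config`.
#' @export
render_trace <- function(trajectories, config = recording_config(),
                         seed = NULL) {
  if (length(trajectories) == 0L) stop("empty trajectory list")
  if (config$n_channels != length(trajectories))
    stop("config$n_channels must match the number of trajectories")
  if (!is.null(seed)) set.seed(seed)
  pr <- trajectories[[1]]$protocol
  n <- floor(pr$total_duration * config$sampling_rate) + 1L
  t <- (seq_len(n) - 1L) / config$sampling_rate
  n_open <- numeric(n)
  for (tr in trajectories) n_open <- n_open + state_at(tr, t)
  cur <- config$baseline + config$baseline_drift * t +
    config$unitary_current * n_open
  if (config$noise_sd > 0) cur <- cur + stats::rnorm(n, 0, config$noise_sd)
  if (!is.null(config$filter_cutoff))
    cur <- single_pole_lowpass(cur, config$filter_cutoff,
                               config$sampling_rate)
  structure(list(time = t, current = cur,
                 truth = lapply(trajectories, gating_events),
                 config = config),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("Current trace: %d samples at %g Hz (%.4g s), %s truth\n",
              length(x$time), x$config$sampling_rate,
              x$time[length(x$time)],
              if (is.null(x$truth)) "no" else "with"))
  invisible(x)
}

#' Write / read a current trace as annotated CSV
#'
#' Two-column CSV (`time_s`, `current_pA`) preceded by `#`-prefixed
#' header lines carrying the recording config and, for synthetic traces,
#' the ground-truth events as JSON — a lossless round trip. A plain
#' header-less two-column CSV is accepted on read, with `truth` and
#' `config` absent.
#'
#' @param trace A `current_trace`.
#' @param path File path.
#' @return `read_trace` returns a `current_trace`; `write_trace` returns
#'   `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- list(config = unclass(trace$config), truth = trace$truth)
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                           digits = NA, null = "null")), con)
  writeLines("time_s,current_pA", con)
  utils::write.table(data.frame(trace$time, trace$current), con, sep = ",",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path, n = 64L)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- NULL
  if (length(hdr)) {
    meta <- tryCatch(jsonlite::fromJSON(sub("^#\\s*", "", hdr[1]),
                                        simplifyVector = TRUE),
                     error = function(e) NULL)
  }
  tab <- utils::read.csv(path, comment.char = "#",
                         header = grepl("time", lines[length(hdr) + 1L],
                                        ignore.case = TRUE))
  if (ncol(tab) < 2L) stop("trace file must have time and current columns")
  config <- NULL
  truth <- NULL
  if (!is.null(meta)) {
    if (!is.null(meta$config)) config <- do.call(recording_config, meta$config)
    if (!is.null(meta$truth) && length(meta$truth))
      truth <- if (is.data.frame(meta$truth)) list(meta$truth) else meta$truth
  }
  if (is.null(config)) {
    dt <- stats::median(diff(tab[[1]]))
    config <- recording_config(sampling_rate = round(1 / dt))
  }
  structure(list(time = tab[[1]], current = tab[[2]],
                 truth = truth, config = config),
            class = "current_trace")
}
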