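#' Voltage-clamp current trace
#'
#' Container for one sweep of sampled membrane current together with the
#' metadata every analysis stage needs: sampling rate, recording polarity and
#' stimulus onsets. Conventions used throughout the package: time in seconds
#' (0-based sample indexing, sample i at `start_time + (i-1)/sampling_rate`),
#' current in pA, charge in pC. Raw recordings are inward-negative (EPSCs are
#' negative deflections); [preprocess()] converts to baseline-subtracted,
#' positive-up magnitude traces on which all measurements are defined.
#'
#' @param samples Numeric vector of current samples, pA.
#' @param sampling_rate Sampling rate, Hz (> 0).
#' @param start_time Time of the first sample, s.
#' @param polarity `"inward_negative"` (raw recording convention) or
#'   `"positive_up"` (rectified magnitude trace).
#' @param stimulus_times Ordered stimulus onsets, s, within the trace extent.
#' @param annotations Named list of free-form metadata (protocol, genotype,
#'   TTX flag, sucrose concentration, ...). Values are scalars.
#' @return An object of class `epsc_trace`.
#' @export
epsc_trace <- function(samples, sampling_rate, start_time = 0,
                       polarity = c("inward_negative", "positive_up"),
                       stimulus_times = numeric(), annotations = list()) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("trace 'samples' must be a non-empty numeric vector", call. = FALSE)
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  stopifnot_scalar(start_time, "start_time")
  polarity <- match.arg(polarity)
  stimulus_times <- as.numeric(stimulus_times)
  if (is.unsorted(stimulus_times, strictly = TRUE) && length(stimulus_times) > 1L)
    stop("'stimulus_times' must be strictly increasing", call. = FALSE)
  t_end <- start_time + length(samples) / sampling_rate
  if (length(stimulus_times) &&
      (min(stimulus_times) < start_time || max(stimulus_times) > t_end))
    stop("'stimulus_times' fall outside the trace extent", call. = FALSE)
  if (!is.list(annotations))
    stop("'annotations' must be a named list", call. = FALSE)
  structure(list(
    samples = as.numeric(samples),
    sampling_rate = sampling_rate,
    start_time = start_time,
    polarity = polarity,
    stimulus_times = stimulus_times,
    annotations = annotations
  ), class = "epsc_trace")
}

# Sample times of a trace, s.
trace_times <- function(trace) {
  trace$start_time + (seq_along(trace$samples) - 1) / trace$sampling_rate
}

# Index of the sample at or just after time `t` (s).
time_index <- function(trace, t) {
  i <- ceiling((t - trace$start_time) * trace$sampling_rate - 1e-9) + 1L
  max(1L, min(length(trace$samples), as.integer(i)))
}

trace_duration <- function(trace) length(trace$samples) / trace$sampling_rate

#' @export
print.epsc_trace <- function(x, ...) {
  cat(sprintf("Voltage-clamp trace: %d samples at %g Hz (%.3g s), polarity %s\n",
              length(x$samples), x$sampling_rate, trace_duration(x), x$polarity))
  if (length(x$stimulus_times))
    cat(sprintf("  %d stimulus onsets (first %.4g s, last %.4g s)\n",
                length(x$stimulus_times), min(x$stimulus_times),
                max(x$stimulus_times)))
  if (length(x$annotations))
    cat("  annotations:", paste(names(x$annotations), unlist(x$annotations),
                                sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Plot a current trace
#'
#' @param x An `epsc_trace`.
#' @param xlim Optional time window to display, s.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.epsc_trace <- function(x, xlim = NULL, ...) {
  t <- trace_times(x)
  keep <- if (is.null(xlim)) TRUE else t >= xlim[1] & t <= xlim[2]
  graphics::plot(t[keep], x$samples[keep], type = "l",
                 xlab = "time (s)", ylab = "current (pA)", ...)
  if (length(x$stimulus_times))
    graphics::abline(v = x$stimulus_times, col = "grey70", lty = 3)
  invisible(x)
}
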