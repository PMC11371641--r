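#' Single-EPSC amplitude, charge and time-to-peak
#'
#' Measures the peak amplitude, time from stimulation onset to the peak, and
#' trapezoidal charge of one evoked EPSC on a preprocessed trace. The
#' response window runs from the stimulus to the next stimulus, or to
#' `fit_window` after the stimulus when it is the last one.
#'
#' @param trace An [epsc_trace()] (preprocessed automatically if raw).
#' @param stim_time Stimulus onset, s; defaults to the first stimulus.
#' @param config An [analysis_config()].
#' @return An object of class `epsc_metrics`: `amplitude` (pA), `charge`
#'   (pC), `time_to_peak` (ms), `peak_time` (s), `baseline` (pA, original
#'   polarity).
#' @export
epsc_metrics <- function(trace, stim_time = NULL,
                         config = analysis_config()) {
  trace <- ensure_preprocessed(trace, config)
  if (is.null(stim_time)) {
    if (!length(trace$stimulus_times))
      stop("no stimulus time available", call. = FALSE)
    stim_time <- trace$stimulus_times[1]
  }
  later <- trace$stimulus_times[trace$stimulus_times > stim_time + 1e-9]
  win_end <- if (length(later)) min(later) else
    stim_time + config$fit_window / 1000
  i1 <- time_index(trace, stim_time)
  i2 <- time_index(trace, win_end)
  if (i2 <= i1)
    stop("no samples in the response window", call. = FALSE)
  x <- trace$samples[i1:i2]
  ipk <- which.max(x)
  structure(list(
    amplitude = max(x[ipk], 0),
    time_to_peak = (ipk - 1) / trace$sampling_rate * 1000,
    peak_time = stim_time + (ipk - 1) / trace$sampling_rate,
    charge = trapz_charge(x, trace$sampling_rate),
    baseline = trace$annotations$baseline_pA %||% 0,
    stim_time = stim_time, window_end = win_end
  ), class = "epsc_metrics")
}

#' @export
print.epsc_metrics <- function(x, ...) {
  cat(sprintf("EPSC: amplitude %.4g pA, charge %.4g pC, time-to-peak %.3g ms\n",
              x$amplitude, x$charge, x$time_to_peak))
  invisible(x)
}

#' Full single-EPSC analysis
#'
#' Convenience wrapper chaining [preprocess()], [epsc_metrics()],
#' [fit_biexp_decay()] and [decompose_sync_async()]: the standard
#' quantification of one evoked response, including the asynchronous charge
#' fraction.
#'
#' @param trace An [epsc_trace()] with at least one stimulus.
#' @param config An [analysis_config()].
#' @return An object of class `epsc_analysis`: `metrics`, `fit`,
#'   `rise_charge`, `sync_charge`, `async_charge`, `async_fraction`.
#' @export
analyze_epsc <- function(trace, config = analysis_config()) {
  trace <- ensure_preprocessed(trace, config)
  m <- epsc_metrics(trace, config = config)
  fit <- fit_biexp_decay(trace, m$peak_time, config)
  i1 <- time_index(trace, m$stim_time)
  i2 <- time_index(trace, m$peak_time)
  rise <- max(0, trapz_charge(trace$samples[i1:i2], trace$sampling_rate))
  if (fit$converged) {
    d <- decompose_sync_async(fit, rise)
  } else {
    d <- list(sync_charge = NA_real_, async_charge = NA_real_,
              async_fraction = NA_real_)
  }
  structure(c(list(metrics = m, fit = fit, rise_charge = rise), d),
            class = "epsc_analysis")
}

#' @export
print.epsc_analysis <- function(x, ...) {
  print(x$metrics)
  print(x$fit)
  if (!is.na(x$async_fraction))
    cat(sprintf("  synchronous %.4g pC + asynchronous %.4g pC -> asynchronous fraction %.4f\n",
                x$sync_charge, x$async_charge, x$async_fraction))
  invisible(x)
}

#' Paired-pulse ratio
#'
#' Amplitude of the second response divided by the first, for two closely
#' spaced stimuli. The second amplitude is measured after subtracting the
#' extrapolated bi-exponential decay of the first response, so residual
#' current from the first pulse does not inflate it.
#'
#' @param trace An [epsc_trace()].
#' @param stim_times Length-2 stimulus onsets, s; defaults to the trace's.
#' @param config An [analysis_config()].
#' @return The paired-pulse ratio (dimensionless); `NA` when the first
#'   response is absent.
#' @export
paired_pulse_ratio <- function(trace, stim_times = NULL,
                               config = analysis_config()) {
  trace <- ensure_preprocessed(trace, config)
  if (is.null(stim_times)) stim_times <- trace$stimulus_times
  if (length(stim_times) != 2L)
    stop("paired-pulse analysis requires exactly 2 stimulus times",
         call. = FALSE)
  t1 <- stim_times[1]; t2 <- stim_times[2]
  isi <- t2 - t1
  i1 <- time_index(trace, t1); i2 <- time_index(trace, t2) - 1L
  x1 <- trace$samples[i1:i2]
  a1 <- max(x1)
  if (a1 <= 0) return(NA_real_)
  pk1 <- t1 + (which.max(x1) - 1) / trace$sampling_rate

  cfg1 <- config
  cfg1$fit_window <- max(5, (t2 - pk1) * 1000 - 0.2)
  fit <- tryCatch(fit_biexp_decay(trace, pk1, cfg1), error = function(e) NULL)

  j1 <- time_index(trace, t2)
  j2 <- min(length(trace$samples), time_index(trace, t2 + isi))
  x2 <- trace$samples[j1:j2]
  tt2 <- trace$start_time + (seq(j1, j2) - 1) / trace$sampling_rate
  resid2 <- if (!is.null(fit) && isTRUE(fit$converged))
    x2 - predict(fit, tt2) else x2
  a2 <- max(resid2, 0)
  a2 / a1
}
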