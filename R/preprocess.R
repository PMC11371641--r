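#' Baseline-subtract, rectify and blank a raw trace
#'
#' All measurements in the package are defined on baseline-subtracted,
#' polarity-rectified magnitude traces (EPSC deflections positive-up). The
#' baseline is the mean over `baseline_window` ms immediately preceding the
#' first stimulus (or the first `baseline_window` ms of the trace when there
#' are no stimuli, as for mini recordings). A `blank_window` ms segment after
#' each stimulus onset is replaced by linear interpolation to remove
#' stimulation artifacts.
#'
#' @param trace An [epsc_trace()].
#' @param config An [analysis_config()].
#' @return A rectified `epsc_trace` (polarity `"positive_up"`) with
#'   annotations `preprocessed = TRUE`, `baseline_pA` (in the original
#'   polarity) and `noise_sd_pA` (SD of the rectified baseline segment).
#' @export
preprocess <- function(trace, config = analysis_config()) {
  if (!inherits(trace, "epsc_trace"))
    stop("'trace' must be an epsc_trace object", call. = FALSE)
  fs <- trace$sampling_rate
  bw <- config$baseline_window / 1000
  if (length(trace$stimulus_times)) {
    t0 <- trace$stimulus_times[1]
    if (t0 - bw < trace$start_time - 1e-9)
      stop("baseline window extends before the start of the trace",
           call. = FALSE)
    i1 <- time_index(trace, t0 - bw)
    i2 <- max(i1, time_index(trace, t0) - 1L)
  } else {
    i1 <- 1L
    i2 <- max(1L, min(length(trace$samples), round(bw * fs)))
  }
  baseline <- mean(trace$samples[i1:i2])
  x <- trace$samples - baseline
  if (trace$polarity == "inward_negative") x <- -x
  # artifact blanking: linear interpolation across blank_window after onset
  for (s in trace$stimulus_times) {
    j1 <- time_index(trace, s)
    j2 <- min(length(x), time_index(trace, s + config$blank_window / 1000))
    if (j2 > j1 + 1L)
      x[j1:j2] <- seq(x[j1], x[j2], length.out = j2 - j1 + 1L)
  }
  ann <- trace$annotations
  ann$preprocessed <- TRUE
  ann$baseline_pA <- baseline
  ann$noise_sd_pA <- stats::sd(x[i1:i2])
  out <- trace
  out$samples <- x
  out$polarity <- "positive_up"
  out$annotations <- ann
  out
}

is_preprocessed <- function(trace) isTRUE(trace$annotations$preprocessed)

ensure_preprocessed <- function(trace, config) {
  if (is_preprocessed(trace)) trace else preprocess(trace, config)
}
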