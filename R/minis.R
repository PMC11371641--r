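#' Detect spontaneous miniature EPSCs
#'
#' Threshold detector on a preprocessed (positive-up) trace. The local
#' baseline is a running median (200 ms window); the noise SD is estimated by
#' a one-sided (left-tail) median-absolute-deviation, robust to event load,
#' of a smoothed high-pass copy (trace minus running baseline). Detection
#' works on two smoothing scales: a fine 1 ms boxcar resolving closely
#' spaced peaks and a coarse 3 ms boxcar integrating over the event width
#' for noise rejection. Candidate events are local maxima of the
#' fine-smoothed residual exceeding `detection_threshold_k` noise SDs on
#' both scales simultaneously, that also
#' rise by at least the threshold above their preceding 2 ms minimum (so
#' noise maxima riding on the decay of an earlier event are rejected);
#' candidates closer than `min_event_interval` are merged keeping the larger
#' peak (so
#' genuinely overlapping events are reported as single summed events, and
#' amplitude inflation at high rates is observable rather than corrected
#' away). Event amplitude is the raw residual peak above the local baseline;
#' event time is the onset, found by walking back from the peak to where the
#' residual last fell below max(noise SD, 5% of the amplitude).
#'
#' @param trace An [epsc_trace()] of at least 1 s, without stimuli
#'   (preprocessed automatically if raw).
#' @param config An [analysis_config()].
#' @return An object of class `mini_events`: `event_times` (s, onsets),
#'   `event_amplitudes` (pA), `duration_analyzed` (s), `noise_sd_estimate`
#'   (pA).
#' @export
detect_minis <- function(trace, config = analysis_config()) {
  trace <- ensure_preprocessed(trace, config)
  fs <- trace$sampling_rate
  x <- trace$samples
  if (length(x) < fs)
    stop("mini detection requires at least 1 s of recording", call. = FALSE)

  k_med <- round(0.2 * fs); k_med <- k_med + (1 - k_med %% 2)
  k_med <- min(k_med, length(x) - (1 - length(x) %% 2))
  baseline <- stats::runmed(x, k_med)
  resid <- x - baseline

  boxcar <- function(x, w) {
    out <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
    out[is.na(out)] <- 0
    out
  }
  # noise SD from the negative half of the smoothed residual: release events
  # only add positive mass, so the left tail is uncontaminated at high rates
  left_sd <- function(x) {
    med <- stats::median(x)
    stats::median(med - x[x <= med]) / 0.6744898
  }
  # two scales: the fine trace resolves closely spaced peaks, the coarse
  # trace integrates over the event width and supplies noise rejection; a
  # candidate must clear the threshold on both simultaneously
  sm <- boxcar(resid, max(3L, round(0.001 * fs)))
  sm_c <- boxcar(resid, max(3L, round(0.003 * fs)))
  sigma <- left_sd(sm)
  thr <- config$detection_threshold_k * sigma
  thr_c <- config$detection_threshold_k * left_sd(sm_c)

  n <- length(sm)
  is_max <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] &
                sm[2:(n - 1)] >= sm[3:n], FALSE)
  cand <- which(is_max & sm > thr & sm_c > thr_c)
  if (length(cand)) {
    w_rise <- max(1L, round(0.002 * fs))
    rise_ok <- vapply(cand, function(i) {
      sm[i] - min(sm[max(1L, i - w_rise):i]) >= thr
    }, logical(1))
    cand <- cand[rise_ok]
  }

  min_gap <- config$min_event_interval / 1000

  if (!length(cand)) {
    ev_t <- ev_a <- numeric()
  } else {
    # refine each candidate to the raw residual peak nearby, then merge on
    # the refined positions: the raw peak localises to within a sample or
    # two, so the merge dead time is min_event_interval, not the (wider)
    # smoothed peak separation
    half <- round(0.0015 * fs)
    half <- as.integer(half)
    pk <- vapply(as.integer(cand), function(i) {
      j1 <- max(1L, i - half); j2 <- min(n, i + half)
      j1 - 1L + which.max(resid[j1:j2])
    }, integer(1))
    pk <- sort(unique(pk))
    pk <- merge_events(pk, resid[pk], min_gap * fs)
    ev_a <- ev_t <- numeric(length(pk))
    for (i in seq_along(pk)) {
      ev_a[i] <- resid[pk[i]]
      floor_lvl <- max(sigma, 0.05 * ev_a[i])
      back <- max(1L, pk[i] - round(0.01 * fs))
      # never walk back past the preceding event's peak
      if (i > 1L) back <- max(back, pk[i - 1L] + 1L)
      below <- which(resid[back:pk[i]] < floor_lvl)
      # riding on a previous event's decay the residual never reaches the
      # floor; the pre-peak minimum of the smoothed trace marks the onset
      onset <- if (length(below)) back - 1L + max(below) else
        back - 1L + which.min(sm[back:pk[i]])
      ev_t[i] <- trace$start_time + (onset - 1) / fs
    }
    keep <- ev_a > 0
    ev_t <- ev_t[keep]; ev_a <- ev_a[keep]
    # onset assignment must respect the minimum separation too
    o <- order(ev_t)
    ev_t <- ev_t[o]; ev_a <- ev_a[o]
    sel <- merge_keep_index(ev_t, ev_a, min_gap)
    ev_t <- ev_t[sel]; ev_a <- ev_a[sel]
  }

  structure(list(event_times = ev_t, event_amplitudes = ev_a,
                 duration_analyzed = trace_duration(trace),
                 noise_sd_estimate = sigma),
            class = "mini_events")
}

# Greedy merge of candidate positions closer than `gap`, keeping the larger.
merge_events <- function(pos, height, gap) {
  pos[merge_keep_index(pos, height, gap)]
}

# Indices retained by the greedy merge.
merge_keep_index <- function(pos, height, gap) {
  keep <- seq_along(pos)
  if (length(pos) < 2L) return(keep)
  repeat {
    d <- diff(pos[keep])
    close_i <- which(d < gap)
    if (!length(close_i)) break
    i <- close_i[1]
    drop <- if (height[keep[i]] >= height[keep[i + 1]]) i + 1L else i
    keep <- keep[-drop]
  }
  keep
}

#' @export
print.mini_events <- function(x, ...) {
  cat(sprintf("Detected %d miniature events over %.4g s (noise SD %.3g pA)\n",
              length(x$event_times), x$duration_analyzed, x$noise_sd_estimate))
  invisible(x)
}

#' Miniature-event frequency and amplitude statistics
#'
#' @param event_set A [detect_minis()] result.
#' @return An object of class `mini_stats`: `frequency` (Hz),
#'   `mean_amplitude`, `median_amplitude` (pA; `NA` when no events were
#'   detected), `n_events`, `duration_analyzed`.
#' @export
mini_statistics <- function(event_set) {
  if (!inherits(event_set, "mini_events"))
    stop("'event_set' must come from detect_minis()", call. = FALSE)
  if (event_set$duration_analyzed <= 0)
    stop("'duration_analyzed' must be positive", call. = FALSE)
  n <- length(event_set$event_times)
  structure(list(
    frequency = n / event_set$duration_analyzed,
    mean_amplitude = if (n) mean(event_set$event_amplitudes) else NA_real_,
    median_amplitude = if (n) stats::median(event_set$event_amplitudes)
      else NA_real_,
    n_events = n,
    duration_analyzed = event_set$duration_analyzed
  ), class = "mini_stats")
}

#' @export
print.mini_stats <- function(x, ...) {
  cat(sprintf("mEPSCs: %.4g Hz (%d events / %.4g s), amplitude mean %.4g, median %.4g pA\n",
              x$frequency, x$n_events, x$duration_analyzed,
              x$mean_amplitude, x$median_amplitude))
  invisible(x)
}
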