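#' Analyze a uniform stimulus train
#'
#' Quantifies short-term plasticity and the synchronous/asynchronous division
#' of release during a uniform train. The asynchronous envelope is the
#' piecewise-linear interpolation through the mean current over the 2 ms
#' preceding each stimulus (the phasic EPSC has fully decayed there, so the
#' pre-pulse level reflects the sustained asynchronous component); its
#' integral over the train window is the asynchronous charge, and the
#' synchronous charge is the remainder of the total train charge. Phasic
#' amplitudes are measured above the pre-pulse level and normalized to the
#' first pulse. The tail current after the train is fit with a
#' mono-exponential from one inter-stimulus interval after the last stimulus
#' until the current returns to within 2 noise SDs of baseline.
#'
#' @param trace An [epsc_trace()] (preprocessed automatically if raw).
#' @param stim_times >= 5 uniformly spaced stimulus onsets, s; defaults to
#'   the trace's.
#' @param config An [analysis_config()].
#' @return An object of class `train_result`: `pulse_amplitudes` (pA),
#'   `normalized_amplitudes` (first = 1), `per_pulse_charges` (pC, total
#'   charge per inter-stimulus interval), `total_charge` (pC),
#'   `sync_charge`, `async_charge`, `train_async_fraction`, `tail_tau` (ms),
#'   `tail_charge` (pC), `stim_times`, and `envelope_clipped` (flag set when
#'   the envelope integral exceeded the total charge and was clipped).
#' @export
analyze_train <- function(trace, stim_times = NULL,
                          config = analysis_config()) {
  trace <- ensure_preprocessed(trace, config)
  if (is.null(stim_times)) stim_times <- trace$stimulus_times
  if (length(stim_times) < 5L)
    stop("train analysis requires at least 5 stimuli", call. = FALSE)
  dt <- diff(stim_times)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("train analysis requires uniformly spaced stimuli", call. = FALSE)
  dt <- dt[1]
  fs <- trace$sampling_rate
  K <- length(stim_times)
  x <- trace$samples

  # pre-pulse asynchronous envelope at each stimulus and at train end
  env_t <- c(stim_times, stim_times[K] + dt)
  b <- vapply(env_t, function(s) {
    j2 <- time_index(trace, s) - 1L
    j1 <- max(1L, time_index(trace, s - 0.002))
    mean(x[j1:max(j1, j2)])
  }, numeric(1))

  i_start <- time_index(trace, stim_times[1])
  i_end <- time_index(trace, stim_times[K] + dt)
  total_charge <- trapz_charge(x[i_start:i_end], fs)
  async_charge <- sum(dt * (b[-1] + b[-(K + 1)]) / 2)
  clipped <- FALSE
  if (async_charge > total_charge) {
    async_charge <- total_charge
    clipped <- TRUE
  }
  async_charge <- max(0, async_charge)
  sync_charge <- total_charge - async_charge
  afrac <- if (total_charge > 0) async_charge / total_charge else NA_real_

  amps <- charges <- numeric(K)
  for (k in seq_len(K)) {
    j1 <- time_index(trace, stim_times[k])
    j2 <- time_index(trace, stim_times[k] + dt)
    amps[k] <- max(x[j1:j2] - b[k], 0)
    charges[k] <- trapz_charge(x[j1:j2], fs)
  }
  norm_amps <- if (amps[1] > 0) amps / amps[1] else rep(NA_real_, K)

  tail <- fit_tail(trace, stim_times[K] + dt, config)

  structure(list(
    pulse_amplitudes = amps,
    normalized_amplitudes = norm_amps,
    per_pulse_charges = charges,
    total_charge = total_charge,
    sync_charge = sync_charge,
    async_charge = async_charge,
    train_async_fraction = afrac,
    tail_tau = tail$tau,
    tail_charge = tail$charge,
    stim_times = stim_times,
    isi = dt,
    envelope = b,
    envelope_clipped = clipped
  ), class = "train_result")
}

# Mono-exponential fit to the post-train tail current.
fit_tail <- function(trace, t0, config) {
  fs <- trace$sampling_rate
  noise_sd <- trace$annotations$noise_sd_pA %||% 0
  i0 <- time_index(trace, t0)
  n <- length(trace$samples)
  if (i0 >= n - 10L) return(list(tau = NA_real_, charge = NA_real_))
  y <- trace$samples[i0:n]
  # smooth over 5 ms to find the return-to-baseline point
  w <- max(3L, round(0.005 * fs)); w <- w + (1 - w %% 2)
  ys <- stats::runmed(y, w)
  cross <- which(ys <= 2 * noise_sd)[1]
  i_end <- if (is.na(cross)) length(y) else max(cross, 10L)
  y <- y[seq_len(i_end)]
  charge <- trapz_charge(y, fs)
  if (length(y) < 10L || max(y) <= 2 * noise_sd)
    return(list(tau = NA_real_, charge = charge))
  t <- (seq_along(y) - 1) / fs
  A0 <- max(mean(y[seq_len(max(2L, round(0.002 * fs)))]), max(y) * 0.1)
  drop_i <- which(ys[seq_len(i_end)] <= A0 / exp(1))[1]
  tau0 <- if (is.na(drop_i)) max(t) / 3 else max(t[drop_i], 2 / fs)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-t / exp(ltau)),
                      start = list(A = A0, ltau = log(tau0)),
                      lower = c(0, log(1 / fs)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(tau = NA_real_, charge = charge))
  list(tau = exp(stats::coef(fit)[["ltau"]]) * 1000, charge = charge)
}

#' @export
print.train_result <- function(x, ...) {
  K <- length(x$pulse_amplitudes)
  cat(sprintf("Stimulus train: %d pulses at %.3g Hz\n", K, 1 / x$isi))
  cat(sprintf("  first amplitude %.4g pA, steady-state rundown %.3f\n",
              x$pulse_amplitudes[1],
              mean(utils::tail(x$normalized_amplitudes, max(1, K %/% 4)))))
  cat(sprintf("  total charge %.4g pC, asynchronous fraction %.4f%s\n",
              x$total_charge, x$train_async_fraction,
              if (x$envelope_clipped) " (envelope clipped)" else ""))
  if (!is.na(x$tail_tau))
    cat(sprintf("  tail: tau %.4g ms, charge %.4g pC\n",
                x$tail_tau, x$tail_charge))
  invisible(x)
}

#' Plot the cumulative-charge back-extrapolation of a train
#'
#' @param x A `train_result`.
#' @param config An [analysis_config()] (for the steady-state fraction).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.train_result <- function(x, config = analysis_config(), ...) {
  t <- x$stim_times - x$stim_times[1]
  y <- cumsum(x$per_pulse_charges)
  graphics::plot(t, y, pch = 16, cex = 0.6,
                 xlab = "time from first pulse (s)",
                 ylab = "cumulative charge (pC)", ...)
  est <- backextrapolate_rrp(x, config = config)
  graphics::abline(est$rrp_charge, est$recruitment_rate, col = "red3")
  invisible(x)
}

new_rrp_estimate <- function(rrp_charge, recruitment_rate, method,
                             fit_r2 = NA_real_, flagged = FALSE) {
  structure(list(rrp_charge = rrp_charge,
                 recruitment_rate = recruitment_rate,
                 method = method, fit_r2 = fit_r2, flagged = flagged),
            class = "rrp_estimate")
}

#' @export
print.rrp_estimate <- function(x, ...) {
  cat(sprintf("RRP estimate (%s): %.4g pC, recruitment %.4g pC/s%s\n",
              x$method, x$rrp_charge, x$recruitment_rate,
              if (x$flagged) " [flagged: steady state not reached]" else ""))
  if (!is.na(x$fit_r2)) cat(sprintf("  linear fit R^2 = %.4f\n", x$fit_r2))
  invisible(x)
}

#' RRP and recruitment rate by cumulative-charge back-extrapolation
#'
#' The cumulative per-pulse charge of a high-frequency train is plotted
#' against pulse time; once depletion has equilibrated with recruitment the
#' curve is linear, and an ordinary least-squares line through the final
#' steady-state pulses back-extrapolates to the Y-axis intercept (the
#' readily releasable pool charge) with slope equal to the recruitment rate.
#'
#' @param train_result A [analyze_train()] result, or any list with a
#'   `per_pulse_charges` element.
#' @param stim_times Stimulus onsets, s; taken from `train_result` if absent.
#' @param config An [analysis_config()]; `steady_state_fraction` (default
#'   0.25) selects the final fraction of pulses to fit.
#' @return An object of class `rrp_estimate` with `rrp_charge` (pC, the
#'   intercept at the first pulse), `recruitment_rate` (pC/s, the slope),
#'   `fit_r2`, and `flagged = TRUE` when the slope is negative (steady state
#'   not reached).
#' @export
backextrapolate_rrp <- function(train_result, stim_times = NULL,
                                config = analysis_config()) {
  ch <- train_result$per_pulse_charges
  if (is.null(stim_times)) stim_times <- train_result$stim_times
  if (is.null(ch) || is.null(stim_times))
    stop("per-pulse charges and stimulus times are required", call. = FALSE)
  K <- length(ch)
  if (K < 20L)
    stop("back-extrapolation requires at least 20 pulses", call. = FALSE)
  t <- stim_times - stim_times[1]
  y <- cumsum(ch)
  m <- max(2L, ceiling(K * config$steady_state_fraction))
  idx <- seq(K - m + 1L, K)
  fit <- stats::lm(y[idx] ~ t[idx])
  cf <- stats::coef(fit)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  slope <- unname(cf[2])
  new_rrp_estimate(unname(cf[1]), slope, "back_extrapolation",
                   fit_r2 = r2, flagged = slope < 0)
}

#' RRP from hypertonic sucrose discharge
#'
#' Integrates the transient current during a hypertonic sucrose application
#' above its steady-state level (mean over the final 20% of the application);
#' the integral is clipped below at 0 (samplewise clipping would rectify
#' noise into a spurious positive charge). The steady-state current itself (pA = pC/s) is the
#' sustained recruitment-driven transfer and is reported as the recruitment
#' rate.
#'
#' @param trace An [epsc_trace()]; the application window is read from the
#'   `application_onset_s`/`application_offset_s` annotations when not given.
#' @param application_window Length-2 onset/offset, s.
#' @param config An [analysis_config()].
#' @return An `rrp_estimate` with `method = "sucrose"`.
#' @export
estimate_rrp_sucrose <- function(trace, application_window = NULL,
                                 config = analysis_config()) {
  trace <- ensure_preprocessed(trace, config)
  if (is.null(application_window)) {
    on <- trace$annotations$application_onset_s
    off <- trace$annotations$application_offset_s
    if (is.null(on) || is.null(off))
      stop("sucrose application window missing from arguments and trace metadata",
           call. = FALSE)
    application_window <- c(on, off)
  }
  i1 <- time_index(trace, application_window[1])
  i2 <- time_index(trace, application_window[2])
  if (i2 <= i1)
    stop("sucrose application window is empty", call. = FALSE)
  x <- trace$samples[i1:i2]
  n_ss <- max(2L, round(length(x) * 0.2))
  ss <- mean(utils::tail(x, n_ss))
  rrp <- max(0, trapz_charge(x - ss, trace$sampling_rate))
  new_rrp_estimate(rrp, max(0, ss), "sucrose")
}
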