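#' Quantal mEPSC waveform (difference of exponentials)
#'
#' Builds the stereotyped postsynaptic current elicited by fusion of a single
#' vesicle, modelled as \eqn{k(t) = c\,(e^{-t/\tau_d} - e^{-t/\tau_r})} with the
#' scale \eqn{c} chosen so that the waveform peaks at `quantal_amplitude`.
#' All simulated traces are superpositions of copies of this kernel, so its
#' analytic peak time \eqn{t^\* = \tau_r\tau_d/(\tau_d-\tau_r)\,\log(\tau_d/\tau_r)}
#' and analytic charge \eqn{c(\tau_d-\tau_r)} double as exact oracles for the
#' downstream amplitude/charge measurements.
#'
#' @param quantal_amplitude Peak current of a single quantum, pA (> 0).
#' @param tau_rise Rise time constant, ms (> 0).
#' @param tau_decay Decay time constant, ms (must exceed `tau_rise`).
#' @param sampling_rate Sampling rate, Hz. At least two samples per
#'   `tau_rise` are required so the sampled peak stays within 0.1% of the
#'   analytic peak.
#' @return An object of class `mini_kernel`: the sampled waveform (`samples`,
#'   pA, starting at 0 and spanning 7 decay constants) plus `peak_time_ms`,
#'   `charge_pC` (analytic, per event) and the generating parameters.
#' @examples
#' k <- make_mini_kernel(20, 0.5, 5, 10000)
#' k$peak_time_ms                       # analytic stationary point
#' max(k$samples)                       # ~ 20 pA
#' @export
make_mini_kernel <- function(quantal_amplitude, tau_rise, tau_decay,
                             sampling_rate = 10000) {
  stopifnot_scalar(quantal_amplitude, "quantal_amplitude", positive = TRUE)
  stopifnot_scalar(tau_rise, "tau_rise", positive = TRUE)
  stopifnot_scalar(tau_decay, "tau_decay", positive = TRUE)
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  if (tau_decay <= tau_rise)
    stop("'tau_decay' must be greater than 'tau_rise'", call. = FALSE)
  if (sampling_rate * tau_rise / 1000 < 2)
    stop("'sampling_rate' too low: need at least 2 samples per tau_rise",
         call. = FALSE)

  tr <- tau_rise / 1000   # work in seconds
  td <- tau_decay / 1000
  t_peak <- tr * td / (td - tr) * log(td / tr)
  u_peak <- exp(-t_peak / td) - exp(-t_peak / tr)
  scale <- quantal_amplitude / u_peak

  n <- ceiling(7 * td * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  samples <- scale * (exp(-t / td) - exp(-t / tr))

  structure(list(
    samples = samples,
    quantal_amplitude = quantal_amplitude,
    tau_rise = tau_rise,
    tau_decay = tau_decay,
    sampling_rate = sampling_rate,
    peak_time_ms = t_peak * 1000,
    charge_pC = scale * (td - tr)   # analytic integral, pA*s = pC
  ), class = "mini_kernel")
}

# Charge carried by a unit-peak kernel (pC per pA of peak amplitude).
kernel_unit_charge <- function(tau_rise, tau_decay) {
  tr <- tau_rise / 1000; td <- tau_decay / 1000
  t_peak <- tr * td / (td - tr) * log(td / tr)
  u_peak <- exp(-t_peak / td) - exp(-t_peak / tr)
  (td - tr) / u_peak
}

#' @export
print.mini_kernel <- function(x, ...) {
  cat("Quantal mEPSC kernel\n")
  cat(sprintf("  peak %.3g pA at %.3g ms (tau_rise %.3g ms, tau_decay %.3g ms)\n",
              x$quantal_amplitude, x$peak_time_ms, x$tau_rise, x$tau_decay))
  cat(sprintf("  charge %.4g pC, %d samples at %g Hz\n",
              x$charge_pC, length(x$samples), x$sampling_rate))
  invisible(x)
}
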