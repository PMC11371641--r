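#' Simulation configuration for the quantal release generator
#'
#' Full generative parameter set for the synthetic recording generator. The
#' model: every release event adds one quantal kernel
#' ([make_mini_kernel()]) whose peak amplitude is lognormal with mean
#' `quantal_amplitude` and CV `quantal_cv`; spontaneous events are a
#' homogeneous Poisson process at `mini_rate`; an action potential triggers
#' `n_sync` synchronous quanta at Gaussian latencies (truncated at 0) plus
#' Poisson(`async_count_mean`) asynchronous quanta at exponential latencies
#' with mean `tau_async`; stimulus trains draw synchronous release
#' Binomial(P_k, p) from a vesicle pool of size `pool_size` replenished at
#' `recruitment_rate` vesicles/s (capped at `pool_size`); hypertonic sucrose
#' discharges the pool with per-vesicle hazard `1/sucrose_discharge_tau`.
#' Gaussian recording noise with SD `noise_sd` is added and traces are emitted
#' inward-negative. `seed` fully determines the output.
#'
#' With `deterministic = TRUE` the generator propagates expected values
#' instead of sampling: per pulse, `P_k * p` quanta are released as a single
#' event of amplitude `released * quantal_amplitude` at the mean latency, and
#' asynchronous release is rendered as 40 fractional-amplitude events at
#' stratified quantiles of the exponential latency law (total charge exact).
#' This mode exists so that closed-form oracles (geometric pool depletion,
#' back-extrapolation intercepts) hold exactly.
#'
#' @param seed Integer seed; fully determines the simulation.
#' @param sampling_rate Sampling rate, Hz.
#' @param noise_sd Additive Gaussian recording noise SD, pA.
#' @param quantal_amplitude Mean single-vesicle peak current, pA.
#' @param quantal_cv Coefficient of variation of quantal amplitude (>= 0).
#' @param tau_rise,tau_decay Kernel rise/decay time constants, ms.
#' @param mini_rate Spontaneous release rate, Hz (>= 0).
#' @param n_sync Synchronous quanta per action potential (>= 0).
#' @param sync_latency_mean,sync_latency_sd Gaussian synchronous latency, ms.
#' @param async_count_mean Mean asynchronous quanta per action potential.
#' @param tau_async Mean exponential asynchronous latency, ms.
#' @param pool_size Readily releasable vesicle count (>= 0).
#' @param release_fraction Per-pulse vesicular release probability p in [0,1].
#' @param recruitment_rate Pool replenishment, vesicles/s (>= 0).
#' @param sucrose_discharge_tau Per-vesicle sucrose discharge time constant, ms.
#' @param stimulus_times Ordered stimulus onsets, s.
#' @param deterministic Use expected-value propagation instead of sampling.
#' @return An object of class `sim_config`.
#' @seealso [make_preset()] for the wild-type / clamping-deficient presets.
#' @export
sim_config <- function(seed = 1L,
                       sampling_rate = 10000,
                       noise_sd = 3,
                       quantal_amplitude = 20,
                       quantal_cv = 0.25,
                       tau_rise = 0.5,
                       tau_decay = 5,
                       mini_rate = 2,
                       n_sync = 148,
                       sync_latency_mean = 1,
                       sync_latency_sd = 0.3,
                       async_count_mean = 12,
                       tau_async = 50,
                       pool_size = 800,
                       release_fraction = 0.2,
                       recruitment_rate = 400,
                       sucrose_discharge_tau = 500,
                       stimulus_times = 0.1,
                       deterministic = FALSE) {
  cfg <- list(seed = as.integer(seed), sampling_rate = sampling_rate,
              noise_sd = noise_sd, quantal_amplitude = quantal_amplitude,
              quantal_cv = quantal_cv, tau_rise = tau_rise,
              tau_decay = tau_decay, mini_rate = mini_rate, n_sync = n_sync,
              sync_latency_mean = sync_latency_mean,
              sync_latency_sd = sync_latency_sd,
              async_count_mean = async_count_mean, tau_async = tau_async,
              pool_size = pool_size, release_fraction = release_fraction,
              recruitment_rate = recruitment_rate,
              sucrose_discharge_tau = sucrose_discharge_tau,
              stimulus_times = as.numeric(stimulus_times),
              deterministic = isTRUE(deterministic))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot_scalar(cfg$sampling_rate, "sampling_rate", positive = TRUE)
  stopifnot_scalar(cfg$noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot_scalar(cfg$quantal_amplitude, "quantal_amplitude", positive = TRUE)
  stopifnot_scalar(cfg$quantal_cv, "quantal_cv", nonneg = TRUE)
  stopifnot_scalar(cfg$tau_rise, "tau_rise", positive = TRUE)
  stopifnot_scalar(cfg$tau_decay, "tau_decay", positive = TRUE)
  if (cfg$tau_decay <= cfg$tau_rise)
    stop("'tau_decay' must be greater than 'tau_rise'", call. = FALSE)
  stopifnot_scalar(cfg$mini_rate, "mini_rate", nonneg = TRUE)
  stopifnot_scalar(cfg$n_sync, "n_sync", nonneg = TRUE)
  stopifnot_scalar(cfg$sync_latency_mean, "sync_latency_mean", nonneg = TRUE)
  stopifnot_scalar(cfg$sync_latency_sd, "sync_latency_sd", nonneg = TRUE)
  stopifnot_scalar(cfg$async_count_mean, "async_count_mean", nonneg = TRUE)
  stopifnot_scalar(cfg$tau_async, "tau_async", positive = TRUE)
  stopifnot_scalar(cfg$pool_size, "pool_size", nonneg = TRUE)
  stopifnot_scalar(cfg$release_fraction, "release_fraction", nonneg = TRUE)
  if (cfg$release_fraction > 1)
    stop("'release_fraction' must lie in [0, 1]", call. = FALSE)
  stopifnot_scalar(cfg$recruitment_rate, "recruitment_rate", nonneg = TRUE)
  stopifnot_scalar(cfg$sucrose_discharge_tau, "sucrose_discharge_tau",
                   positive = TRUE)
  if (length(cfg$stimulus_times) > 1L &&
      is.unsorted(cfg$stimulus_times, strictly = TRUE))
    stop("'stimulus_times' must be strictly increasing", call. = FALSE)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Quantal release simulation config\n")
  cat(sprintf("  quantum %.3g pA (CV %.2g), kernel %0.3g/%0.3g ms, fs %g Hz, noise %.3g pA\n",
              x$quantal_amplitude, x$quantal_cv, x$tau_rise, x$tau_decay,
              x$sampling_rate, x$noise_sd))
  cat(sprintf("  minis %.3g Hz; evoked: %g sync (lat %.3g+/-%.3g ms) + Pois(%.3g) async (tau %.3g ms)\n",
              x$mini_rate, x$n_sync, x$sync_latency_mean, x$sync_latency_sd,
              x$async_count_mean, x$tau_async))
  cat(sprintf("  pool %g, p %.3g, recruitment %.3g /s, sucrose tau %.3g ms, %s mode, seed %d\n",
              x$pool_size, x$release_fraction, x$recruitment_rate,
              x$sucrose_discharge_tau,
              if (x$deterministic) "expected-value" else "stochastic", x$seed))
  invisible(x)
}

#' Genotype presets for the release-clamping simulator
#'
#' Encodes the two study conditions as generator parameter sets. `"WT"` is a
#' wild-type-like synapse population with tight synchronous release, a small
#' asynchronous component and a low spontaneous rate. `"PL"` models a
#' clamping-deficient synaptotagmin-1 variant: release triggering is intact
#' (identical kernel kinetics, synchronous latency and release probability)
#' but suppression of spontaneous and asynchronous fusion is impaired —
#' the spontaneous per-synapse rate is 6-fold higher, the asynchronous share
#' of evoked release is more than doubled (at unchanged total evoked charge),
#' the asynchronous decay is slower, and the total releasable pool charge is
#' unchanged.
#'
#' @param genotype `"WT"` or `"PL"`.
#' @param seed Seed stored in the returned config.
#' @param deterministic Passed through to [sim_config()].
#' @return A [sim_config()].
#' @examples
#' wt <- make_preset("WT"); pl <- make_preset("PL")
#' pl$mini_rate / wt$mini_rate          # 6-fold spontaneous rate
#' @export
make_preset <- function(genotype = c("WT", "PL"), seed = 1L,
                        deterministic = FALSE) {
  if (!is.character(genotype) || length(genotype) != 1L ||
      !genotype %in% c("WT", "PL"))
    stop("unknown genotype label; expected \"WT\" or \"PL\"", call. = FALSE)
  if (genotype == "WT") {
    sim_config(seed = seed, deterministic = deterministic,
               mini_rate = 2, n_sync = 148, async_count_mean = 12,
               tau_async = 50)
  } else {
    # reduced clamping: 6x per-synapse spontaneous rate, >2x asynchronous
    # share at equal total evoked quanta (148+12 = 128+32), slower
    # asynchronous decay; pool, p, recruitment and kinetics unchanged.
    sim_config(seed = seed, deterministic = deterministic,
               mini_rate = 12, n_sync = 128, async_count_mean = 32,
               tau_async = 100)
  }
}

#' Analysis configuration
#'
#' Tunable parameters of the measurement stages, all windows in ms.
#'
#' @param baseline_window Pre-stimulus window used for baseline estimation.
#' @param blank_window Post-stimulus window replaced by linear interpolation
#'   (stimulation artifact blanking).
#' @param fit_window Response/decay-fit window after a stimulus.
#' @param detection_threshold_k Mini detection threshold in units of noise SD.
#' @param min_event_interval Minimum separation of detected minis, ms.
#' @param steady_state_fraction Final fraction of train pulses used for the
#'   cumulative-charge linear back-extrapolation (in (0, 1]).
#' @param alpha Significance level for normality / variance screening and
#'   group comparisons (in (0, 0.5)).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(baseline_window = 50,
                            blank_window = 0.5,
                            fit_window = 500,
                            detection_threshold_k = 4,
                            min_event_interval = 3,
                            steady_state_fraction = 0.25,
                            alpha = 0.05) {
  stopifnot_scalar(baseline_window, "baseline_window", positive = TRUE)
  stopifnot_scalar(blank_window, "blank_window", positive = TRUE)
  stopifnot_scalar(fit_window, "fit_window", positive = TRUE)
  stopifnot_scalar(detection_threshold_k, "detection_threshold_k",
                   positive = TRUE)
  stopifnot_scalar(min_event_interval, "min_event_interval", positive = TRUE)
  stopifnot_scalar(steady_state_fraction, "steady_state_fraction",
                   positive = TRUE)
  if (steady_state_fraction > 1)
    stop("'steady_state_fraction' must lie in (0, 1]", call. = FALSE)
  stopifnot_scalar(alpha, "alpha", positive = TRUE)
  if (alpha >= 0.5)
    stop("'alpha' must lie in (0, 0.5)", call. = FALSE)
  structure(list(baseline_window = baseline_window,
                 blank_window = blank_window,
                 fit_window = fit_window,
                 detection_threshold_k = detection_threshold_k,
                 min_event_interval = min_event_interval,
                 steady_state_fraction = steady_state_fraction,
                 alpha = alpha),
            class = "analysis_config")
}
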