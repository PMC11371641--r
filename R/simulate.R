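## Ground-truthed synthetic voltage-clamp recordings.
##
## Every simulated trace is a superposition of quantal kernels at the event
## times listed in the accompanying ground truth, plus Gaussian noise, emitted
## inward-negative. The ground truth carries per-event class labels and
## analytic per-event charges (amplitude x unit-kernel charge), so each
## analysis stage can be scored by parameter recovery.

# Add amplitude-scaled copies of a unit-peak kernel at the given times (s).
render_events <- function(times, amps, n, fs, kernel) {
  L <- length(kernel)
  sig <- numeric(n + L)
  if (length(times)) {
    i0 <- round(times * fs) + 1L
    keep <- i0 >= 1L & i0 <= n
    i0 <- i0[keep]; a <- amps[keep]
    for (e in seq_along(i0))
      sig[i0[e]:(i0[e] + L - 1L)] <- sig[i0[e]:(i0[e] + L - 1L)] + a[e] * kernel
  }
  sig[seq_len(n)]
}

unit_kernel <- function(cfg)
  make_mini_kernel(1, cfg$tau_rise, cfg$tau_decay, cfg$sampling_rate)$samples

# Assemble the recorded trace: inward-negative polarity plus recording noise.
make_sim_trace <- function(signal, cfg, stimulus_times, annotations) {
  noise <- if (cfg$noise_sd > 0)
    stats::rnorm(length(signal), 0, cfg$noise_sd) else 0
  epsc_trace(-signal + noise, cfg$sampling_rate,
             polarity = "inward_negative",
             stimulus_times = stimulus_times, annotations = annotations)
}

new_ground_truth <- function(times, amps, class, pulse, cfg,
                             per_pulse_released_charge = NULL,
                             true_rrp_charge = NA_real_) {
  stopifnot(length(times) == length(amps), length(times) == length(class))
  o <- order(times)
  times <- times[o]; amps <- amps[o]; class <- class[o]
  pulse <- if (is.null(pulse)) rep(NA_integer_, length(times)) else pulse[o]
  kq <- kernel_unit_charge(cfg$tau_rise, cfg$tau_decay)
  ch <- amps * kq
  sync <- sum(ch[class == "synchronous"])
  async <- sum(ch[class == "asynchronous"])
  af <- if (sync + async > 0) async / (sync + async) else NA_real_
  structure(list(
    event_times = times, event_amplitudes = amps, event_class = class,
    event_pulse = pulse, event_charges = ch,
    per_pulse_released_charge = per_pulse_released_charge,
    true_async_fraction = af, true_rrp_charge = true_rrp_charge,
    unit_charge_pC = kq), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d events (%s)\n", length(x$event_times),
              paste(sprintf("%s=%d", names(table(x$event_class)),
                            as.integer(table(x$event_class))), collapse = ", ")))
  if (!is.na(x$true_async_fraction))
    cat(sprintf("  true asynchronous charge fraction %.4f\n",
                x$true_async_fraction))
  if (!is.na(x$true_rrp_charge))
    cat(sprintf("  true RRP charge %.4g pC\n", x$true_rrp_charge))
  invisible(x)
}

# Stratified fractional-event rendering of an expected asynchronous count
# (deterministic mode): exact total charge, smooth exponential profile.
async_strata <- function(lambda, tau_s, n_strata = 40L) {
  if (lambda <= 0) return(list(lat = numeric(), amp_frac = numeric()))
  u <- (seq_len(n_strata) - 0.5) / n_strata
  list(lat = -tau_s * log(1 - u), amp_frac = rep(lambda / n_strata, n_strata))
}

#' Simulate a spontaneous miniature EPSC recording
#'
#' Event times follow a homogeneous Poisson process at `mini_rate`; each event
#' adds one quantal kernel with a lognormal amplitude (mean
#' `quantal_amplitude`, CV `quantal_cv`).
#'
#' @param config A [sim_config()].
#' @param duration Recording length, s (> 0).
#' @return A list with elements `trace` ([epsc_trace()]) and `ground_truth`.
#' @export
simulate_minis <- function(config, duration) {
  config <- validate_sim_config(config)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  with_seed(config$seed, {
    n_ev <- stats::rpois(1, config$mini_rate * duration)
    times <- sort(stats::runif(n_ev, 0, duration))
    amps <- rlnorm_mean_cv(n_ev, config$quantal_amplitude, config$quantal_cv)
    n <- round(duration * config$sampling_rate)
    sig <- render_events(times, amps, n, config$sampling_rate,
                         unit_kernel(config))
    trace <- make_sim_trace(sig, config, numeric(),
                            list(protocol = "minis"))
    gt <- new_ground_truth(times, amps, rep("spontaneous", n_ev), NULL, config)
    list(trace = trace, ground_truth = gt)
  })
}

#' Simulate a single evoked EPSC
#'
#' One action potential at `config$stimulus_times[1]` releases `n_sync`
#' synchronous quanta at Gaussian latencies (truncated at 0) and
#' Poisson(`async_count_mean`) asynchronous quanta at exponential latencies
#' with mean `tau_async`. The ground-truth asynchronous charge fraction is
#' recorded from the summed per-class event charges.
#'
#' @param config A [sim_config()] with exactly one stimulus time.
#' @return A list with elements `trace` and `ground_truth`.
#' @export
simulate_evoked_epsc <- function(config) {
  config <- validate_sim_config(config)
  if (length(config$stimulus_times) != 1L)
    stop("evoked EPSC simulation requires exactly one stimulus time",
         call. = FALSE)
  stim <- config$stimulus_times[1]
  tau_as <- config$tau_async / 1000
  duration <- stim + max(0.6, 6 * tau_as + 0.1)
  with_seed(config$seed, {
    if (config$deterministic) {
      s_lat <- if (config$n_sync > 0) config$sync_latency_mean / 1000 else numeric()
      s_amp <- if (config$n_sync > 0)
        config$n_sync * config$quantal_amplitude else numeric()
      st <- async_strata(config$async_count_mean, tau_as)
      a_lat <- st$lat
      a_amp <- st$amp_frac * config$quantal_amplitude
    } else {
      s_lat <- pmax(0, stats::rnorm(config$n_sync,
                                    config$sync_latency_mean / 1000,
                                    config$sync_latency_sd / 1000))
      s_amp <- rlnorm_mean_cv(length(s_lat), config$quantal_amplitude,
                              config$quantal_cv)
      n_as <- stats::rpois(1, config$async_count_mean)
      a_lat <- stats::rexp(n_as, 1 / tau_as)
      a_amp <- rlnorm_mean_cv(n_as, config$quantal_amplitude, config$quantal_cv)
    }
    times <- stim + c(s_lat, a_lat)
    amps <- c(s_amp, a_amp)
    class <- c(rep("synchronous", length(s_lat)),
               rep("asynchronous", length(a_lat)))
    n <- round(duration * config$sampling_rate)
    sig <- render_events(times, amps, n, config$sampling_rate,
                         unit_kernel(config))
    trace <- make_sim_trace(sig, config, stim, list(protocol = "epsc"))
    gt <- new_ground_truth(times, amps, class,
                           rep(1L, length(times)), config)
    list(trace = trace, ground_truth = gt)
  })
}

#' Simulate a uniform stimulus train with pool depletion and recruitment
#'
#' Pool dynamics: starting from `P_1 = pool_size`, pulse k releases
#' Binomial(`P_k`, p) synchronous quanta (expected-value mode: `P_k p`), then
#' `P_{k+1} = min(pool_size, P_k - released_k + round(rho * dt))` with
#' recruitment rate rho in vesicles/s, where `released_k` counts synchronous
#' quanta plus the asynchronous quanta whose release times fell in the
#' preceding inter-stimulus interval. Asynchronous release triggered by
#' pulse k is Poisson with mean `async_count_mean` scaled by that pulse's
#' synchronous release relative to the first-pulse expectation
#' `pool_size * p` (so the asynchronous tail tracks recent release);
#' asynchronous quanta draw on the same vesicle pool, and deplete it when
#' they actually fuse, not at the triggering pulse. Per-pulse released
#' charge and the true pool charge (`pool_size` x mean quantal charge) are
#' recorded.
#'
#' @param config A [sim_config()] with >= 2 uniformly spaced stimulus times.
#' @return A list with elements `trace` and `ground_truth`; the ground truth
#'   carries `per_pulse_released_charge` (pC) and `true_rrp_charge` (pC).
#' @seealso [train_stimulus_times()] to build the stimulus schedule.
#' @export
simulate_train <- function(config) {
  config <- validate_sim_config(config)
  st <- config$stimulus_times
  if (length(st) < 2L)
    stop("train simulation requires at least 2 stimulus times", call. = FALSE)
  dt <- diff(st)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("train stimulus times must be uniformly spaced", call. = FALSE)
  dt <- dt[1]
  tau_as <- config$tau_async / 1000
  duration <- st[length(st)] + dt + max(0.5, 5 * tau_as)
  q <- config$quantal_amplitude
  p <- config$release_fraction
  e_first <- config$pool_size * p
  with_seed(config$seed, {
    times <- amps <- numeric(0)
    class <- character(0); pulse <- integer(0)
    pool <- config$pool_size
    released <- numeric(length(st))
    decay <- exp(-dt / tau_as)
    # asynchronous quanta triggered earlier but not yet fused: a scalar
    # expected mass in deterministic mode, a list of fusion times otherwise
    pending_mass <- 0
    pending_times <- numeric(0)
    for (k in seq_along(st)) {
      if (config$deterministic) {
        # asynchronous fusions during the preceding interval deplete first
        fused_async <- pending_mass * (1 - decay)
        pending_mass <- pending_mass * decay
        pool <- max(0, min(config$pool_size,
                           pool - fused_async +
                             (if (k > 1) config$recruitment_rate * dt else 0)))
        rel <- pool * p
        if (rel > 0) {
          times <- c(times, st[k] + config$sync_latency_mean / 1000)
          amps <- c(amps, rel * q)
          class <- c(class, "synchronous"); pulse <- c(pulse, k)
        }
        pool <- pool - rel
        lam <- if (e_first > 0) config$async_count_mean * rel / e_first else 0
        lam <- min(lam, pool)
        sa <- async_strata(lam, tau_as)
        if (length(sa$lat)) {
          times <- c(times, st[k] + sa$lat)
          amps <- c(amps, sa$amp_frac * q)
          class <- c(class, rep("asynchronous", length(sa$lat)))
          pulse <- c(pulse, rep(k, length(sa$lat)))
        }
        pending_mass <- pending_mass + lam
      } else {
        fused_async <- sum(pending_times < st[k])
        pending_times <- pending_times[pending_times >= st[k]]
        recruit <- if (k > 1) round(config$recruitment_rate * dt) else 0
        pool <- max(0, min(config$pool_size, pool - fused_async + recruit))
        rel <- stats::rbinom(1, as.integer(round(pool)), p)
        if (rel > 0) {
          lat <- pmax(0, stats::rnorm(rel, config$sync_latency_mean / 1000,
                                      config$sync_latency_sd / 1000))
          times <- c(times, st[k] + lat)
          amps <- c(amps, rlnorm_mean_cv(rel, q, config$quantal_cv))
          class <- c(class, rep("synchronous", rel))
          pulse <- c(pulse, rep(k, rel))
        }
        pool <- pool - rel
        lam <- if (e_first > 0) config$async_count_mean * rel / e_first else 0
        n_as <- min(stats::rpois(1, lam), as.integer(pool))
        if (n_as > 0) {
          a_lat <- stats::rexp(n_as, 1 / tau_as)
          times <- c(times, st[k] + a_lat)
          amps <- c(amps, rlnorm_mean_cv(n_as, q, config$quantal_cv))
          class <- c(class, rep("asynchronous", n_as))
          pulse <- c(pulse, rep(k, n_as))
          pending_times <- c(pending_times, st[k] + a_lat)
        }
      }
      released[k] <- rel
    }
    kq <- kernel_unit_charge(config$tau_rise, config$tau_decay)
    per_pulse <- vapply(seq_along(st),
                        function(k) sum(amps[pulse == k]) * kq, numeric(1))
    n <- round(duration * config$sampling_rate)
    sig <- render_events(times, amps, n, config$sampling_rate,
                         unit_kernel(config))
    trace <- make_sim_trace(sig, config, st,
                            list(protocol = "train",
                                 train_rate_Hz = 1 / dt))
    gt <- new_ground_truth(times, amps, class, pulse, config,
                           per_pulse_released_charge = per_pulse,
                           true_rrp_charge = config$pool_size * q * kq)
    gt$released_per_pulse <- released
    list(trace = trace, ground_truth = gt)
  })
}

#' Uniform train stimulus schedule
#'
#' @param rate_hz Stimulation frequency, Hz.
#' @param n_pulses Number of pulses.
#' @param start First stimulus onset, s.
#' @return Numeric vector of stimulus onsets, s.
#' @export
train_stimulus_times <- function(rate_hz, n_pulses, start = 0.1)
  start + (seq_len(n_pulses) - 1) / rate_hz

#' Simulate a hypertonic sucrose application
#'
#' During the application window each of the `pool_size` vesicles releases
#' independently with hazard `1/sucrose_discharge_tau` (an inhomogeneous
#' Poisson discharge whose rate is proportional to the remaining pool),
#' superimposed on steady-state spontaneous release at `mini_rate` throughout
#' the trace. The true pool charge is `pool_size` x mean quantal charge.
#'
#' @param config A [sim_config()].
#' @param application_window Numeric length-2, application onset/offset, s.
#' @return A list with elements `trace` and `ground_truth`. The trace is
#'   annotated with `sucrose_concentration = "500 mM"` and the window.
#' @export
simulate_sucrose <- function(config, application_window) {
  config <- validate_sim_config(config)
  if (length(application_window) != 2L ||
      application_window[1] < 0 ||
      application_window[2] <= application_window[1])
    stop("'application_window' must be increasing times within the trace",
         call. = FALSE)
  t_on <- application_window[1]; t_off <- application_window[2]
  duration <- t_off + 0.5
  q <- config$quantal_amplitude
  tau_s <- config$sucrose_discharge_tau / 1000
  with_seed(config$seed, {
    if (config$deterministic) {
      m <- 200L
      frac_rel <- 1 - exp(-(t_off - t_on) / tau_s)
      u <- frac_rel * (seq_len(m) - 0.5) / m
      d_times <- t_on - tau_s * log(1 - u)
      d_amps <- rep(config$pool_size * q / m, m)
    } else {
      lat <- stats::rexp(config$pool_size, 1 / tau_s)
      lat <- lat[lat <= (t_off - t_on)]
      d_times <- t_on + lat
      d_amps <- rlnorm_mean_cv(length(d_times), q, config$quantal_cv)
    }
    n_sp <- stats::rpois(1, config$mini_rate * duration)
    s_times <- sort(stats::runif(n_sp, 0, duration))
    s_amps <- rlnorm_mean_cv(n_sp, q, config$quantal_cv)
    times <- c(d_times, s_times)
    amps <- c(d_amps, s_amps)
    class <- c(rep("asynchronous", length(d_times)),
               rep("spontaneous", n_sp))
    n <- round(duration * config$sampling_rate)
    sig <- render_events(times, amps, n, config$sampling_rate,
                         unit_kernel(config))
    kq <- kernel_unit_charge(config$tau_rise, config$tau_decay)
    trace <- make_sim_trace(sig, config, numeric(),
                            list(protocol = "sucrose",
                                 sucrose_concentration = "500 mM",
                                 application_onset_s = t_on,
                                 application_offset_s = t_off))
    gt <- new_ground_truth(times, amps, class, NULL, config,
                           true_rrp_charge = config$pool_size * q * kq)
    list(trace = trace, ground_truth = gt)
  })
}
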