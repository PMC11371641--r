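# Independent oracles and fixture builders used across the suite.

# Exhaustive two-tailed Mann-Whitney p value by enumeration of all splits.
perm_mwu_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  splits <- utils::combn(nx + ny, nx)
  U <- apply(splits, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  mean(abs(U - mu) >= abs(u_obs - mu) - 1e-9)
}

# Trace holding a known decay y(t) preceded by `pad` zero samples, already in
# analysis (positive-up, preprocessed) form.
decay_trace <- function(y, fs = 10000, pad = 100, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  epsc_trace(c(rep(0, pad), y), fs, polarity = "positive_up",
             annotations = list(preprocessed = TRUE, baseline_pA = 0,
                                noise_sd_pA = noise_sd))
}

biexp_curve <- function(A_f, tau_f_ms, A_s, tau_s_ms, dur_s = 0.25,
                        fs = 10000) {
  t <- seq(0, dur_s, by = 1 / fs)
  A_f * exp(-t / (tau_f_ms / 1000)) + A_s * exp(-t / (tau_s_ms / 1000))
}

# Fraction of `a` times that have a partner in `b` within `tol` seconds.
match_fraction <- function(a, b, tol = 0.002) {
  if (!length(a)) return(NA_real_)
  if (!length(b)) return(0)
  mean(vapply(a, function(t) any(abs(b - t) <= tol), logical(1)))
}

# 20 Hz deterministic train config with a prescribed asynchronous charge
# share and constant per-pulse release (recruitment caps the pool).
ladder_train_config <- function(share, n_pulses = 100) {
  sim_config(seed = 1, deterministic = TRUE, noise_sd = 0, quantal_cv = 0,
             pool_size = 1000, release_fraction = 0.16,
             recruitment_rate = 12800,
             async_count_mean = share / (1 - share) * 160, tau_async = 300,
             stimulus_times = train_stimulus_times(20, n_pulses))
}
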