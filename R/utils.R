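## Internal helpers shared across stages.

# Trapezoidal integral of current (pA) sampled at `fs` Hz -> charge in pC
# (1 pA * 1 s == 1 pC).
trapz_charge <- function(x, fs) {
  if (length(x) < 2L) return(0)
  pracma::trapz(seq_along(x) / fs, x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic per-cell / per-protocol seed streams, kept below 2^31.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) s <- (s * 7919 + as.double(i) * 104729 + 1) %% 2147483647
  as.integer(s)
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Lognormal with mean `m` and coefficient of variation `cv` (cv = 0 -> constant).
rlnorm_mean_cv <- function(n, m, cv) {
  if (cv <= 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}
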