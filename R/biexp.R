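#' Fit a bi-exponential decay to an EPSC
#'
#' Least-squares fit of \eqn{A_f e^{-t/\tau_f} + A_s e^{-t/\tau_s}} to the
#' decay phase of an evoked EPSC, from the identified peak to the end of the
#' fit window. The fast component captures synchronous release driving the
#' phasic EPSC; the slow component captures the asynchronous release tail.
#' Fitting is performed with Levenberg-Marquardt in a log-tau
#' parameterisation with the ordering \eqn{\tau_s = \tau_f + e^{\delta}}
#' enforced by construction; amplitudes are bounded below at 0.
#' Initialisation: \eqn{\tau_f} from the 80->20% decay time,
#' \eqn{\tau_s = 10\tau_f}, amplitudes from a two-point linear solve.
#' Fits whose components collapse (\eqn{\tau_s/\tau_f < 1.5}) are refit and
#' reported as mono-exponential with `A_slow = 0` and `tau_slow = NA`.
#'
#' @param trace A preprocessed (positive-up) [epsc_trace()].
#' @param peak_time Time of the EPSC peak, s (e.g. from [epsc_metrics()]).
#' @param config An [analysis_config()]; the decay segment runs from
#'   `peak_time` to `peak_time + fit_window`.
#' @return An object of class `biexp_fit` with elements `A_fast`, `tau_fast`
#'   (ms), `A_slow`, `tau_slow` (ms), `relative_slow_amplitude`, `fit_rmse`
#'   (pA), `converged`, `peak_time`, and the fitted segment (`t` seconds from
#'   peak, `y` pA). Methods: `print`, `coef`, `predict`, `residuals`, `plot`.
#' @export
fit_biexp_decay <- function(trace, peak_time, config = analysis_config()) {
  trace <- ensure_preprocessed(trace, config)
  fs <- trace$sampling_rate
  i1 <- time_index(trace, peak_time)
  i2 <- min(length(trace$samples),
            time_index(trace, peak_time + config$fit_window / 1000))
  if (i2 - i1 + 1L < 10L)
    stop("fewer than 10 samples in the decay segment", call. = FALSE)
  y <- trace$samples[i1:i2]
  t <- (seq_along(y) - 1) / fs

  out <- list(peak_time = peak_time, t = t, y = y, converged = FALSE,
              A_fast = NA_real_, tau_fast = NA_real_,
              A_slow = NA_real_, tau_slow = NA_real_,
              relative_slow_amplitude = NA_real_, fit_rmse = NA_real_,
              diagnostics = NULL)
  class(out) <- "biexp_fit"

  y0 <- max(y[1], max(y) * 1e-3, .Machine$double.eps)
  tf0 <- decay_time_start(t, y, y0)
  ts0 <- 10 * tf0
  amps <- two_point_amplitudes(t, y, y0, tf0, ts0)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ Af * exp(-t / exp(ltf)) + As * exp(-t / (exp(ltf) + exp(lds))),
      start = list(Af = amps[1], As = amps[2],
                   ltf = log(tf0), lds = log(ts0 - tf0)),
      lower = c(0, 0, log(1 / fs / 10), -20),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out$diagnostics <- conditionMessage(fit)
    return(out)
  }
  cf <- stats::coef(fit)
  tau_f <- exp(cf[["ltf"]])
  tau_s <- tau_f + exp(cf[["lds"]])
  A_f <- cf[["Af"]]; A_s <- cf[["As"]]

  collapsed <- tau_s / tau_f < 1.5 ||
    (A_s * tau_s) < 0.01 * (A_f * tau_f + A_s * tau_s)
  if (collapsed) {
    mono <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-t / exp(ltau)),
                        start = list(A = A_f + A_s,
                                     ltau = log(max(tau_f, 1 / fs))),
                        lower = c(0, log(1 / fs / 10)),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(mono)) {
      cm <- stats::coef(mono)
      out$A_fast <- cm[["A"]]
      out$tau_fast <- exp(cm[["ltau"]]) * 1000
      out$A_slow <- 0
      out$tau_slow <- NA_real_
      out$relative_slow_amplitude <- 0
      out$fit_rmse <- sqrt(mean(stats::resid(mono)^2))
      out$converged <- TRUE
      out$diagnostics <- "component collapse: reported as mono-exponential"
      return(out)
    }
  }
  out$A_fast <- A_f
  out$tau_fast <- tau_f * 1000
  out$A_slow <- A_s
  out$tau_slow <- tau_s * 1000
  out$relative_slow_amplitude <- if (A_f + A_s > 0) A_s / (A_f + A_s) else NA_real_
  out$fit_rmse <- sqrt(mean(stats::resid(fit)^2))
  out$converged <- fit$convInfo$isConv %||% TRUE
  if (!out$converged) out$diagnostics <- "Levenberg-Marquardt did not converge"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tau seed from the 80% -> 20% decay time (exact for a mono-exponential).
decay_time_start <- function(t, y, y0) {
  t80 <- t[which(y <= 0.8 * y0)[1]]
  t20 <- t[which(y <= 0.2 * y0)[1]]
  if (is.na(t80) || is.na(t20) || t20 <= t80) return(max(t) / 5)
  (t20 - t80) / log(4)
}

# Solve Af, As from y(0) and y(t_mid) given candidate time constants.
two_point_amplitudes <- function(t, y, y0, tf, ts) {
  tm <- min(max(t), 3 * tf)
  ym <- y[which.min(abs(t - tm))]
  M <- rbind(c(1, 1), c(exp(-tm / tf), exp(-tm / ts)))
  a <- tryCatch(solve(M, c(y0, ym)), error = function(e) c(y0 * 0.9, y0 * 0.1))
  pmax(a, y0 * 1e-3)
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat("Bi-exponential EPSC decay fit\n")
  if (!x$converged) {
    cat("  NOT converged:", x$diagnostics %||% "", "\n")
    return(invisible(x))
  }
  if (!is.na(x$tau_slow)) {
    cat(sprintf("  fast: A = %.4g pA, tau = %.4g ms\n", x$A_fast, x$tau_fast))
    cat(sprintf("  slow: A = %.4g pA, tau = %.4g ms (relative amplitude %.3f)\n",
                x$A_slow, x$tau_slow, x$relative_slow_amplitude))
  } else {
    cat(sprintf("  mono-exponential: A = %.4g pA, tau = %.4g ms (no slow component)\n",
                x$A_fast, x$tau_fast))
  }
  cat(sprintf("  RMSE %.3g pA over %d samples\n", x$fit_rmse, length(x$y)))
  invisible(x)
}

#' @export
coef.biexp_fit <- function(object, ...) {
  c(A_fast = object$A_fast, tau_fast = object$tau_fast,
    A_slow = object$A_slow, tau_slow = object$tau_slow)
}

#' Evaluate a fitted EPSC decay
#'
#' @param object A `biexp_fit`.
#' @param times Absolute times (s) at which to evaluate the fitted decay;
#'   defaults to the fitted segment.
#' @param ... Unused.
#' @return Fitted current, pA (0 before the peak).
#' @export
predict.biexp_fit <- function(object, times = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit",
                              call. = FALSE)
  tt <- if (is.null(times)) object$t else times - object$peak_time
  slow <- if (is.na(object$tau_slow)) 0 else
    object$A_slow * exp(-tt / (object$tau_slow / 1000))
  out <- object$A_fast * exp(-tt / (object$tau_fast / 1000)) + slow
  out[tt < 0] <- 0
  out
}

#' @export
residuals.biexp_fit <- function(object, ...) {
  object$y - predict(object)
}

#' @export
plot.biexp_fit <- function(x, ...) {
  graphics::plot(x$t * 1000, x$y, type = "l", col = "grey40",
                 xlab = "time from peak (ms)", ylab = "current (pA)", ...)
  if (x$converged) {
    graphics::lines(x$t * 1000, predict(x), col = "black", lty = 2)
    graphics::lines(x$t * 1000,
                    x$A_fast * exp(-x$t / (x$tau_fast / 1000)), col = "red3")
    if (!is.na(x$tau_slow))
      graphics::lines(x$t * 1000,
                      x$A_slow * exp(-x$t / (x$tau_slow / 1000)), col = "blue3")
  }
  invisible(x)
}

#' Decompose an EPSC into synchronous and asynchronous charge
#'
#' Synchronous charge is the current integral of the rise phase plus the
#' analytic integral of the fitted fast decay component (\eqn{A_f \tau_f});
#' asynchronous charge is the analytic integral of the slow component
#' (\eqn{A_s \tau_s}). The integrals run from the peak to infinity, making the
#' decomposition independent of the fit-window length.
#'
#' @param fit A converged [fit_biexp_decay()] result.
#' @param rise_charge Trapezoidal current integral from stimulus onset to the
#'   peak, pC.
#' @return A list with `sync_charge`, `async_charge` (pC) and
#'   `async_fraction` = async / (sync + async) (`NA` when both are zero).
#' @export
decompose_sync_async <- function(fit, rise_charge) {
  if (!inherits(fit, "biexp_fit") || !isTRUE(fit$converged))
    stop("'fit' must be a converged biexp_fit", call. = FALSE)
  stopifnot_scalar(rise_charge, "rise_charge", nonneg = TRUE)
  sync <- rise_charge + fit$A_fast * fit$tau_fast / 1000    # pA*ms -> pC
  async <- if (is.na(fit$tau_slow)) 0 else fit$A_slow * fit$tau_slow / 1000
  frac <- if (sync + async > 0) async / (sync + async) else NA_real_
  list(sync_charge = sync, async_charge = async, async_fraction = frac)
}
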