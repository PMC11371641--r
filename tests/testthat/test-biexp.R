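test_that("noiseless bi-exponential parameters are recovered exactly", {
  tr <- decay_trace(biexp_curve(1000, 5, 100, 50))
  fit <- fit_biexp_decay(tr, 100 / 10000, analysis_config(fit_window = 250))
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(1000, 5, 100, 50), tolerance = 0.01)
  expect_lt(fit$fit_rmse, 1e-3)
  expect_equal(fit$relative_slow_amplitude, 100 / 1100, tolerance = 0.01)
})

test_that("parameters are recovered within 5% median under 5 pA noise", {
  errs <- sapply(1:20, function(s) {
    tr <- decay_trace(biexp_curve(1000, 5, 100, 50), noise_sd = 5, seed = s)
    fit <- fit_biexp_decay(tr, 100 / 10000, analysis_config(fit_window = 250))
    abs(coef(fit) / c(1000, 5, 100, 50) - 1)
  })
  expect_true(all(apply(errs, 1, median) < 0.05))
})

test_that("a mono-exponential input collapses to a fast-only fit", {
  tr <- decay_trace(500 * exp(-seq(0, 0.25, by = 1e-4) / 0.008))
  fit <- fit_biexp_decay(tr, 100 / 10000, analysis_config(fit_window = 250))
  expect_true(fit$converged)
  expect_equal(fit$A_fast, 500, tolerance = 0.01)
  expect_equal(fit$tau_fast, 8, tolerance = 0.01)
  slow_charge <- if (is.na(fit$tau_slow)) 0 else fit$A_slow * fit$tau_slow
  expect_lt(slow_charge, 0.01 * (fit$A_fast * fit$tau_fast + slow_charge))
})

test_that("short decay segments raise a fit error", {
  tr <- decay_trace(rep(1, 5), pad = 0)
  expect_error(fit_biexp_decay(tr, 0, analysis_config(fit_window = 250)),
               "10 samples")
})

test_that("predict/residuals reproduce the fitted segment", {
  tr <- decay_trace(biexp_curve(800, 4, 50, 40))
  fit <- fit_biexp_decay(tr, 100 / 10000, analysis_config(fit_window = 200))
  expect_lt(max(abs(residuals(fit))), 1e-3)
  expect_equal(predict(fit)[1], fit$A_fast + fit$A_slow, tolerance = 1e-6)
})

test_that("synchronous/asynchronous decomposition matches the closed form", {
  fit <- structure(list(converged = TRUE, A_fast = 1000, tau_fast = 5,
                        A_slow = 100, tau_slow = 50), class = "biexp_fit")
  d <- decompose_sync_async(fit, 0.2)
  expect_equal(d$sync_charge, 0.2 + 5, tolerance = 1e-12)
  expect_equal(d$async_charge, 5, tolerance = 1e-12)
  expect_equal(d$async_fraction, 5 / 10.2, tolerance = 1e-12)

  # no slow component -> zero asynchronous fraction
  fit$A_slow <- 0
  expect_equal(decompose_sync_async(fit, 0.2)$async_fraction, 0)
  # symmetric components with no rise charge -> one half
  fit2 <- structure(list(converged = TRUE, A_fast = 1000, tau_fast = 5,
                         A_slow = 100, tau_slow = 50), class = "biexp_fit")
  expect_equal(decompose_sync_async(fit2, 0)$async_fraction,
               5 / 10, tolerance = 1e-12)
  # both charges zero -> undefined fraction
  zero <- structure(list(converged = TRUE, A_fast = 0, tau_fast = 5,
                         A_slow = 0, tau_slow = 50), class = "biexp_fit")
  expect_true(is.na(decompose_sync_async(zero, 0)$async_fraction))
  # non-converged fits are rejected
  bad <- structure(list(converged = FALSE), class = "biexp_fit")
  expect_error(decompose_sync_async(bad, 0), "converged")
})

test_that("decomposed charges add up to the measured EPSC charge end-to-end", {
  for (g in c("WT", "PL")) {
    cc <- make_preset(g, seed = 17); cc$noise_sd <- 0
    sim <- simulate_evoked_epsc(cc)
    a <- analyze_epsc(sim$trace)
    expect_true(a$fit$converged)
    expect_equal(a$sync_charge + a$async_charge, a$metrics$charge,
                 tolerance = 0.01)
  }
})

test_that("recovered asynchronous fraction increases along a generator ladder", {
  shares <- c(0.02, 0.1, 0.2, 0.35)
  rec <- vapply(shares, function(sh) {
    n_total <- 160
    cc <- sim_config(seed = 1, deterministic = TRUE, noise_sd = 0,
                     quantal_cv = 0, n_sync = round(n_total * (1 - sh)),
                     async_count_mean = n_total * sh)
    analyze_epsc(simulate_evoked_epsc(cc)$trace)$async_fraction
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
  expect_equal(rec, shares, tolerance = 0.35)
})
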