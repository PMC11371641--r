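test_that("a clean synchronous train shows no rundown and no asynchronous charge", {
  # expected-value mode, recruitment caps the pool -> identical pulses
  cc <- sim_config(seed = 1, deterministic = TRUE, noise_sd = 0,
                   quantal_cv = 0, async_count_mean = 0, pool_size = 1000,
                   release_fraction = 0.16, recruitment_rate = 12800,
                   stimulus_times = train_stimulus_times(20, 30))
  tr <- analyze_train(simulate_train(cc)$trace)
  expect_true(all(abs(tr$normalized_amplitudes - 1) < 0.02))
  expect_lt(tr$train_async_fraction, 0.02)
})

test_that("train asynchronous fraction tracks the generator share and is monotone", {
  shares <- c(0, 0.1, 0.3, 0.5)
  rec <- vapply(shares, function(sh) {
    st <- simulate_train(ladder_train_config(sh, n_pulses = 50))
    analyze_train(st$trace)$train_async_fraction
  }, numeric(1))
  expect_true(all(abs(rec - shares) <= 0.05))
  expect_true(all(diff(rec) > 0))
})

test_that("stochastic trains recover the ground-truth asynchronous share", {
  errs <- vapply(1:8, function(s) {
    cc <- make_preset("PL", seed = s)
    cc$stimulus_times <- train_stimulus_times(20, 50)
    sim <- simulate_train(cc)
    analyze_train(sim$trace)$train_async_fraction -
      sim$ground_truth$true_async_fraction
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.05)
})

test_that("post-train tail decay recovers a pure exponential time constant", {
  cc <- sim_config(seed = 2, deterministic = TRUE, noise_sd = 0,
                   quantal_cv = 0, pool_size = 1000, release_fraction = 0.2,
                   recruitment_rate = 4000, async_count_mean = 60,
                   tau_async = 200,
                   stimulus_times = train_stimulus_times(20, 30))
  tr <- analyze_train(simulate_train(cc)$trace)
  expect_equal(tr$tail_tau, 200, tolerance = 0.05)
  expect_gt(tr$tail_charge, 0)
})

test_that("back-extrapolation is exact on collinear cumulative charges", {
  res <- backextrapolate_rrp(list(per_pulse_charges = rep(1, 40),
                                  stim_times = train_stimulus_times(40, 40)))
  expect_equal(res$rrp_charge, 1, tolerance = 1e-9)
  expect_equal(res$recruitment_rate, 40, tolerance = 1e-9)
  expect_false(res$flagged)

  zero <- backextrapolate_rrp(list(per_pulse_charges = rep(0, 40),
                                   stim_times = train_stimulus_times(40, 40)))
  expect_equal(zero$rrp_charge, 0)
  expect_equal(zero$recruitment_rate, 0)
})

test_that("back-extrapolation recovers the initial pool under depletion with recruitment", {
  cc <- make_preset("WT", seed = 1, deterministic = TRUE)
  cc$noise_sd <- 0
  cc$stimulus_times <- train_stimulus_times(40, 100)
  sim <- simulate_train(cc)
  est <- backextrapolate_rrp(analyze_train(sim$trace))
  expect_lt(abs(est$rrp_charge / sim$ground_truth$true_rrp_charge - 1), 0.15)
  expect_gt(est$fit_r2, 0.99)
  expect_error(backextrapolate_rrp(list(per_pulse_charges = rep(1, 10),
                                        stim_times = train_stimulus_times(40, 10))),
               "20 pulses")
})

test_that("sucrose RRP estimate matches ground truth and scales with pool size", {
  base <- make_preset("WT", seed = 6)
  base$noise_sd <- 0; base$mini_rate <- 0; base$quantal_cv <- 0
  sim <- simulate_sucrose(base, c(0.3, 5.3))
  est <- estimate_rrp_sucrose(sim$trace)
  expect_identical(est$method, "sucrose")
  expect_lt(abs(est$rrp_charge / sim$ground_truth$true_rrp_charge - 1), 0.05)

  dbl <- base; dbl$pool_size <- 2 * base$pool_size
  est2 <- estimate_rrp_sucrose(simulate_sucrose(dbl, c(0.3, 5.3))$trace)
  expect_equal(est2$rrp_charge / est$rrp_charge, 2, tolerance = 0.05)

  flat <- epsc_trace(rep(0, 20000), 10000, polarity = "positive_up",
                     annotations = list(preprocessed = TRUE))
  expect_equal(estimate_rrp_sucrose(flat, c(0.5, 1.5))$rrp_charge, 0)
  expect_error(estimate_rrp_sucrose(flat), "window missing")
})

test_that("sucrose and train pool estimates agree on matched configurations", {
  cc <- make_preset("WT", seed = 1, deterministic = TRUE)
  cc$noise_sd <- 0
  cc$stimulus_times <- train_stimulus_times(40, 100)
  be <- backextrapolate_rrp(analyze_train(simulate_train(cc)$trace))
  cs <- make_preset("WT", seed = 1)
  cs$noise_sd <- 0; cs$mini_rate <- 0; cs$quantal_cv <- 0
  su <- estimate_rrp_sucrose(simulate_sucrose(cs, c(0.3, 5.3))$trace)
  expect_lt(abs(be$rrp_charge / su$rrp_charge - 1), 0.2)
})

test_that("train analysis validates its stimulus schedule", {
  tr <- epsc_trace(rep(0, 50000), 10000, polarity = "positive_up",
                   stimulus_times = c(0.1, 0.15, 0.21, 0.25, 0.3),
                   annotations = list(preprocessed = TRUE))
  expect_error(analyze_train(tr), "uniform")
  tr2 <- epsc_trace(rep(0, 50000), 10000, polarity = "positive_up",
                    stimulus_times = c(0.1, 0.15),
                    annotations = list(preprocessed = TRUE))
  expect_error(analyze_train(tr2), "at least 5")
})
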