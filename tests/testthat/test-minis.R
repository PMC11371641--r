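test_that("a single noiseless quantum is detected with exact amplitude and onset", {
  sim <- simulate_minis(sim_config(seed = 3, mini_rate = 0.2, noise_sd = 0,
                                   quantal_cv = 0), 10)
  ev <- detect_minis(sim$trace)
  expect_length(ev$event_times, length(sim$ground_truth$event_times))
  expect_equal(ev$event_amplitudes,
               sim$ground_truth$event_amplitudes, tolerance = 0.02)
  expect_true(all(abs(ev$event_times - sim$ground_truth$event_times) < 0.001))
})

test_that("detection achieves >= 95% recall and precision at SNR 10", {
  cc <- sim_config(seed = 11, mini_rate = 1, noise_sd = 2)  # q = 20 pA
  sim <- simulate_minis(cc, 50)
  ev <- detect_minis(sim$trace)
  gt <- sim$ground_truth$event_times
  expect_gte(match_fraction(ev$event_times, gt), 0.95)   # precision
  expect_gte(match_fraction(gt, ev$event_times), 0.95)   # recall
})

test_that("the false-event rate on pure noise stays below 0.2 Hz at threshold 4", {
  sim <- simulate_minis(sim_config(seed = 1, mini_rate = 0, noise_sd = 2), 100)
  expect_lt(length(detect_minis(sim$trace)$event_times) / 100, 0.2)
})

test_that("event rate recovery is unbiased across rates at SNR 10", {
  for (rate in c(0.5, 2, 8)) {
    res <- vapply(1:6, function(s) {
      sim <- simulate_minis(sim_config(seed = s, mini_rate = rate,
                                       noise_sd = 2), 60)
      c(length(detect_minis(sim$trace)$event_times),
        length(sim$ground_truth$event_times))
    }, numeric(2))
    # seed-averaged estimate against the realized ground-truth event count
    expect_lt(abs(sum(res[1, ]) / sum(res[2, ]) - 1), 0.05)
  }
})

test_that("raising the threshold never increases the detected count", {
  sim <- simulate_minis(sim_config(seed = 5, mini_rate = 2, noise_sd = 2), 30)
  counts <- vapply(c(3, 4, 5, 6, 8), function(k) {
    length(detect_minis(sim$trace,
                        analysis_config(detection_threshold_k = k))$event_times)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("overlap summation inflates amplitudes at high rates only", {
  lo <- simulate_minis(sim_config(seed = 2, mini_rate = 1, noise_sd = 1,
                                  quantal_cv = 0.1), 30)
  hi <- simulate_minis(sim_config(seed = 2, mini_rate = 50, noise_sd = 1,
                                  quantal_cv = 0.1), 30)
  amp_lo <- mean(detect_minis(lo$trace)$event_amplitudes)
  amp_hi <- mean(detect_minis(hi$trace)$event_amplitudes)
  expect_lt(abs(amp_lo / 20 - 1), 0.1)   # low rate: amplitudes unaffected
  expect_gt(amp_hi, 1.1 * 20)            # high rate: summation inflation
})

test_that("detected event spacing respects the minimum interval", {
  sim <- simulate_minis(sim_config(seed = 9, mini_rate = 20, noise_sd = 2), 20)
  ev <- detect_minis(sim$trace)
  expect_true(all(diff(ev$event_times) >= 0.003 - 1e-9))
  expect_true(all(ev$event_amplitudes > 0))
})

test_that("mini statistics follow the event set and handle the empty contract", {
  es <- structure(list(event_times = seq(0.5, 9.5, by = 1),
                       event_amplitudes = rep(20, 10),
                       duration_analyzed = 10, noise_sd_estimate = 1),
                  class = "mini_events")
  st <- mini_statistics(es)
  expect_equal(st$frequency, 1)
  expect_equal(st$mean_amplitude, 20)

  empty <- structure(list(event_times = numeric(), event_amplitudes = numeric(),
                          duration_analyzed = 10, noise_sd_estimate = 1),
                     class = "mini_events")
  st0 <- mini_statistics(empty)
  expect_equal(st0$frequency, 0)
  expect_true(is.na(st0$mean_amplitude))
})

test_that("frequency estimates concentrate on the generator rate", {
  freq <- vapply(1:10, function(s) {
    sim <- simulate_minis(sim_config(seed = s, mini_rate = 2, noise_sd = 2), 60)
    mini_statistics(detect_minis(sim$trace))$frequency
  }, numeric(1))
  expect_lt(abs(mean(freq) / 2 - 1), 0.05)
})

test_that("traces shorter than 1 s are rejected", {
  tr <- epsc_trace(rnorm(5000), 10000, polarity = "positive_up",
                   annotations = list(preprocessed = TRUE))
  expect_error(detect_minis(tr), "1 s")
})
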