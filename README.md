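# epsctools

Analysis of whole-cell voltage-clamp recordings of excitatory postsynaptic
currents (EPSCs), built for studying how synaptic mutations shift the
balance between synchronous, asynchronous and spontaneous neurotransmitter
release — the phenotype produced, for example, by synaptotagmin-1 variants
that impair release clamping. It is aimed at cellular
electrophysiologists who need the standard quantification chain as tested,
scriptable functions rather than one-off analysis scripts.

## What it computes

* **Evoked EPSCs** — amplitude, charge, time-to-peak; bi-exponential decay
  fits $I(t) = A_f e^{-t/\tau_f} + A_s e^{-t/\tau_s}$ (Levenberg–Marquardt,
  $\tau_f < \tau_s$ by construction); decomposition of the EPSC into
  synchronous charge $Q_{rise} + A_f\tau_f$ and asynchronous charge
  $A_s\tau_s$, and the asynchronous fraction
  $A_s\tau_s / (Q_{rise} + A_f\tau_f + A_s\tau_s)$.
* **Short-term plasticity** — paired-pulse ratio with decay-extrapolated
  subtraction of the first response; 20 Hz train rundown, the
  synchronous/asynchronous division of train charge via the pre-pulse
  envelope, and the post-train tail time constant.
* **Readily releasable pool (RRP)** — back-extrapolation of cumulative
  train charge (pool charge = Y-intercept, recruitment rate = slope of the
  steady-state line) and the hypertonic-sucrose transient integral.
* **Spontaneous minis** — threshold detection of miniature EPSCs with
  robust noise estimation, and frequency/amplitude statistics.
* **Group statistics** — the conventional select-then-test procedure
  (Shapiro–Wilk, then Student's/Welch's t or Mann–Whitney U, two-tailed;
  mean ± SD or median ± unscaled MAD summaries).
* **A ground-truthed simulator** — quantal difference-of-exponentials
  kernels, Poisson minis, latency-structured evoked release, binomial pool
  depletion with recruitment, sucrose discharge, and Gaussian noise, with
  an exact event-level ground truth and `"WT"`/`"PL"` genotype presets, so
  every estimator above is validated by parameter recovery
  (`run_recovery()` runs the whole pipeline on simulated cohorts).

Traces are exchanged as HDF5 (`/samples`, `/stimulus_times`, metadata
attributes) or two-column CSV with a JSON sidecar; see `?read_trace`.

## Worked example

Simulate one clamping-deficient ("PL") cell and quantify it:

```r
library(epsctools)
cfg <- make_preset("PL", seed = 42)

sim <- simulate_evoked_epsc(cfg)
analyze_epsc(sim$trace)
#> EPSC: amplitude 2479 pA, charge 19.9 pC, time-to-peak 2.5 ms
#> Bi-exponential EPSC decay fit
#>   fast: A = 2554 pA, tau = 5.442 ms
#>   slow: A = 30.45 pA, tau = 101.5 ms (relative amplitude 0.012)
#>   RMSE 8.44 pA over 5001 samples
#>   synchronous 16.87 pC + asynchronous 3.089 pC -> asynchronous fraction 0.1548
sim$ground_truth$true_async_fraction
#> [1] 0.1784

minis <- simulate_minis(cfg, duration = 30)
mini_statistics(detect_minis(minis$trace))
#> mEPSCs: 12.3 Hz (369 events / 30 s), amplitude mean 25.06, median 23.74 pA

cfg$stimulus_times <- train_stimulus_times(40, 100)
tr40 <- simulate_train(cfg)
backextrapolate_rrp(analyze_train(tr40$trace))
#> RRP estimate (back_extrapolation): 94.16 pC, recruitment 54.42 pC/s
#>   linear fit R^2 = 0.9971
tr40$ground_truth$true_rrp_charge
#> [1] 103.324
```

Reading the numbers: the evoked EPSC decays with a fast ~5 ms synchronous
component and a slow ~100 ms asynchronous component; the decomposition
attributes 15% of the released charge to asynchronous release against a
generator truth of 18% for this cell. The detected mini rate (12.3 Hz)
recovers the preset's 12 Hz spontaneous rate — the mean amplitude exceeds
the 20 pA quantum because independent events summate at such high rates.
The back-extrapolated pool charge (94 pC) recovers the true 103 pC pool
within the known ~5–10% intercept bias of the method. Comparing against
`make_preset("WT")` cohorts with `run_recovery()` reproduces the
clamping-deficiency pattern: several-fold higher mini rate and asynchronous
fraction with unchanged synchronous kinetics, release probability and RRP.

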