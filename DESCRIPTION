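Package: epsctools
Title: Synaptic Current Decomposition, Pool Estimation and Quantal Release Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of whole-cell voltage-clamp recordings of excitatory
    postsynaptic currents (EPSCs): bi-exponential decay fitting and
    decomposition of evoked release into synchronous and asynchronous charge,
    paired-pulse and stimulus-train analysis with tail-current kinetics,
    readily-releasable-pool (RRP) estimation by cumulative-charge
    back-extrapolation and by hypertonic-sucrose discharge, and detection and
    quantification of spontaneous miniature EPSCs. Includes a ground-truthed
    quantal release simulator (difference-of-exponentials quantal waveform,
    Poisson spontaneous release, Gaussian synchronous and exponential
    asynchronous evoked latencies, binomial vesicle-pool depletion with
    recruitment) so that every analysis stage can be validated by parameter
    recovery, plus the two-sample test-selection procedure
    (Student/Welch/Mann-Whitney) used to compare recording groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    pracma,
    jsonlite,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
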