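---
title: "Decomposing synaptic currents: models, estimators and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing synaptic currents: models, estimators and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epsctools)
```

## The problem

Synaptotagmin-1 both triggers action-potential-locked (synchronous)
neurotransmitter release and clamps release between action potentials.
Mutations that impair the clamp leave the evoked EPSC amplitude and kinetics
largely intact but elevate spontaneous miniature release and the delayed,
asynchronous component of evoked release. Quantifying that phenotype from
whole-cell voltage-clamp recordings requires a chain of estimators — EPSC
decay decomposition, train analysis, readily-releasable-pool (RRP)
estimation, miniature-event detection, and two-sample statistics — none of
which can be validated on experimental data, because the ground truth (which
vesicle fused when) is unobservable. `epsctools` therefore pairs every
estimator with a generative model of the recordings whose event-level ground
truth is known exactly, and treats parameter recovery on simulated data as
the package's test of correctness.

## The generative model

All simulated traces are superpositions of a quantal kernel

$$k(t) = c\,(e^{-t/\tau_d} - e^{-t/\tau_r}),$$

the current elicited by a single vesicle, with $c$ chosen so the waveform
peaks at the quantal amplitude $q$. Defaults: $\tau_r = 0.5$ ms,
$\tau_d = 5$ ms, $q = 20$ pA with lognormal between-event variability
(CV 0.25), sampling at 10 kHz, additive Gaussian recording noise (SD 3 pA),
inward-negative polarity as recorded. The kernel's peak time
$t^* = \frac{\tau_r\tau_d}{\tau_d-\tau_r}\log\frac{\tau_d}{\tau_r}$ and
charge $c(\tau_d-\tau_r)$ are analytic, so every downstream amplitude and
charge measurement has a closed-form oracle.

Release processes:

* **Spontaneous minis** — homogeneous Poisson process at `mini_rate`.
* **Evoked EPSC** — `n_sync` quanta at Gaussian latencies (mean 1 ms,
  SD 0.3 ms, truncated at 0; truncation keeps latencies physical) plus
  Poisson(`async_count_mean`) quanta at exponential latencies with mean
  `tau_async`. The tight Gaussian component models fusion driven by the
  local calcium peak; the exponential tail models fusion driven by residual
  calcium.
* **Trains** — a vesicle pool of size $P_1 = N$ releases
  $\mathrm{Binomial}(P_k, p)$ synchronous quanta per pulse and recovers at a
  constant recruitment rate $\rho$ (vesicles/s, capped at $N$). Asynchronous
  quanta triggered by pulse $k$ are Poisson with mean scaled by that pulse's
  synchronous release (so the asynchronous tail tracks recent release), and
  deplete the *same* pool — at their actual fusion times, not at the
  triggering pulse. A single pool feeding both release modes is the simplest
  structure consistent with the observation that a clamping-deficient
  synapse can double its asynchronous output while total train charge and
  RRP stay unchanged.
* **Hypertonic sucrose** — each pooled vesicle releases independently with
  hazard $1/\tau_{suc}$ during the application (default $\tau_{suc}=500$ ms),
  i.e. an inhomogeneous Poisson discharge proportional to the remaining
  pool, on top of steady-state spontaneous release.

An **expected-value mode** (`deterministic = TRUE`) propagates means instead
of sampling: synchronous release per pulse is rendered as one event of
amplitude $P_k\,p\,q$ at the mean latency, and asynchronous release as 40
fractional-amplitude events at stratified quantiles of the exponential
latency law (total charge exact). This mode exists to make closed-form test
oracles — geometric pool depletion $P_1 p (1-p)^{k-1}$, exact
back-extrapolation intercepts — hold to machine precision.

Evoked, train and sucrose simulations do not superimpose spontaneous release
(`mini_rate` enters the minis and sucrose protocols only); this keeps the
per-class ground-truth charges unambiguous for recovery testing.

### Genotype presets

`make_preset()` encodes the two study conditions. Relative to `"WT"`
(`mini_rate` 2 Hz, 148 synchronous + 12 asynchronous quanta per evoked
EPSC, `tau_async` 50 ms), the clamping-deficient `"PL"` preset has a 6-fold
per-synapse spontaneous rate (12 Hz), an asynchronous share of evoked
release raised from 0.075 to 0.20 at *equal total quanta*
(128 + 32 = 148 + 12), and a 2-fold slower asynchronous decay (100 ms),
with identical kernel kinetics, synchronous latency, release probability,
pool size (800 vesicles) and recruitment rate (400 vesicles/s). One
modelling tension is worth noting: in this generator the single-EPSC slow
decay constant and the post-train tail decay are both governed by
`tau_async`, so giving PL a slower tail (as observed) necessarily also
slows its single-EPSC slow component; the presets prioritise the tail
effect. The fast (synchronous) kinetics are identical by construction.

## The estimators

**Preprocessing.** All measurements operate on baseline-subtracted,
polarity-rectified (positive-up) traces. The baseline is the mean over 50 ms
before the first stimulus; 0.5 ms after each stimulus onset is replaced by
linear interpolation (artifact blanking). Times are seconds, currents pA,
charges pC.

**Single EPSC.** Amplitude is the window maximum, time-to-peak is measured
from stimulus onset (not from detectable response onset — the onset
convention follows the amplitude measurement), charge is the trapezoidal
integral to the next stimulus or to `fit_window` (500 ms). The decay from
the peak is fit with $A_f e^{-t/\tau_f} + A_s e^{-t/\tau_s}$ by
Levenberg–Marquardt in a log-$\tau$ parameterisation with the ordering
$\tau_s = \tau_f + e^{\delta}$ enforced by construction and amplitudes
bounded at 0. Initialisation: $\tau_f$ from the 80→20% decay time (exact
for a mono-exponential), $\tau_s = 10\tau_f$, amplitudes from a two-point
linear solve. Fits whose components collapse ($\tau_s/\tau_f < 1.5$, or a
slow contribution below 1% of the fitted charge) are refit and reported as
mono-exponential with $A_s = 0$ rather than failing — clean synchronous
EPSCs must still yield a fit. Non-convergence sets `converged = FALSE` with
diagnostics instead of raising.

**Synchronous/asynchronous decomposition.** Synchronous charge is the rise
integral (stimulus to peak) plus the analytic fast-component integral
$A_f\tau_f$; asynchronous charge is $A_s\tau_s$. Analytic integrals to
infinity make the decomposition independent of the fit-window length.
The asynchronous fraction is async/(sync + async).

**Paired pulses.** The second amplitude is measured after subtracting the
extrapolated bi-exponential decay of the first response, so PPR is not
inflated by residual current.

**Trains.** The asynchronous level under the phasic EPSCs is estimated by
the pre-pulse envelope: the mean current over 2 ms before each stimulus
(where the fast component, with $\tau_d = 5$ ms and 50 ms between pulses,
has decayed by $e^{-9}$), linearly interpolated and integrated over the
train window. Synchronous charge is the remainder of the total; phasic
amplitudes are measured above the envelope and normalised to pulse 1. The
envelope method under-reports asynchronous charge whose decay is fast
relative to the inter-stimulus interval (the sampled pre-pulse level is the
exponential's minimum, and current flowing after the train window is
credited to the tail, which is reported separately). With
$\tau_{async}/\Delta t \gtrsim 6$ the combined bias stays below 0.02 in
fraction terms; the train asynchronous fraction excludes the tail by
definition here. The tail itself is fit mono-exponentially from one
inter-stimulus interval after the last pulse until the smoothed current
returns to within 2 noise SD of baseline.

**RRP.** Back-extrapolation: cumulative per-pulse charge against pulse time,
ordinary least squares over the final 25% of pulses (steady state), pool
charge = intercept, recruitment rate = slope, with $R^2$ as the diagnostic
and a flag when the slope is negative. On the constant-recruitment depletion
model this intercept underestimates the true pool by roughly
$P_{ss}(1-p)$ quanta; at the preset's recruitment (10 vesicles per 40 Hz
interval, $P_{ss} = 50$) the bias is ~5%. Sucrose: transient integral above
the steady-state level (mean of the final 20% of the application); the
*integral* is clipped at 0 — samplewise clipping would rectify noise into a
positive charge bias that grows with the spontaneous rate. The steady-state
current (pA = pC/s) is reported as the recruitment estimate.

**Mini detection.** Running-median baseline (200 ms), noise SD from a
one-sided (left-tail) MAD of the high-pass residual — release only adds
positive mass, so the left tail stays clean at high event rates. Detection
uses two boxcar scales: fine (1 ms) maxima resolve closely spaced events;
a coincident threshold on the coarse (3 ms) statistic, which integrates
over the event width, suppresses noise triggers. Candidates must exceed
`threshold_k` = 4 noise SD on both scales and rise by at least the
threshold above their preceding 2 ms minimum (rejecting noise maxima riding
on an earlier event's decay). Peaks are refined on the raw residual and
merged below `min_event_interval` = 3 ms keeping the larger — deliberately,
so that genuine overlap at high rates produces summed single events and the
amplitude-inflation phenomenon is observable rather than corrected away.
Event times are onsets (walk-back from the peak to the noise floor, never
past the preceding peak). A threshold-based detector was preferred over
template matching for determinism and parameter transparency.

**Statistics.** `compare_groups()` reproduces the conventional
select-then-test procedure: Shapiro–Wilk normality per group at $\alpha$,
F-test variance screen choosing Student vs Welch when both groups pass,
Mann–Whitney U otherwise; all two-tailed. Summaries are mean ± SD on the
parametric branch and median ± MAD (unscaled — no 1.4826 factor) otherwise.
The normality and variance screens use the same $\alpha$ as the final test;
both choices are declared rather than estimated, since the procedure must
be a pure function of the two samples. Constant samples bypass the
normality screen to Mann–Whitney with a warning. No multiplicity correction
is applied; the recovery report prints the number of comparisons instead.
No outlier exclusion is applied at any stage.

## Cohort recovery

`run_recovery()` simulates whole cohorts (default 30 cells per genotype; a
40 s mini recording, one evoked EPSC, a 50 ms paired pulse, a 50-pulse
20 Hz train, a 100-pulse 40 Hz train and a 2.5 s sucrose application per
cell), runs every estimator, and compares genotypes metric by metric. Cells
within a cohort draw lognormal factors on $\tau_d$ (CV 8%) and $q$ (CV 10%)
from the same law for both genotypes: real cohorts vary between cells, and
without that variability group tests resolve sub-percent estimator biases
that no experiment could see. The 40 Hz train length (100 pulses) is long
enough to reach the depletion/recruitment steady state that
back-extrapolation requires; the 20 Hz train uses 50 pulses. These problem
sizes, like the 20-seed Monte-Carlo fits and the 2000-replicate null
calibration of the test-selection procedure, are the package's declared
test conditions.

```{r cohort, eval = FALSE}
rep <- run_recovery(n_cells = 30, seed = 1)
print(rep)
```

The expected pattern, and what the acceptance suite asserts: PL/WT mini
frequency fold ≥ 4 (the detector recovers ~6 at the preset's per-synapse
encoding), asynchronous fraction fold ≥ 2, and no significant difference in
$\tau_f$, PPR, or either RRP estimate.

## What passing tests do and do not show

The generator emulates quantal superposition, Poisson spontaneous release,
latency-structured evoked release, pool depletion with recruitment, sucrose
discharge, and stationary Gaussian noise. It does not emulate series-
resistance and space-clamp errors, receptor saturation or desensitisation,
electrode drift, line noise, or facilitation; spatial calcium microdomains
are deliberately out of scope (the presets encode their consequences, not
their mechanism). Parameter recovery here therefore demonstrates that the
estimators are correct under the stated model, not that the model captures
every property of experimental recordings. Deconvolution-based release-rate
estimation and template-matching event detection are out of scope, as are
vendor acquisition formats (traces are exchanged as HDF5 or CSV with a JSON
metadata sidecar).

## Numerical notes and degenerate inputs

Zero-length traces are rejected at construction; mini detection requires
≥ 1 s; decay fits require ≥ 10 samples; back-extrapolation requires ≥ 20
pulses. An EPSC with no events reports an undefined (NA) asynchronous
fraction, as does a zero-amplitude first pulse for PPR and an empty event
set for mini amplitudes. Envelope integrals exceeding the total train
charge are clipped with a flag. Seeds fully determine every simulation
(identical configs are bitwise-reproducible); derived per-cell seeds stay
below $2^{31}$.
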