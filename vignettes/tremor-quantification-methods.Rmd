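---
title: "Methods: simulating and quantifying action tremor from finger-force series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying action tremor from finger-force series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorforce)
```

This vignette is the package's account of its models and the design choices
behind them. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The measurement and its signal model

The instrument records the force a fingertip applies to a strain gauge at
40 Hz, in gram-force, while the subject ramps up to a 300 gf target and
holds it for 3 s (5 s in the repeatability protocol). Action tremor —
present during voluntary contraction — appears as an approximately
sinusoidal oscillation superimposed on the voluntary force. Parkinsonian
tremor has a roughly fixed frequency, usually above 5 Hz, with an amplitude
that fluctuates on a time scale of seconds; physiological tremor of healthy
subjects sits mostly above 7 Hz and is small.

`simulate_trace()` generates exactly this decomposition:

* **voluntary force**: a cubic smoothstep ramp over `ramp_s` (default 1 s)
  reaching the target exactly, then a flat plateau. The smoothstep is a
  modelling choice — the protocol only requires that subjects reach the
  target; any smooth monotone ramp would do, and the plateau being exact
  makes the noise-free case analytically checkable.
* **tremor**: `A(t) sin(2π f t + φ)` with
  `A(t) = A₀ (1 + m sin(2π f_m t + ψ))`; the slow sinusoidal modulation
  (`m = amp_mod_depth`, default 0.1; `f_m = 0.5 Hz`) emulates the
  amplitude variability of Parkinsonian tremor while leaving the frequency
  fixed. Phases are drawn from the per-trace seed.
* **noise and drift**: white Gaussian noise (default SD 2 gf, a plausible
  figure for a 24-bit load-cell channel) and linear drift (default
  0.5 gf/s) standing in for slow voluntary corrections and thermal drift.
* **contact loss** (off by default): with per-second probability
  `tap_dropout_prob`, a 0.1–0.3 s interval is clamped to 0 gf, emulating a
  finger that taps the gauge instead of pressing it — the artifact that
  invalidated one patient's right-hand measurements in practice.

The default noise, drift and modulation levels are deliberately small
enough that, even at the largest default tremor amplitude, the total
excursion stays inside the protocol's ±20 % tolerance band. This is not a
simplification so much as a consequence of the protocol itself: a live
measurement that leaves the band has no qualifying hold and is repeated,
so the data that reach analysis are exactly the in-band ones.

### Cohort design

`default_cohort_design()` ships 36 healthy subjects (one session each) and
7 subjects with Parkinson's disease carrying clinician tremor ratings
(Fahn–Tolosa–Marin scale, 0–4) of 1, 2, 3, 3, 3, 3 and 4, with 13 PD
sessions in total — 49 sessions × 10 fingers = 490 measurements. The
published per-patient session counts sum to 14, which is inconsistent with
the stated totals of 49 sessions and 490 measurements; the shipped design
resolves the conflict in favour of the totals (the most-measured patient
keeps 7 sessions; one other patient is reduced from 2 sessions to 1) and
the design is configuration, not code, so any other reading is one
`cohort_design()` call away.

Tremor ratings map to amplitudes 0, 5, 10, 20, 40 gf. No published mapping
exists; this doubling progression is a modelling default chosen so that
amplitude is monotone in the rating and the severest rating still fits the
tolerance band. Healthy subjects receive a 1.5 gf, 10 Hz physiological
tremor, placed above the 7.5 Hz band edge precisely so that the analysis
band-pass removes it. Each subject's tremor frequency is jittered
uniformly by ±0.5 Hz around the nominal value so the cohort is not a
single pure tone.

### The validation rig

`simulate_rig()` models the hardware-validation device: a DC motor rotates
a pulley with an eccentrically mounted elastic band pressing on a gauge,
while an optical encoder logs pulses at equal phase increments. The gauge
reads `F(t) = F₀ + F₁ sin θ(t)` with
`dθ/dt = 2π·rev_per_s·(1 + β sin θ)`. The β term models the elastic band
braking the motor while stretching and releasing it while contracting;
β > 0 distorts the force away from a pure sinusoid and injects harmonics
(the suspected cause of the low-frequency disagreement seen with the real
rig). With β = 0 the phase is linear and computed in closed form; otherwise
the phase ODE is integrated by fixed-step RK4 at 1 kHz and inverted by
interpolation for the pulse times.

## Preprocessing

1. **Outlier repair.** Samples strictly below the 1.25th percentile of the
   measurement's *own* sample distribution are replaced by linear
   interpolation between the nearest non-outlier neighbours (ends take the
   nearest non-outlier value). The percentile is the linearly interpolated
   empirical quantile (R type 7); "strictly below" guarantees that at most
   ⌈0.0125 N⌉ samples can change and that a constant trace is untouched.
   The repair is idempotent on dropout-type artifacts; on continuous noise
   distributions a second pass can nominate new points, which is inherent
   to any self-referential percentile rule.
2. **Band-pass.** A 4th-order Butterworth band-pass (3.5–7.5 Hz) applied
   forward and backward (`signal::filtfilt`) for zero phase, so the tremor
   waveform is not shifted relative to the hold window. The contract is
   stated in attenuation terms — ≥ 0.9 amplitude ratio at band centre,
   ≤ 0.1 at ≤ 1.5 Hz and ≥ 10 Hz — so any compliant realization passes the
   tests; the measured response of this design is well inside it.
3. **Hold-window extraction.** The first contiguous run of `hold_s`
   seconds within ±20 % of the target on the *raw* (outlier-repaired)
   trace, truncated to exactly `round(hold_s × rate)` samples. The
   tolerance half-width is a configurable default: the live protocol
   displays a target region but its published width is not stated. Window
   indices are found on the raw stream and the samples cut from the
   filtered stream: filtering first would remove the voluntary plateau the
   window is defined by. Whether the original pipeline windows before or
   after filtering is not documented; this order is recorded here as the
   package's choice, not an inference.

## Spectral statistics

The periodogram is a single-segment, mean-subtracted, rectangular-windowed
DFT — no Welch averaging or tapering, because the analysis unit is one
short hold and the statistic of interest is concentration, not variance
reduction. One-sided scaling doubles interior bins so that the bins sum to
the demeaned signal's mean square (Parseval; asserted at 1e-9 relative in
the tests). The amplitude spectrum uses `2|X_k|/N`, which returns a
bin-centred sinusoid's amplitude exactly.

The dominant frequency is the in-band PSD argmax with ties broken toward
the lower frequency (a deterministic rule; ties occur only in constructed
fixtures). Peak power integrates the piecewise-linear PSD curve over
`f_d ± 0.3 Hz` by trapezoidal quadrature with interpolated edge values —
the definition is a continuous integral, and at the 3 s window's 1/3 Hz
bin spacing the ±0.3 Hz edges always fall between bins. The peak power
proportion divides by the trapezoidal integral of the *full* one-sided
PSD, with the same quadrature in numerator and denominator so the ratio
cannot exceed 1 by construction. Because the window has already been
band-passed, out-of-band power is negligible and the denominator is, in
effect, the in-band area; how the original statistic treats out-of-band
power in unfiltered signals is not documented.

Two numerical facts shape the tests. First, a bin-centred tone in a 3 s
window yields a proportion of exactly 0.99 under this quadrature (the
triangle that the trapezoid draws around a single-bin peak loses 1 % of
the bin's area); a 5 s window yields exactly 1. Second, rectangular-window
leakage means an off-bin tone spreads real power into neighbouring bins,
so energy-concentration invariants are asserted at bin-aligned frequencies
— the recovery property (±0.35 Hz in ≥ 95/100 noisy windows at 4.0, 5.5
and 7.0 Hz) covers the off-bin case.

## Features and classifiers

Each window's amplitude spectrum is linearly interpolated onto the fixed
grid 3.5, 3.6, …, 7.5 Hz — 41 values at 0.1 Hz spacing. (The source
pipeline description says "resamples at 0.01 Hz" yet states 41 values
twice; 41 values over a 4 Hz band implies 0.1 Hz, and the 41-value reading
is adopted because the feature count is load-bearing downstream.)

The four reference classifiers keep their published hyperparameters:

* **SVM**, Gaussian (RBF) kernel with γ = 6.4, features standardized.
  Under the `exp(−γ‖u−v‖²)` convention used here (and by `e1071`), γ = 6.4
  on 41 standardized features gives an extremely narrow kernel; a toolbox
  that reads the same number as a *kernel scale* σ (with γ = 1/σ²) would
  get a much wider one. The printed value is kept literally; no package
  result depends on the SVM's accuracy.
* **Naive Bayes**, "nonparametric Gaussian": per-feature, per-class
  Gaussian kernel density estimates with Silverman's rule-of-thumb
  bandwidth — the standard reading of a nonparametric NB with Gaussian
  kernels. Densities are floored at 1e-300 before taking logs.
* **Decision tree**, Gini diversity index, node count bounded at 100. The
  tree grower used here caps depth rather than node count, so the bound is
  realized as depth ≤ 6 (≤ 127 nodes for a complete tree; far fewer in
  practice).
* **KNN**, k = 13 under cosine distance, features standardized. Written
  directly (row-normalized dot products) because the standard KNN
  implementations are Euclidean-only; vote ties resolve by summed
  similarity, then toward the healthy class.

Cross-validation is stratified five-fold with a seeded assignment that
deals shuffled rows to folds cyclically, continuing the cycle across
classes so per-class and overall fold sizes differ by at most one.
Validation accuracy is the mean of per-fold accuracies; sensitivity,
specificity, precision and F1 come from confusion counts pooled over
validation folds with the disease class as target (whether the original
benchmark pooled or averaged these is unstated; pooling is the
deterministic choice). Measurement-level splitting is the default, matching
the 490-measurement framing, but it leaks subject identity across folds —
repeated sessions of one subject can appear on both sides — so
`group_by = "subject"` assigns whole subjects to folds for a
leakage-free estimate.

## Study harnesses

**Rig validation.** For each trial the rig is simulated afresh, the
rotation rate estimated from the encoder pulse count and, independently,
from the gauge PSD argmax over the full 0–20 Hz band; the arms are
compared with the unpooled two-sample z statistic
`z = (μ_r − μ_oe)/√(s_oe²/n + s_r²/n)` at α = 0.05, using sample (n−1)
standard deviations. The published analysis states only that a z-test was
computed, and its printed z values are not reproducible from its printed
columns under any standard formula we tried, so the conventional unpooled
form is used. Each trial draws its motor speed with a 1 % standard
deviation around the nominal rate — DC motors under load hold their speed
only approximately — which is also what gives the two arms sampling
variance; with a perfectly constant speed both estimators are
deterministic and the test degenerate. Trials default to 3 s (the
published account gives both 3 s and 10 s; 3 s matches the hold-window
analysis and is configurable).

**Repeatability.** Given repeated assessments of one subject (the shipped
emulation: 7 protocol repetitions per hand at a 5 s hold, 28 non-thumb
measurements per hand), the sweep counts valid measurements at thresholds
0.5–0.9 per hand and reports the mean and sample SD of the dominant
frequency over valid measurements only. Cells with fewer than 2 valid
measurements report no frequency statistics — a spread estimate from a
two-point sample was already judged too small in the original analysis.
Valid counts are monotone non-increasing in the threshold by construction.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use the full 490-measurement
default cohort for counting and classification; 100-seed Monte-Carlo loops
for the noise, recovery and rig properties (40 trials per arm per
replicate, the published per-frequency trial count); and 28-window
repeatability sets. These sizes keep every stochastic property at the
sample sizes its acceptance bound is stated for while the whole suite runs
in a few minutes on one core.

## Limitations

The generator emulates the phenomenology the analysis chain is sensitive
to — a quasi-sinusoidal tremor with slow amplitude modulation riding on a
protocol-shaped voluntary force — not the physiology behind it. It does
not model multi-component tremor (multiple simultaneous dominant
frequencies), tremor frequency wander within a hold, subject fatigue
across sessions, sensor quantization, or correlated noise between fingers.
Classifier accuracies on this synthetic cohort therefore demonstrate that
the pipeline preserves and extracts the class-separating spectral
information, not that comparable accuracy would be achieved on clinical
recordings; the published clinical metrics come from human data that is
not deposited and are not reproduction targets here.
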