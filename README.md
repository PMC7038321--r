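# tremorforce

Quantification of action tremor from fingertip force recordings.

Parkinsonian action tremor is an approximately sinusoidal, roughly
fixed-frequency oscillation (typically above 5 Hz) whose amplitude varies
with activity and stress. One way to measure it without wearable sensors is
a strain-gauge keyboard: the subject presses each finger in turn to a
300 gram-force target shown on screen and holds it for 3–5 s, and the
tremor rides on top of the voluntary force during the hold. `tremorforce`
implements the complete analysis chain for such recordings — and seeded
generators that emulate the instrument, so the chain is fully testable
without hardware — for researchers working on tremor quantification and
instrument validation.

## The statistic at the core

Each hold window is analysed by a single-segment periodogram of the
mean-subtracted, rectangular-windowed signal $x_1,\dots,x_N$ sampled at
40 Hz,

$$P(f_k) \propto \frac{\mathrm{FT}^*(x)\,\mathrm{FT}(x)}{N^2},$$

one-sided and scaled so the bins sum to the signal's mean square. The
dominant frequency $f_d$ is the in-band (3.5–7.5 Hz) argmax of the PSD, the
peak power is the area under the PSD curve around it,

$$P_{\mathrm{peak}} = \int_{f_d-0.3}^{f_d+0.3} P(f)\,df,$$

and the **peak power proportion**

$$V_f = \frac{P_{\mathrm{peak}}}{\sum_i P_i}$$

is the fraction of total spectral power concentrated at the dominant
frequency — a scale-free statistic near 1 for a strong sinusoidal tremor
and small for broadband noise. A measurement is *valid* when $V_f$ exceeds
a set threshold (0.5–0.9), and only valid measurements enter frequency
statistics. Upstream, raw traces are repaired (samples below the 1.25th
percentile of the measurement's own distribution are replaced by linear
interpolation), band-pass filtered to 3.5–7.5 Hz with a zero-phase
Butterworth design, and windowed where the subject held the target force.
Downstream, 41-point resampled amplitude spectra (3.5–7.5 Hz at 0.1 Hz)
feed four reference classifiers (RBF SVM, kernel-density naive Bayes, Gini
decision tree, cosine KNN) under stratified five-fold cross-validation.

## Worked example

```r
library(tremorforce)

# one simulated measurement: 5.8 Hz tremor, 25 gf amplitude
tr <- simulate_trace(sim_params(tremor_freq_hz = 5.8, tremor_amp_gf = 25, seed = 42))
tr |> preprocess() |> assess(threshold = 0.5)
#>   finger   f_d p_peak    v_f valid
#> 1  index 5.667  68.44 0.6888  TRUE
```

The detected dominant frequency (5.667 Hz) is the PSD bin nearest the true
5.8 Hz (3 s window ⇒ 1/3 Hz bins); 69% of the window's power is
concentrated within ±0.3 Hz of it, so the measurement is valid at the 0.5
threshold.

```r
# the shipped 49-session cohort: 36 healthy + 7 PD subjects, 490 measurements
prm    <- default_cohort_params()
cohort <- simulate_cohort(default_cohort_design(), prm$healthy, prm$pd, seed = 1)
res    <- run_pipeline(run_config(), cohort)
nrow(res$assessments)
#> [1] 392            # 490 minus 98 thumb measurements

crossvalidate(res$features, classifier_spec("decision_tree"), k = 5, seed = 1)
#> <metrics_report> decision_tree, 5-fold CV on 392 measurements
#>   val_accuracy 0.9974 | sensitivity 1.0000 | specificity 0.9965 | precision 0.9905 | F1 0.9952
```

On the synthetic cohort the tremor classes are well separated, so the
decision tree is near-perfect; `tidy()` and `glance()` return the metrics
as tibbles, and `autoplot()` methods exist for traces, spectra and
repeatability sweeps. A thin CLI over the same functions is installed at
`inst/cli/tremorforce` (subcommands `simulate`, `run`, `assess`,
`train-eval`, `repeatability`, `rig-validate`).

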