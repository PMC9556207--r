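# bcimusic

An R implementation of a closed-loop brain–computer-interface (BCI)
music-therapy pipeline for mild depression. The loop decodes a subject's
emotional state from frontal EEG and plays it back as music so the subject
can self-regulate: EEG is denoised, classified into 0.5-second
emotion-state markers (*active* / *passive* / *normal*), aggregated into
6-second music-feedback decisions (*positive* / *medium* / *negative*
stimuli), and the intervention is evaluated longitudinally with the
SCL-90, SDS and PHQ-9 depression scales.

No recordings or questionnaire data accompany studies of this design, so
the package is built around seeded synthetic generators with exact ground
truth; every algorithm is exercised end to end from code alone.

## What is inside

* **Synthetic data** — `gen_clean_eeg()` (band-structured frontal EEG whose
  theta/alpha/beta amplitudes follow a hidden per-window emotion state),
  `contaminate()` (Poisson-timed ocular blinks, mains interference, sensor
  noise, with the additive ground truth retained), and
  `gen_scale_cohort()` (longitudinal scale scores for the feedback,
  depression-control and normal-control groups).
* **Denoising** — `sift_imfs()` (empirical mode decomposition by classic
  sifting), `fast_ica()` (symmetric fixed-point FastICA, tanh contrast),
  and `denoise()` with three paths: EMD, FastICA, and the chained
  EMD+FastICA combination. Quality metrics: `snir()` (signal-to-noise
  improvement, dB), `mean_energy()`, `mape()`.
* **Classifiers** — a from-scratch convolutional network for window
  tensors (`train_cnn()`: conv/pool/FC/softmax layers, cross-entropy,
  plain gradient descent, dropout and L1, finite-difference-verified
  backpropagation) and a logistic gradient-boosting classifier
  (`train_gb()`: link `p = e^F/(e^F + e^-F)`, pseudo-residuals `2(y-p)`,
  time-indexed OLS weak learners, line-searched weights, shrinkage).
* **Feedback layer** — `classify_windows()` (dual-threshold ternary
  decision), `segment_decision()` (12-window majority per 6-s block),
  `render_music()` (symbolic motif tables per valence),
  `fragment_trend()`, `marker_count()`, and `schedule_protocol()` (the
  42-minute session plan under a strict 45-minute cap).
* **Scales & statistics** — `classify_severity()`, `assign_group()`,
  `t_test_from_stats()` (pooled/Welch from summary statistics),
  `longitudinal_report()`.
* **IO & pipeline** — EDF and CSV readers/writers (`read_eeg()`,
  `write_eeg()`), JSON model serialization, and `run_pipeline()` wiring
  acquire → denoise → classify → music → report. A thin command-line front
  end lives in `inst/cli/bcimusic.R`.

## Worked example

Generate the standard contaminated benchmark session, compare the three
denoising paths, and inspect the feedback arithmetic:

```r
library(bcimusic)

ses <- standard_contamination_session(seed = 1)
ses
#> <session_truth> 3 channel(s), 30.0 s, 14 blink(s), seed 863928

compare_denoisers(ses, seed = 1)
#>        method snir_db mean_energy mape_pct
#> 1         EMD   0.000       631.4    821.4
#> 2     FastICA   7.344       126.2    511.4
#> 3 EMD_FastICA   7.775       115.4    462.8
```

The combined EMD+FastICA path attains the highest signal-to-noise
improvement (+7.8 dB over the contaminated input) and the lowest mean
absolute percentage error against the clean ground truth; the EMD-only
correlation screen removes essentially nothing on this contamination mix
(0 dB), reproducing the known ordering of the three methods. MAPE values
are large in absolute terms because EEG crosses zero constantly; they are
meaningful comparatively.

```r
marker_count(399)        # 6-s segments -> 0.5-s markers
#> [1] 4788

t_test_from_stats(31.40, 5.10, 4, 2.74, 3.19, 4)   # depressed vs normal baseline
#> <t_test_result> t = 9.5287, df = 6.00, p = 7.622e-05 (pooled)

schedule_protocol()
#> <protocol_schedule> 5 stage(s), 42 min total (cap 45)
```

The full classification loop is exercised by `window_benchmark()`, which
trains the network on eight synthetic sessions, stacks the boosting model
on its penultimate features, and measures 0.5-s window agreement against
the ground-truth states of a held-in session (typically 0.94–1.00).

## Documentation

The methods vignette (`vignettes/music-feedback-pipeline.Rmd`) documents
the generator design, the denoising composition and its component
rejection rules, both classifiers' equations and the choices made where
the design was open, the severity-banding decisions, and what the
synthetic benchmarks do and do not demonstrate about real recordings.
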