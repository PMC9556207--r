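---
title: "An EEG music-feedback pipeline for depression neurofeedback: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An EEG music-feedback pipeline for depression neurofeedback: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`bcimusic` implements a closed-loop brain-computer-interface music-therapy
pipeline for mild depression: frontal EEG is denoised, classified into
0.5-second emotion-state markers, aggregated into 6-second music-feedback
decisions, and the intervention is evaluated with standard depression
rating scales. Because no recordings or questionnaire data are distributed
with studies of this design, the package is built around a synthetic-data
module that generates every input with known ground truth; all tests and
the acceptance script run from those generators alone.

This vignette documents the models, the tunable parameters, the design
choices made where the design was genuinely open, and what the synthetic
benchmarks do and do not demonstrate.

## The synthetic EEG generator

`gen_clean_eeg()` produces a 3-channel frontal montage (FP1, FP2, FPZ — the
electrode placement used in portable depression-feedback setups) sampled at
`fs` >= 100 Hz. Each channel is a sum of three band-limited oscillators —
theta (4–8 Hz), alpha (8–13 Hz), beta (13–30 Hz) — plus a 1/f pink
background. Oscillator centre frequencies and phases are drawn once per
channel, so a session has a stable spectral fingerprint; the hidden emotion
state of each 0.5-s window modulates only the band amplitudes.

The state-to-band mapping in `default_band_profile()` raises beta power
(12 µV vs 3 µV) in the *active* state and alpha power (12 µV vs 4 µV) in
the *passive* state, with *normal* in between. This follows the common
affective-EEG convention of beta engagement versus alpha idling; it is a
modelling choice whose purpose is to make states spectrally separable, not
to be physiologically exact. Consequences of this design worth keeping in
mind:

* Within a session the oscillator frequencies never change, so a
  classifier trained on a *single* session can memorise frequencies rather
  than band structure. The benchmark (below) therefore trains across
  several sessions.
* Real EEG has volume-conducted correlation between nearby channels; the
  generated channels are independent draws. Artifact removal by spatial
  filtering is therefore, if anything, harder on the synthetic data than on
  real recordings, because clean rank-1 structure exists only for the
  artifacts themselves.

`contaminate()` adds three artifact classes with stored ground truth so
that denoising quality is measurable exactly:

* ocular blinks — Poisson-timed (default 0.25 events/s) raised-cosine
  transients, 400 ms wide and 80 µV at the peak, weighted 1.0 on FP
  channels and 0.35 elsewhere;
* mains interference — a common sinusoid (default 50 Hz, 10 µV) with a
  random per-channel gain in [0.8, 1.2], making it a spatial rank-1
  source;
* white sensor noise (default 5 µV SD).

The additivity invariant `clean + artifacts == noisy` holds to machine
precision, and every operation is bit-reproducible under a fixed seed.

`standard_contamination_session()` freezes the benchmark condition used
throughout: 30 s at 250 Hz with all three artifact classes at the defaults
above. Thirty seconds was chosen so that the ~20–30-dimensional ICA run by
the combined denoiser has an adequate sample count (7500 samples); the
white-noise, blink and mains levels are typical of dry-electrode frontal
recordings.

## Denoising

Three paths share one interface, `denoise(rec, method)`:

**EMD.** Classic Huang-style sifting (`sift_imfs()`): cubic-spline upper
and lower envelopes through the local extrema with mirror-symmetric
boundary extension, a Cauchy standard-deviation stopping rule (threshold
0.2) combined with the IMF criterion (|#extrema − #zero-crossings| ≤ 1),
at most 10 sifting passes per mode and 10 modes. Decomposition is exactly
invertible by construction. The EMD-only denoiser drops leading
(fastest) IMFs whose correlation with the channel is below one tenth of
the best IMF–channel correlation — a common heuristic. On realistic
contamination this screen rarely removes anything (the noise IMFs still
correlate with the noisy input), which reproduces the known weakness of
correlation-screened EMD denoising: the EMD row of the benchmark table is
essentially a no-op, and its improvement ratio hovers near 0 dB.

**FastICA.** Symmetric fixed-point iteration with the tanh contrast, PCA
whitening, tolerance 1e-6, and a seeded random orthonormal initialisation
(`fast_ica()`). Components flagged as artifacts are zeroed and the rest
back-projected.

**EMD+FastICA.** Two chained stages targeting complementary artifact
classes:

1. a channel-space FastICA rejection pass — ocular and mains artifacts are
   spatially rank-1 across the montage (one waveform times a channel-gain
   vector), which channel ICA isolates and removes essentially exactly;
2. per-channel EMD, all channels' IMFs *and residues* stacked into one
   multivariate matrix, FastICA across the stack (at the stack's effective
   rank), rejection of band-concentrated noise components, reconstruction
   and per-channel re-summation. The residues must be part of the stack
   because low-frequency artifact energy ends up partly in them.

The band-separated stack is what lets the second stage see broadband
sensor noise at all: in channel space, white noise is spread across every
component and cannot be isolated, whereas fast IMF rows are nearly pure
out-of-band noise. This division of labour is why the combined method
dominates both single methods on the benchmark — each stage removes what
the other cannot.

Component rejection uses three criteria, each evaluated on the interior of
the record (trimming 0.5 s per side, because spline end effects can make
decomposition components look spiky) and only for components whose
back-projected amplitude exceeds 1 µV RMS on their strongest row — faint
background never qualifies as an artifact:

* *transient*: excess kurtosis > 5, and (in the stacked stage) projection
  spread over more than one channel's rows — ocular artifacts are
  multi-channel by construction, while background-EEG components
  concentrate in a single channel. Slow narrowband components with few
  cycles in the record routinely show high sample kurtosis, so kurtosis
  alone over-rejects; the spread gate fixes that. In the chained
  composition the stacked stage omits this criterion entirely, since the
  channel stage has already taken the spatially coherent transients.
* *line*: more than 60% of spectral power within ±1 Hz of the configured
  mains frequency;
* *out-of-band*: more than 60% of spectral power above 35 Hz (the EEG band
  of interest ends at 30 Hz; the margin avoids clipping beta).

With these rules a zero-artifact session passes through all three paths
essentially unchanged, and on the standard benchmark the combined path
achieves the highest signal-to-noise improvement and lowest MAPE of the
three methods on effectively every seed.

**Metrics.** `snir()` is the output-minus-input SNR difference in dB,
equivalently `10*log10(P_noise_in / P_noise_out)`; a perfect
reconstruction saturates at +300 dB rather than overflowing. `mean_energy()`
is the mean squared amplitude — note the unit is µV² even though
comparison tables in this field often label the column just "µV"; the
formula is the squared one regardless. `mape()` excludes samples whose
reference magnitude is below 1e-6 µV (the ratio is undefined at zero
crossings, which EEG hits constantly) and warns when it does so. MAPE on
zero-mean signals is dominated by samples near zero crossings and is
therefore large in absolute terms for any broadband residual; it is used
comparatively, never as an absolute quality figure.

## The window classifier network

`train_cnn()` implements the classifier from first principles (no deep
learning framework): valid-mode convolution layers with weight sharing,
pooling layers computing `pool(window) * beta_j + b_j` with the multiplier
and additive deviations trainable (initialised at 1 and 0), fully
connected stages, and a 2-unit softmax output with log-sum-exp
stabilisation. The loss is mean cross-entropy; training is plain
full-batch gradient descent `W <- W - eta * dE/dW` with optional inverted
dropout on FC activations (masks resampled per batch from a seeded
stream) and an L1 subgradient on all weight matrices.

Choices the printed architecture leaves open, and what this package does:

* Kernel sizes, filter counts and FC widths are unspecified upstream; the
  defaults are conv kernels (1×7) along time, filters (8, 16, 32, 64),
  (1×2) pools after every conv layer, FC stages of 64 and 16 units, ReLU
  activations — matching the 11-stage layer numbering (input; four
  conv/pool pairs; two FC stages; output). Everything is configurable,
  and `validate_architecture()` rejects sequences that break the
  conv-pool alternation.
* Backpropagation is implemented as exact reverse-mode differentiation of
  the loss and verified against central finite differences (max relative
  error below 1e-4, in practice ~1e-8) for every layer type, activation
  and pooling mode. This is deliberate: transcribing printed chain-rule
  sketches is error-prone, whereas the gradient check pins the
  implementation to the mathematics.
* Pooling inputs that do not divide evenly are zero-padded on the
  right/bottom, preserving early samples.
* Inputs can be standardised by the training-set mean/SD (stored in the
  model); raw microvolt magnitudes otherwise interact poorly with
  unit-scale weight initialisation.
* The optimiser is deliberately plain gradient descent (no momentum or
  Adam); the default learning rate 0.01 is conservative, and the
  benchmark uses 0.05, which occasionally lands full-batch descent in a
  poor optimum — handled by deterministic random restarts, not by
  changing the optimiser.

`to_input_tensor()` maps a window to the `[n_channels, n_samples, 1]`
array the network consumes, values unchanged.

## The gradient-boosting classifier

`train_gb()` implements stagewise logistic boosting: the link is
`p = e^F / (e^F + e^-F)` (algebraically `logistic(2F)`), the initial score
F0 = 0 so the initial probability is exactly 0.5, pseudo-residuals are
`2(y - p)`, and each weak learner is a time-indexed ordinary-least-squares
projection: for every candidate time index t, the coefficient vector a(t)
solves `min_a sum_i (r_i - a' o_i(t))^2`, and the (a, t) pair with minimum
SSE wins (ties to the smallest t; singular designs fall back to a 1e-8
ridge with a warning). The learner weight gamma maximises the
log-likelihood along the update direction — the likelihood is concave in
gamma for this link, so a golden-section/parabolic search on [-10, 10]
refined by bisection on the derivative finds it reliably — and the update
applies shrinkage: `F <- F + epsilon * gamma * f`, with `epsilon = 0.1` by
default ("a small number"; 0.1 is the standard shrinkage scale). Training
stops early when the likelihood gain falls below 1e-8, and the likelihood
history is non-decreasing by construction (a line-search result that would
decrease it is rejected).

The feature representation `o_i(t)` is a per-sample matrix with one column
per time index. In the full pipeline the boosting model is stacked on the
network's penultimate-layer features (a single time index); it can equally
be trained on raw per-channel values over a decimated time grid.

## From probabilities to music

`classify_windows()` scores each 0.5-s window with the available models
and maps the positive-state probability s to a ternary label with a dual
threshold: *active* above 0.6, *passive* below 0.4, *normal* between. The
binary classifiers upstream force this bridge; the thresholds are
configurable. When both models are present the decision uses the more
decisive of the two probabilities (the one further from 0.5): the
network's softmax is typically sharp on windows it recognises, while the
stacked boosting score degrades gracefully toward 0.5 on unfamiliar ones,
and an undecided member should not veto a confident one.

`segment_decision()` aggregates 12 consecutive windows (6 s) by majority;
ties go to *medium* music — the neutral stimulus is the safe default. The
state-to-music mapping (active → positive music, passive → negative,
normal → medium) follows the therapeutic aim of reflecting the decoded
state back to the subject; an inverse, compensatory mapping is one
argument away. `marker_count()` is the window accounting: 399 six-second
segments make 4788 half-second markers.

`render_music()` emits symbolic note events, not audio: an ascending
major-mode motif at 120 bpm for positive valence, a descending minor-mode
motif at 60 bpm for negative, a pentatonic drone at 90 bpm for medium,
with seeded octave/velocity variation. Segments are written as CSV event
tables. `schedule_protocol()` encodes the session plan — scales 10 min,
preparation 3, breathing practice 3, two 13-minute feedback exercises —
totalling 42 minutes and validating any configuration against the
45-minute session cap.

## Scales and statistics

`classify_severity()` bands SCL-90 as normal (0–26) / mild (>26), the SDS
index as normal (0–52) / mild (53–62) / moderate (63–72) /
moderate-severe (>72), and PHQ-9 with the standard five bands (0–4, 5–9,
10–14, 15–19, 20–27). Published banding tables for this design garble the
upper SCL-90 and PHQ-9 cells; the package keeps SCL-90 to two bands and
adopts the standard PHQ-9 cuts, which is the only reading consistent with
the instruments' ranges. Group eligibility (`assign_group()`) is a
separate rule set — normal controls below 8/53/5, the mild-depression
band at SCL-90 > 26, SDS 53–62, PHQ-9 5–9 — and deliberately does not
reuse the severity bands: screening criteria and severity grading serve
different purposes and are documented separately.

`t_test_from_stats()` computes the independent two-sample t-test from
summary statistics, pooled-variance by default ("independent t-test" in
the classic sense) with Welch available by flag; it agrees with
`stats::t.test()` to 1e-10 across randomised grids and is calibrated —
5% ± 2% type-I error over 2000 seeded null draws. `longitudinal_report()`
produces the per-scale, per-occasion group summaries, the three pairwise
tests, and least-squares trend flags. P-values published from rounded
summary rows cannot be recovered exactly — the rounding discards the
information they were computed from — so the statistics layer asserts
qualitative structure (group separation growing over occasions,
feedback-group decline), never specific published p-values.

`gen_scale_cohort()` draws subjects from truncated normals around group
trajectories (feedback declining from the mild-depression baseline toward
the normal range over six weekly occasions, controls flat), truncating
baselines to the eligibility box so generated cohorts always satisfy the
grouping criteria. Study sizes default to 4 feedback / 8 depression
control / 4 normal control. One published trajectory skips the fifth
occasion; the generator interpolates it linearly.

## The end-to-end benchmark

`window_benchmark()` is the package's scaled stand-in for a study-size
evaluation: eight 60-second training sessions at 128 Hz (960 windows),
alternating 6-s active/passive blocks; the network (two conv/pool pairs,
filters 4 and 8, kernel 1×5, one FC stage of 8 units, learning rate 0.05,
60 epochs) is trained on all sessions pooled, with up to three
deterministic restarts if training accuracy stays below 0.98; the boosting
model is stacked on the penultimate features (M = 30, epsilon = 0.1); and
agreement is measured against the ground-truth states of a held-in
session drawn from the same generator conditions. Eight sessions matter
more than long sessions: each session contributes three fresh oscillator
draws per band, and frequency coverage — not sample count — is what makes
the learned features band-level rather than session-specific. Typical
agreement is 0.94–1.00, against the 0.90 acceptance bar.

The benchmark uses two-state (active/passive) sequences. The *normal*
state is defined by the dual-threshold bridge, not by the binary
classifiers, so a three-state truth sequence would conflate classifier
quality with threshold calibration; the two-state benchmark isolates the
former. Problem sizes throughout the test-suite (30-s denoising sessions,
10-seed comparisons, 60-s benchmark sessions, 2000-draw calibration) were
chosen as the smallest sizes at which the corresponding estimator is
stable.

## What passing tests do and do not show

The synthetic generator emulates band-structured oscillatory EEG with
additive, statistically well-behaved artifacts. Real recordings add
non-stationary rhythms, volume conduction, electrode drift, muscle
artifacts with EEG-band overlap, and subject variability — none of which
are modelled. Green benchmarks therefore demonstrate that the algorithms
are implemented correctly and behave as designed under controlled
conditions; they do not demonstrate clinical performance. The same
applies to the scale-score layer: it reproduces the statistical
machinery, not patient data.

Known limitations: the EMD-only denoiser inherits the weakness of its
correlation screen by design; the MAPE metric is unstable near zero
crossings and is used comparatively only; FastICA on very
high-dimensional IMF stacks occasionally fails to converge within the
iteration cap (the best iterate is used and flagged); and the music
renderer is symbolic, with no audio synthesis.
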