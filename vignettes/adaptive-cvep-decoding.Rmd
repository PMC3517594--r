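---
title: "Adaptive c-VEP decoding: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive c-VEP decoding: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cvep)
```

## The decoding problem

A code-modulated visual evoked potential (c-VEP) speller presents 32
targets that all flash the same pseudorandom binary sequence, each at a
different circular shift.  Attending one target imprints a code-locked
response on the EEG over parieto-occipital cortex; identifying *which*
circular shift best explains the recorded trial identifies the attended
target.  One selection takes a 63-bit stimulation period of 1.05 s at a
60 Hz refresh rate plus a break of about 0.85 s — a nominal 1.9 s per
selection, which is what makes the paradigm one of the fastest
non-invasive BCIs.

The modulation sequence is a maximal-length LFSR sequence (m-sequence) of
length `2^6 - 1 = 63`.  Its two properties do the heavy lifting:

* **balance** — 32 ones and 31 zeros, so every target receives nearly
  identical stimulation energy;
* **two-valued cyclic autocorrelation** — in the ±1 mapping, the
  autocorrelation is 63 at lag zero and exactly −1 at *every* other lag,
  so a response template correlates almost orthogonally with every wrong
  shift.

`generate_msequence()` runs a configurable Fibonacci LFSR and verifies the
full period; non-primitive tap sets are rejected rather than silently
producing a short cycle.  The polynomial and seed of the originally
deployed system are not recoverable, so the default (taps {6,5}, all-ones
seed) is one valid choice among the equivalence class that satisfies both
invariants; taps and seed are recorded on the code object for session
logs.  Consecutive targets are separated by `bit_lag = 2` bits, and the
global convention — used identically by the code generator, the simulator
and the classifier — is that target *k*'s stimulus (and response) is the
base sequence *delayed* by `2k` bits (20·k samples at 600 Hz).  Only
consistency of this convention matters; the opposite direction would work
equally well everywhere.

## Calibration pipeline

Training trials are circularly re-shifted into the target-0 frame so they
can be averaged.  Calibration is then three steps:

1. **Best-channel selection** (`select_best_channel()`).  For every
   channel, a leave-one-out cross-validation classifies each trial by
   Pearson correlation against the circular shifts of the remaining
   trials' average; the channel with the highest LOO accuracy becomes the
   reference channel.  Ties break to the lowest channel index.  This stage
   deliberately uses the plain correlation classifier, not the one-class
   SVM: it is a cheap, template-free scoring rule, and the SVM enters only
   after spatial filtering.
2. **CCA spatial filter** (`compute_cca_filter()`).  With the across-trial
   average waveform of the best channel (tiled over trials) as a
   univariate reference, canonical correlation analysis reduces to a
   single canonical pair: `w ∝ Cxx⁻¹ Cxy`.  We add a relative ridge of
   1e-8·mean(diag(Cxx)) — the problem (≥ 630·Nt samples for ≤ 30
   channels) is well-posed, but degenerate synthetic edge cases (zero
   channels, duplicated channels) need the guard.  The filter is scaled to
   unit norm and its sign fixed so the canonical correlation is
   non-negative; Euclidean template matching downstream is sign-sensitive,
   so the sign convention must be deterministic.
3. **One-class SVM template** (`fit_template()`).  The spatially filtered,
   label-aligned trials are summarized by a one-class SVM with a linear
   kernel (ν = 0.5 by default).  The solution is a capped-simplex weighted
   mean of the trials: each trial's weight is bounded by `1/(ν·n)`, and
   trials that would inflate the enclosed region get zero weight — an
   outlier-robust average.  The template of target *k* is the base
   template circularly delayed by `2k` bits, and a new trial is classified
   by minimal Euclidean distance over the 32 shifted templates (ties to
   the lowest index).  Distances are computed on the full 630-sample
   window without energy normalization; a normalization flag is not
   offered because nearest-template matching on the raw filtered signal is
   the documented contract, and scale differences are already absorbed by
   the fixed filter normalization.

The choice ν = 0.5 is a midpoint giving robust-mean behaviour; tests
exercise ν ∈ {0.1, 0.5, 0.9} against an independent projected-gradient
solver of the same dual, so the contract is the optimization, not the
specific solver.

The simulator plants the response with a fixed latency (36 ms by default,
rounded to whole samples — 22 samples at 600 Hz).  The classifier never
compensates latency explicitly: because stimulation is periodic and
steady-state, a constant latency is simply absorbed into the learned
template.  This mirrors the deployed pipeline, which likewise contains no
latency parameter.

## Online adaptation

A `classifier_state` bundles the training buffer, the spatial filter and
the template set.  Every retrain re-runs the whole calibration chain on
the buffer (best channel, CCA, one-class SVM, 32 shifted templates) and
increments a generation counter.  Four regimes feed the buffer:

* **supervised** — co-adaptive calibration: the system starts from random
  templates (standard-normal base template; the distribution is our
  choice, since only "random" is specified), classifies each trial for
  feedback, then adds it under its *true* label;
* **unsupervised** — self-training: the predicted label is assumed
  correct.  Each misclassification contaminates the buffer with a trial
  aligned in the wrong frame; thanks to the −1 off-peak autocorrelation
  such contamination acts mostly as added noise rather than systematic
  bias, which is why self-training helps under drift until the error rate
  grows large;
* **ErrP-gated** — self-training, except trials on which an error-related
  potential is detected are discarded: their label is suspect and the true
  one is unknown;
* **two-target ErrP calibration** — classification is restricted to a
  target pair (J and W by default); a detected error *flips* the label to
  the other pair member.  With a perfect detector the label stream equals
  the supervised one; with a blind detector (zero sensitivity) the loop
  can lock into the inverted mapping and end below 50 % accuracy — a
  failure mode the tests reproduce deliberately.  Because all targets
  share one code, a 2-target calibration suffices to build all 32
  templates.

Design choices where the loop design was genuinely open:

* **Retraining data** — all accumulated trials, with no forgetting window:
  nothing suggests a window, and the drift rates we emulate are slow
  enough that the growing buffer still tracks them.
* **Best-channel re-estimation** — recomputed at every retrain (the
  retraining step is described as including channel estimation), with a
  `freeze_channel` flag for studies that want it fixed after calibration.
* **Retrain cadence** — synchronous (`batch_size = 1`, retrain after every
  accepted trial) or deferred (`batch_size > 1`): trials accepted
  mid-batch wait for the next retrain, emulating an adaptation loop
  running in parallel with classification.  The two modes provably ingest
  identical buffers in identical order; the per-trial waiting time is
  logged in trials rather than wall-clock so tests stay deterministic.
* **Initial filter** — before any data arrive the state uses a uniform
  unit-norm channel average; any fixed non-degenerate filter would do, as
  the first retrains replace it.

## Error-related potential detection

Feedback-locked epochs are processed exactly in this order: common-average
reference over all channels, per-channel linear detrend, 1–16 Hz bandpass,
resampling to 32 Hz, extraction of the 300–990 ms window, concatenation of
the five midline channels Fz, Cz, CPz, Pz, POz.  Numerical choices:

* the bandpass is a zero-phase (forward-backward) 4th-order Butterworth —
  the filter family for this stage is not recoverable, and a zero-phase
  Butterworth is the standard, artifact-free default for ERP windows;
* resampling is polyphase (`signal::resample`, 600 → 32 Hz as 4/75) after
  the bandpass, so no aliasing concern arises;
* the window is half-open, `[300, 990) ms`: at 32 Hz the printed endpoints
  are compatible with 22 or 23 samples per channel, and the half-open
  convention gives 22 — hence 5 × 22 = 110 features.  The window and rate
  are configurable; 110 is asserted in tests as the default geometry.

The detector is a binary SVM with an RBF kernel at the historical LibSVM
defaults (`gamma = 1/n_features`, `cost = 1`).  When the training data
contain no error epochs — a realistic outcome for a user whose BCI hardly
errs — a degenerate always-"no-error" detector is returned with a warning,
so downstream gating degrades gracefully to plain self-training.
Closed-loop studies may replace the trained detector by an oracle with
stated sensitivity/specificity (`errp_oracle()`); that separation lets the
adaptation behaviour be studied independently of detector quality.

## Performance accounting

`wolpaw_itr()` implements the standard bits-per-selection formula
`B = log2(N) + P·log2(P) + (1−P)·log2((1−P)/(N−1))` scaled by 60/duration.
The formula is mathematically positive again below chance for N = 2, yet
printed results use 0 for a below-chance run; we therefore define ITR = 0
for P ≤ 1/N.  The nominal selection period is 1.9 s, but because measured
periods in practice differ at the 10-ms level, duration is an explicit
argument everywhere and never silently defaulted in reports.  Free
spelling is summarized application-centred: error-free letters per minute,
with every error corrected once via a backspace selection, so
`trials = written + 2·deleted` whenever backspaces themselves classify
correctly.  Table percentages round half away from zero to two decimals
(`as_table_percent()`).

## What the synthetic generator emulates — and what it does not

`forward_model()` plants: a code-locked kernel (the ±1 stimulus sequence
circularly convolved with two damped sinusoids, a few µV in amplitude), a
fixed unit-norm spatial pattern peaking at P4/PO3, a 36 ms response
latency, additive white noise (optionally 1/f), and optional slow linear
drift of amplitude and latency.  Error epochs plant a −3 µV deflection at
310 ms and a +5 µV deflection at 420 ms with a fronto-central topography.
Every stochastic operation takes an explicit seed and leaves the global
RNG untouched.

It does **not** emulate: biophysical volume conduction, eye blinks and
EOG contamination (the known failure mode of one excluded participant),
non-target complementary flickers, amplifier filter ringing (the 0.5–60 Hz
Chebyshev chain is available as an optional post-filter but off by
default so tests see the raw construction), or realistic cross-subject
variability.  Green tests therefore certify the *machinery* — code
properties, filter optimality, template optimization, adaptation
book-keeping, accounting identities — and the qualitative behaviours
(robustness to outliers, benefit of adaptation under drift, inverted
lock-in), not the absolute accuracies a particular human cohort would
reach.

## Study conditions used by the simulation studies

Problem sizes were chosen so the full suite runs comfortably on one CPU:

* **Regime comparison** (no/unsupervised/ErrP-gated/supervised): 20 seeds,
  a 12-channel montage (prefix of the 30-channel one, containing all
  decoding and ErrP electrodes), noise sd 10 µV, 30 ms linear latency
  drift over the session, 64-trial supervised calibration + 128 test
  trials, deferred retraining with `batch_size = 4`, and a (0.70, 0.98)
  oracle detector.  Noise and drift were set so the frozen-classifier
  baseline lands clearly below 85 % — the moderate-accuracy regime in
  which gating has room to help.
* **Two-target calibration**: 64 trials, alternating J/W intents; perfect
  detection is checked for label-stream equality with supervised
  calibration (2 seeds), and the inverted lock-in probe runs 50 seeds on
  an 8-channel montage.
* **Detector studies** use 10-channel epochs and 40–120 epochs per class.

## Known limitations

* The exact deployed m-sequence polynomial, the per-session selection
  periods behind printed bit rates, and the ν used originally are not
  recoverable; defaults are documented single choices, all configurable.
* The LOO channel scorer is O(channels × trials²) per retrain; it is
  vectorized (cached autocorrelations plus one BLAS product per channel)
  but very long sessions with synchronous retraining will want
  `batch_size > 1` or `freeze_channel = TRUE`.
* Latency is rounded to whole samples (36 ms → 22 samples at 600 Hz);
  sub-sample latency drift is approximated by its rounded schedule.
* EEG import/export is limited to a plain-text trial container
  (CSV + JSON sidecar); session logs are CSV/JSON-lines.
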