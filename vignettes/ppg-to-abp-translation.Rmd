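---
title: "Translating PPG into continuous blood pressure waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translating PPG into continuous blood pressure waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Arterial blood pressure (ABP) varies continuously — over days, minutes, even
seconds — but the clinical reference for a continuous ABP waveform is an
invasive arterial catheter.  Photoplethysmography (PPG), the optical
blood-volume signal behind every pulse oximeter and fitness tracker, is
noninvasive and cheap, and its morphology carries information about the
pressure wave that produced it.  `ppg2abp` implements a cuff-less estimation
pipeline that maps a raw 125 Hz PPG segment to a full ABP waveform in mmHg,
then reads systolic (SBP) and diastolic (DBP) pressure off the translated
waveform as its per-segment maximum and minimum.

The translator is a sequence-to-sequence LSTM autoencoder trained in two
stages:

1. **Reconstruction.**  The autoencoder learns to reproduce the PPG from its
   own 3-channel representation (PPG, first derivative, second derivative).
   This teaches the encoder a latent description of pulse morphology.
2. **Translation with a frozen encoder.**  The encoder weights are frozen
   bit-for-bit and only the decoder (carried over, not re-initialized) plus a
   per-timestep linear head continue training, now against ABP targets.

The latent representation is the full per-timestep hidden-state sequence
(`T x hidden`), not a single bottleneck vector, so any input length maps to
an equal-length output.

## Preprocessing

Every segment passes through four steps, in order:

* **Denoising** — third-order Butterworth bandpass, 0.5–8 Hz at 125 Hz,
  applied forward–backward.  Zero-phase application is a deliberate choice:
  the PPG/ABP phase lag is estimated and corrected separately, and a causal
  filter's phase distortion would corrupt the derivative channels.
* **Alignment** — PPG physically lags ABP by less than one pulse period.
  The lag is the argmax of the valid-overlap cross-correlation
  `g(dt) = sum_t ABP[t] * PPG[t + dt]` over `dt in [0, max_lag)`; the PPG is
  advanced by that lag and both channels are shortened equally (the exposed
  tail is dropped rather than invented).  The ABP channel is never shifted.
* **Normalization** — each training signal is z-scored with its own mean and
  population (divide-by-n) standard deviation; the *averages* of those
  per-signal parameters over the training set are applied to every test
  signal.  ABP targets are scaled with a single global pair fit on training
  ABP and inverted to mmHg at prediction time.  How the reference setup
  scaled its ABP targets is not documented anywhere we know of; a global
  z-score is this package's choice, made so that the inverse transform is a
  fixed affine map independent of the (unknown at test time) target segment.
* **Derivative channels** — central differences
  `(x[i+1] - x[i-1]) / (2h)` with one-sided first-order differences at the
  two endpoints, keeping all three channels the same length.  `h = 1/125` s.

## Quality control

Four elimination rules screen every aligned segment; all four are always
evaluated and reported:

| rule | condition to pass |
|---|---|
| SBP range | `80 <= max(ABP) <= 180` mmHg |
| DBP range | `60 <= min(ABP) <= 130` mmHg |
| morphology | Pearson r between aligned PPG and ABP `>= 0.8` |
| peaks | at least one detectable PPG systolic peak |

The pressure bounds are strict on the outside (exactly 180 or exactly 60
passes).  The correlation is computed per segment on the whole aligned pair;
where the threshold should apply (per beat, per segment, per subject) is
ambiguous in the source description, and per-segment is the choice that
reproduces an elimination rule cleanly.  The systolic peak detector is a
rolling-mean adaptive threshold: candidates are maxima of regions above a
0.75 s rolling mean raised by a percentage of the signal amplitude; several
percentages are tried; detections implying an instantaneous rate above
180 bpm are rejected; and the winning threshold's rhythm must be regular
(robust interval dispersion below 25% of the median, median rate inside
40–180 bpm) *and* visible in the signal's autocorrelation at the median beat
interval.  The autocorrelation gate is what rejects noise-only signals whose
surviving detections can masquerade as a plausible rate.

## The synthetic paired-waveform generator

Real paired PPG/ABP data comes from ICU waveform databases that cannot ship
with a package.  The generator replaces them with segments whose ground
truth is known exactly:

* Each beat is the sum of two Gaussian lobes — systolic at 30% of the beat
  period, dicrotic at 65% — which reproduces the four classic landmarks
  (foot, systolic peak, dicrotic notch, diastolic peak) with two parameters.
* The ABP waveform is affinely rescaled so `max = SBP` and `min = DBP`
  exactly when noise is off; the PPG is emitted in arbitrary units centred
  near zero and circularly delayed by `lag_samples`.
* Because the PPG and ABP beat shapes differ, their raw cross-correlation
  optimum would sit a couple of samples off the shared beat clock; the
  generator pre-aligns the templates so the optimum is exactly at the
  configured lag, which is what makes exhaustive lag-recovery tests
  meaningful.
* **Morphology–pressure coupling.**  The PPG systolic lobe width grows
  linearly with DBP and its dicrotic amplitude falls linearly with SBP,
  emulating (in stylized form) the dependence of peripheral pulse shape on
  vascular tone.  This deterministic map is what makes the translation task
  well-posed: per-segment z-scoring erases amplitude, so pressure must be
  readable from shape alone, exactly as in the real task.
* Corruption modes map one-to-one onto QC failure reasons so QC tests have
  labelled ground truth: `flatline` → no detectable peak, `dropout_burst`
  (a zeroed 45% run) → morphology correlation below 0.8, `saturation` (an
  ABP run railed at 200 mmHg) → systolic bound violation.

Defaults: 1024-sample segments (~8.2 s; the length is not documented in the
reference description, so a power of two covering at least eight beats at
60 bpm was fixed once), heart rate 75 bpm with 2% beat-to-beat jitter, lag
35 samples (0.28 s, a typical observed value), additive Gaussian noise of
0.05 per channel in channel units, and 0.1 a.u. of 0.25 Hz baseline wander
on the PPG.

What the generator does **not** emulate: drug-induced blood-pressure
variability of ICU patients, motion artefacts with in-band spectra,
respiratory modulation, arrhythmia, sensor-coupling drift, and any
hemodynamic (Windkessel/pulse-wave-velocity) physics.  Passing tests on
synthetic data therefore demonstrate that the pipeline's machinery is
correct and that the model can learn a morphology-to-pressure map; they do
not certify accuracy on clinical data.

## Model and training

Reference hyperparameters, all overridable: two LSTM layers per phase with
128 hidden nodes, dropout 0.2 at the end of the decoding phase, learning
rate 0.0025 with Adam, at most 50 epochs per stage, and a 70/10/20
train/validation/test split.  Choices this package had to make where the
reference setup is silent:

* **Loss** — mean squared error (only "reconstruction error" is specified).
* **Stage-1 target** — the PPG channel only, so the one-channel decoder head
  is identical across stages.
* **Decoder provenance** — stage 2 fine-tunes the stage-1 decoder rather
  than re-initializing it; only the encoder's freezing is prescribed.
* **Split unit** — subjects, not segments, to prevent leakage between
  partitions.
* **Batch size** — 128 by default; early stopping on validation loss with
  patience 5 inside the epoch cap.
* **Initialization** — uniform `(-1/sqrt(H), 1/sqrt(H))` weights, zero
  biases except a +1 forget-gate bias; global gradient-norm clipping at 5.
  Training is exactly reproducible for a fixed seed (a private Mersenne
  Twister drives initialization, shuffling and dropout).

The LSTM forward pass, backpropagation through time, Adam and dropout are
implemented in compiled code inside the package; activations are stored
time-major so input projections, the linear head and all weight gradients
are single large matrix products, and gate nonlinearities use an exp-based
tanh that is bit-stable and faster than the library call.

## Desk-scale validation study

`desk_config()` pins the package's reference small-compute experiment: 250
synthetic subjects × 8 noise-free 256-sample segments (≈2,000 segments,
~10% of which QC eliminates — short segments genuinely have poorly settled
filter transients and hence weaker morphology correlation), a 32-unit model,
15 epochs per stage, batch 64, learning rate 0.005, and a control arm in
which a never-pretrained random encoder is frozen and given the identical
translation budget.  On one CPU a full run takes a few minutes.  Typical
results (seed 1): held-out median |SBP error| ≈ 3 mmHg, r(SBP) ≈ 0.95, and
the transferred encoder reaches a lower validation loss than the random
frozen encoder.  The acceptance script (`scripts/acceptance.R`) recomputes
all of these from scratch.

## Evaluation

Per-segment SBP/DBP errors (predicted − observed, mmHg) feed:

* **MAE** and **RMSE**;
* **BHS grading** — cumulative percentages of absolute errors within 5, 10
  and 15 mmHg, graded A (≥60/85/95), B (≥50/75/90), C (≥40/65/85), else
  fail; threshold comparisons on errors are inclusive (an error of exactly
  5 mmHg counts as within 5);
* **AAMI criterion** as applied in this line of work — MAE < 5 mmHg,
  error SD < 8 mmHg, more than 85 subjects, all strict.  The real standard
  uses the mean signed error; the MAE usage is reproduced deliberately, not
  corrected, so results remain comparable.
* Pearson correlations between predicted and observed SBP and DBP.

The error standard deviation uses the population formula, consistent with
the normalization step.

## Known limitations

* Synthetic morphology is two Gaussian lobes per beat; real PPG has richer
  harmonic content and age-dependent dicrotic visibility.
* The morphology–pressure coupling is deliberately strong and noiseless in
  the desk-scale study; real coupling is weaker, subject-specific and
  confounded.
* Whole-segment alignment approximates the per-beat alignment a
  beat-delineation stage would provide.
* Length generalization is imperfect for extrema: the network emits valid
  waveforms for any input length, but a model trained on ~2 s windows
  over-predicts the segment maximum on much longer inputs (more beats give
  upward excursions more chances to inflate `max(ABP)`).  Translate at, or
  near, the trained window length, or train at the target length.
* Full-scale training (128 hidden units, hundreds of thousands of segments)
  is out of desk reach; the implementation is exact but slow at that scale
  on a single CPU.
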