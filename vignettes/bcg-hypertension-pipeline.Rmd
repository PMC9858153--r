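---
title: "Detecting hypertension from ballistocardiograms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hypertension from ballistocardiograms: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the pipeline

A ballistocardiogram (BCG) records the micro-movements of the body caused by
the heart ejecting blood, typically through a pressure sensor in a mattress
or chair. Because acquisition is contactless, BCG is attractive for long-term
screening — including screening for hypertension, whose cardiac signature is
subtle but present in beat timing and beat morphology.

`bcgmixer` implements an end-to-end classification pipeline for one-channel
BCG amplitude series sampled at 100 Hz, labelled hypertensive (HPT) or
normotensive (NRT). The stages are fixed and ordered:

1. **Robust normalization.** Each recording is centered on its median and
   scaled by its raw median absolute deviation, `MAD = median(|x - median(x)|)`,
   so that the output has median 0 and MAD exactly 1. Body weight strongly
   scales raw BCG amplitudes, and the amplitude distribution is heavy-tailed,
   which is why MAD is used instead of the standard deviation and why **no**
   Gaussian consistency constant (1.4826) is applied: the contract is
   `MAD(out) = 1`, not `SD(out) ≈ 1`.
2. **Bandpass filtering** with a fixed fourth-order IIR transfer function,
   reported as a Chebyshev type II design at 1–50 Hz (see "The canonical
   filter" below).
3. **Segmentation** into non-overlapping 30-second windows (3,000 samples at
   100 Hz); the trailing remainder is discarded. Normalization is computed on
   the whole (trimmed) recording before segmentation, never per segment.
4. **Spectrogram imaging.** Each segment becomes a one-sided short-time
   Fourier magnitude matrix (Hann window of 128 samples, 15/16 overlap — an
   8-sample hop — and a 128-point FFT: 65 frequency rows × 360 frames for a
   3,000-sample segment), expressed in dB, floored at a configurable relative
   threshold, and rendered as an RGB heat map, first at 420 × 560 and then
   resized to the 224 × 224 × 3 classifier input.
5. **ConvMixer classification** with 10-fold cross-validation and
   accuracy/precision/recall/F1 reporting.

## The canonical filter

The filtering stage uses one fixed coefficient set:

```
b = (0.028, 0.053, 0.071, 0.053, 0.028)
a = (1, -2.026, 2.148, -1.159, 0.279)
```

These constants are treated as the reproducible contract of the stage and
are applied verbatim, causally (single forward pass, zero initial state).
They cannot, however, be a literal 1–50 Hz Chebyshev II bandpass at
fs = 100 Hz: the upper edge would coincide with the Nyquist frequency, where
no discrete-time bandpass is realizable, and the printed constants have DC
gain Σb/Σa ≈ 0.963, i.e. they barely attenuate baseline wander at all. The
poles sit at radii 0.61 and 0.87, so the filter is comfortably stable, and
its response is a mild low-pass-like smoothing rather than a sharp bandpass.
We keep the constants because fidelity to the published stage matters more
than fidelity to its description; `design_cheby2_bandpass()` (backed by
`signal::cheby2`) exists for users who want a true band-edge-specified
design, and it rejects edges at or above Nyquist. A `zero_phase` flag
switches to forward–backward filtering for users who care about phase
linearity more than causality.

One practical consequence is documented throughout: because the canonical
filter passes low frequencies, slow baseline wander survives into the
spectrogram and can dominate its lowest rows.

## The spectrogram and its one free parameter

Window type (symmetric Hann; a periodic variant is available), window length
(128), overlap (120) and FFT length (128) are all fixed defaults. Power is
converted to dB as `10·log10(power)` with a −120 dB floor for exact zeros.

The amplitude threshold is the single consequential free parameter of the
imaging stage: every time–frequency point more than `|threshold_db|` dB below
the per-segment maximum is clamped to that floor before color mapping,
removing low-amplitude clutter. The default is −40 dB relative to the
per-segment maximum. Published variants of this pipeline use *a* threshold
without stating its value; anything trained on these images is sensitive to
it, so it is exposed prominently in `spectrogram_config()`.

Rendering is deliberately free of plotting chrome: the dB matrix is min–max
normalized (making images invariant to additive dB offsets), mapped through
a perceptually ordered colormap (`grDevices::hcl.colors("viridis")` by
default), oriented with low frequencies at the bottom, resampled to
420 × 560 and then to 224 × 224 with an anti-aliased triangle (bilinear)
kernel whose support widens by the scale factor when downsampling. Both
resampling steps are linear maps, so they are applied as one fused
operator; a unit test verifies the fused operator equals the two-step path.
A constant matrix renders as a uniform image rather than erroring.

## The ConvMixer

The classifier is a from-scratch ConvMixer implementation (forward pass,
backpropagation and the optimizer are all implemented in this package, in
RcppArmadillo):

* patch embedding: a valid convolution with `hidden_dim = 32` filters of
  size 5 × 5 and stride 5, taking 224 × 224 × 3 to 44 × 44 × 32, followed by
  GELU and batch normalization;
* `depth = 7` mixer blocks, each a residual spatial-mixing stage
  (5 × 5 same-padded depthwise convolution → GELU → batch norm, with the
  block input added back) followed by channel mixing (1 × 1 pointwise
  convolution → GELU → batch norm); spatial size never changes;
* global average pooling to a 32-vector, then a dense layer and softmax.

The default configuration has exactly 16,674 trainable parameters, verified
in tests against a closed-form layer-count oracle.

Design points left open by the architecture's usual description, and how
they were resolved:

* **Depthwise kernel size** is 5 × 5 with same padding (the only kernel
  size that appears anywhere in the architecture description); configurable.
* **Residual placement.** The default wraps the whole spatial stage:
  `x + BN(GELU(DW(x)))`. A `residual = "pre_act"` variant adds the input
  before the activation, `BN(GELU(DW(x) + x))`, for users who read the
  block that way. Both variants pass the same finite-difference gradient
  check.
* **GELU** is computed with the widely used tanh approximation
  `0.5·z·(1 + tanh(√(2/π)(z + 0.044715 z³)))`. On a CPU-only double-precision
  engine the exact erf evaluation tripled the per-iteration cost while
  differing by less than 10⁻³ anywhere; the backward pass differentiates the
  implemented function exactly (verified against central differences at
  tolerance 10⁻⁴).
* **Batch normalization** uses biased batch variance during training and
  running statistics at inference; after training, inference statistics are
  recomputed exactly in one pass over the training split (combining batch
  moments by the law of total variance), which matters much more than the
  exponential moving average when training runs are short.
* **Initialization** is He-normal for weights, zeros for biases, unit gains
  for batch norm, fully determined by a seed.
* **Input normalization**: per-channel zero-centering with training-split
  means, stored on the model and re-applied at prediction time.

Training is classical SGD with momentum (`v ← μv − η·grad; w ← w + v`),
μ = 0.9, minibatch 64, 7 epochs, initial learning rate 0.001, cross-entropy
loss, with a 10% validation stream held out of each training split for curve
logging. No augmentation, weight decay, schedule or early stopping, since
the protocol defines none.

### Learning rates and problem size

The default learning rate (0.001) is calibrated for full-size image sets: at
12,800 images and batch 64 it corresponds to roughly 1,260 SGD iterations
over 7 epochs. The package's own test cohorts are deliberately small — a
16-subject, 5-minute easy-mode cohort yields 160 images and therefore only
14 iterations — and at that budget a rate of 0.001 cannot move the network
appreciably in any direction; measured fold accuracy was initialization
luck. The desk-scale checks in the test suite therefore train with
`lr = 0.05`, the rate matched to a ~100× smaller iteration budget, while
`train_config()` keeps 0.001 as the default for full-scale use. Under the
desk-scale rate the easy-mode 5-fold cross-validation reaches 100% mean
accuracy deterministically.

## The synthetic cohort generator

No clinical recordings ship with the package; every stage is exercised on
synthetic cohorts from `generate_cohort()`. A synthetic subject is

```
amplitude_scale × (beat wavelet train) + baseline wander + white noise (+ optional mains tone)
```

* Each heartbeat is a Gaussian-modulated sinusoid (center 5 Hz, envelope
  FWHM 0.15 s) — a stand-in for the BCG IJK complex that places beat energy
  inside the 1–50 Hz analysis band without claiming physiological
  morphology.
* Heart rate is drawn per subject from the class distribution; the
  realistic defaults are 77.1 ± 9.2 BPM (hypertensive) and 73.6 ± 8.3 BPM
  (normotensive), heavily overlapping, as in published cohort statistics for
  the 61 + 67-subject dataset this pipeline targets. Beat-to-beat intervals
  are jittered with a 3% fractional SD.
* The per-subject amplitude scale is log-normal (σ = 0.5), emulating
  body-weight effects and exercising the normalization stage.
* Baseline wander is a 0.2 Hz sinusoid (amplitude 0.5 by default), below
  the nominal 1 Hz band edge; broadband sensor noise has SD 0.3; an optional
  mains tone and an optional respiration-like amplitude modulation are off
  by default. An optional 16-bit quantization step emulates the ADC and is
  also off by default.
* Everything is reproducible from a single master seed, with per-subject
  seeds derived deterministically.

**Easy mode** (`separation_mode = "easy"`) is a testing construction, not a
model of physiology: the two classes get disjoint wavelet centers (10 Hz for
HPT, 4 Hz for NRT), disjoint heart-rate ranges (85 ± 1.5 vs 65 ± 1.5 BPM),
and reduced wander (0.1) and noise (0.1) so that the beat wavelet is the
dominant spectral signature of every segment — a property the test suite
asserts. The reduction matters because the canonical filter does *not*
remove wander (see above); without it, both classes' spectrograms would be
dominated by the same low-frequency band. Easy mode exists so that
end-to-end learning checks have a separable-by-construction surface.

What passing tests on synthetic cohorts do **not** show: that the pipeline
reaches any particular accuracy on real BCG recordings. Real signals have
richer beat morphology (H through N waves), artifacts, posture changes and
non-stationary heart rates that the generator does not emulate. Published
full-scale accuracies for this pipeline family (roughly 94–98% under
image-level 10-fold cross-validation on the real 128-subject dataset) are
benchmarks requiring the original recordings and hours of training; they are
out of scope for this package's test suite and are not claimed by it.

## Evaluation protocol

`kfold_split()` supports two granularities:

* `image_level` (default): a random partition of images into k folds of
  near-equal size. This replicates the usual protocol for this pipeline
  family, but note that segments of one subject can then appear in both
  training and test folds, which inflates accuracy on subject-correlated
  data (the per-subject amplitude scale in the synthetic generator makes
  this measurable).
* `subject_level`: whole subjects are assigned to folds, never split. This
  is the leakage-free protocol and is one flag away.

`cross_validate()` trains a fresh model per fold, reports per-fold metrics,
their arithmetic mean (the "average k-fold" convention), and the cumulative
confusion counts over all test folds (each item tested exactly once). The
hypertensive class is the positive class for per-class metrics; because a
single headline precision/recall/F1 convention is ambiguous, per-class
*and* macro-averaged values are always reported, with macro as the headline.
Metrics with zero denominators are reported as 0 with a `degenerate` flag
and a warning. All metrics are percentages printed to two decimals.

## The equal-count experiment

`run_experiment1()` implements the equal-count protocol: every recording is
truncated to its first 50 minutes (shorter recordings are rejected by
name), preprocessed and imaged, giving exactly 100 segments per subject;
with the canonical 61 + 67 cohort this is 12,800 images (6,100 HPT, 6,700
NRT). Artifacts — PNG images, an image manifest CSV, per-fold metrics,
cumulative confusion and a JSON run record carrying a configuration hash —
are written to the output directory so stages can be rerun and audited
independently.

## Problem sizes used by the test suite

The suite runs entirely on synthetic data at sizes chosen to exercise every
contract while staying desk-scale: the accounting check generates the full
61 + 67 cohort at 50 minutes (12,800 images, a few minutes of rendering);
the learning check uses 16 easy-mode subjects at 5 minutes (160 images,
5-fold cross-validation with the desk-scale learning rate, about six
minutes of training); all other tests use cohorts of 2–4 subjects, tiny
classifier configurations (down to 10 × 10 single-channel inputs for the
finite-difference gradient checks) and closed-form or pure-R oracles.

## Known limitations

* The canonical filter's published description and its constants disagree;
  we follow the constants and say so, but users comparing against a
  re-designed 1–50 Hz bandpass will see different low-frequency behavior.
* The spectrogram threshold value is a package default (−40 dB), not a
  published constant; results are sensitive to it.
* The synthetic generator is a test harness, not a validated BCG simulator.
* The full-dataset (all-minutes) experiment of the pipeline family is out
  of scope; only the equal-count protocol is implemented end to end.
* Training is CPU-only double precision; at full scale (12,800 images) a
  10-fold run is hours of compute, which is why the package's own checks
  run at desk scale.
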