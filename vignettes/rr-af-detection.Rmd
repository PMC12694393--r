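---
title: "Detecting atrial fibrillation from RR-interval windows: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting atrial fibrillation from RR-interval windows: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrafnet)
```

## The problem

Atrial fibrillation (AF) is the most common sustained cardiac arrhythmia and
is frequently silent: short paroxysmal episodes escape a spot ECG and are only
caught by long-term monitoring. Its most robust signature in any heart-beat
sensor — ECG, PPG, or anything else that timestamps beats — is an
*irregularly irregular* ventricular response: successive inter-beat (RR)
intervals vary strongly and carry almost no serial correlation, whereas sinus
rhythm (SR) produces regular intervals modulated slowly by respiration.

`rrafnet` implements a complete screening stack that operates on RR intervals
alone: dataset construction from rhythm-annotated recordings, a compact
one-dimensional convolutional network (1D-CNN) classifying fixed-length RR
windows, full-integer INT8 conversion of the trained network for
microcontroller deployment, fold-aggregated evaluation, and a simulator of
the embedded buffer–infer–publish loop.

## From annotated recordings to window datasets

The ingest stage follows the conventions of long-term Holter databases in
WFDB format:

* **Rhythm segments.** Rhythm annotations are point events; each label rules
  until the next label or the end of the record. `"(N"` maps to SR,
  `"(AFIB"` to AF, anything else (flutter, junctional rhythm, unknown
  dialects) to OTHER. Segments are half-open `[start, next_start)`, so a beat
  exactly on a boundary belongs to the later segment.
* **RR extraction.** Beats inside same-rhythm segments are concatenated in
  time order and differenced. Concatenating across an intervening
  other-rhythm segment creates one spurious long "interval" per gap; these
  are removed by the plausibility filter rather than by special-casing, which
  keeps the extraction rule simple and auditable. A strict `within_segment`
  mode is available for users who prefer never to difference across a gap.
* **Plausibility filter.** Only RR values in the closed interval
  [0.25 s, 2 s] — 30 to 240 bpm — are kept. Both endpoints are inclusive:
  the interval notation denotes a closed range, and heart rates of exactly
  240 or 30 bpm are extreme but physiological.
* **Beat symbols.** All annotation symbols in the beat file count as beats.
  Holter beat files are unaudited QRS detections, and the method needs beat
  *times*, not beat *types*; filtering by type would silently change the RR
  distribution.

Windowing cuts each subject-and-rhythm series into `N` consecutive intervals
(`N` = 25, 50 or 100), with non-overlapping windows by default
(stride = `N`). Overlap would multiply highly redundant intra-subject
samples without adding independent information; the stride is still a
parameter for users who want denser sampling.

### Subject-wise folds and balancing

Cross-validation is subject-wise: 15 of the subjects are drawn at random
(seeded) and partitioned into five disjoint test triples; each fold trains on
the remaining 20 subjects. Windows inherit their subject's assignment
wholesale, so no individual's beats can appear on both sides of a split —
the leakage that plagues record-level evaluation of physiological
classifiers. The specific triples are drawn from a recorded seed, and the
same assignment is reused across all window lengths so lengths are
comparable.

Each train table and each test table is balanced separately by randomly
down-sampling the majority class (seeded, order-preserving) to the minority
count. Balancing is pooled within a fold rather than per subject: the target
is equal class totals per table.

## The classifier

The network is deliberately small — it must fit a Cortex-M-class
microcontroller:

```
Input (N x 1)
Conv1D(16 filters, kernel 3) -> BatchNorm -> ReLU -> AvgPool(2) -> Dropout 0.25
Conv1D(32 filters, kernel 3) -> BatchNorm -> ReLU -> AvgPool(2)
Flatten -> Dense(64) -> ReLU -> Dropout 0.1 -> Dense(2) -> Softmax
```

Convolutions use valid padding (the framework default when none is
specified; `"same"` is available as a config option). At `N = 25` the
flattened feature length is 128 and the whole network has 10,210 parameters
(batch-norm moving statistics included); at `N = 100` the chain is
100 → 98 → 49 → 47 → 23 temporal positions, so the dense layer sees
23 × 32 = 736 features.

Training uses Adam (learning rate 0.0009, β₁ = 0.9, β₂ = 0.999),
categorical cross-entropy on one-hot labels, batch size 32, at most 100
epochs, and an internal stratified 80/20 train/validation split. Early
stopping monitors validation loss with patience 5 and `min_delta = 0`, and
the best-validation weights are restored. Inputs are raw RR values in
seconds — no normalization — so the deployed model consumes exactly what the
front-end's beat detector produces.

The implementation is self-contained base-R matrix code: convolutions as
im2col matrix products, analytic backpropagation (verified against finite
differences in the test suite), and seeded initialization, shuffling and
dropout so a fit is exactly reproducible.

### Batch-norm statistics

One numerical choice deserves a note. Frameworks usually track batch-norm
inference statistics as exponential moving averages with momentum 0.99.
With this data the network converges in a handful of epochs, and a moving
average started at variance 1 is then still far from the true activation
variance (~10⁻³ here), which wrecks inference-mode accuracy while training
accuracy looks perfect. `rrafnet` therefore *recalibrates* the statistics
exactly: at each epoch end it recomputes the population mean and variance of
every batch-norm input over the full training set at the current weights.
This costs one extra forward pass per epoch and makes the inference path
exact rather than a lagged estimate.

## INT8 quantization

Post-training full-integer quantization mirrors the standard converter
pipeline:

1. Batch norm is folded into the preceding convolution
   (`W' = W·γ/σ`, `b' = (b−μ)·γ/σ + β`).
2. Weights are quantized per-tensor to symmetric int8
   (scale = max|w|/127, zero-point 0); biases to int32 at the product of the
   weight and input-activation scales.
3. Activation ranges are calibrated on 200 windows drawn (seeded) from the
   training table, giving each tensor an asymmetric int8 scale and
   zero-point. 200 windows is a conventional calibration size: large enough
   to pin the activation ranges, small enough to be instant.
4. Inference simulates the integer pipeline: inputs, weights and every
   intermediate activation pass through their int8 grid (round, clamp to
   [−128, 127], dequantize) before the next layer, reproducing the rounding
   and saturation of a deployed integer interpreter.

Serialized, the int8 artifact stores weights as single bytes and is roughly
a quarter of the float32 file. On balanced synthetic test sets the int8 and
float32 models agree on ≥ 98% of labels, with accuracy differences well
below 0.01 — consistent with integer deployment being essentially free for
this architecture.

## Evaluation conventions

* Accuracy, precision, recall and F1 are computed per class and
  macro-averaged. On balanced tables with a roughly symmetric classifier,
  macro and micro averaging coincide with accuracy, which is why all metrics
  cluster tightly in this setting.
* AUC-ROC is the rank statistic (Wilcoxon form) of the AF probability, with
  midrank tie handling; the test suite cross-checks it against an
  independent brute-force implementation and against `pROC`.
* The decision threshold is the softmax argmax — 0.5 on a binary softmax.
* Cross-fold spread is the sample standard deviation (n − 1 denominator)
  over five folds.
* Per-fold confusion matrices may be summed element-wise into an aggregate:
  because test subjects are disjoint across folds, the sum equals the
  confusion matrix of all pooled test predictions, and the test suite
  asserts that equality.

## The streaming simulator

The embedded signal flow is reproduced as a desk-scale object: RR intervals
and 125 Hz ECG samples accumulate in independent buffers; when the RR buffer
reaches `N`, the model classifies the window, an event is emitted, and both
buffers are cleared atomically. AF events become JSON payloads (stream id,
event time, RR values, the ECG samples spanning exactly the buffered
interval, sampling rate, AF probability) delivered to a pluggable sink — a
directory of files by default, standing in for the device's cellular MQTT
publisher. Sinus events produce nothing and acquisition continues.

Buffers are cleared after *every* inference, not only after sinus windows:
clearing only on SR would make consecutive AF windows overlap-free anyway,
and a uniform rule gives non-overlapping analysis windows whose event count
is exactly `floor(total RR / N)` — an invariant the tests rely on. The
`fifo_period()` and `mean_hr_bpm()` helpers expose the front-end arithmetic
(32 samples at 125 Hz fill every 256 ms; a 768 ms mean RR is 78 bpm) used
when validating timing against a playback bench, and `quantize_to_dac()`
models that bench's 12-bit, 3.3 V DAC (0.805 mV per step).

## The synthetic cohort

Because the clinical database cannot be redistributed, the package ships a
seeded generator that emulates the *one* property the method exploits —
regularity versus irregularity:

* **SR:** mean RR per subject from Uniform(0.7, 1.0) s, a 0.04 s sinusoidal
  modulation with a 4.5 s period standing in for respiratory sinus
  arrhythmia, and 0.02 s Gaussian beat-to-beat noise.
* **AF:** i.i.d. Gamma intervals with subject mean from Uniform(0.55, 0.85) s
  and coefficient of variation 0.22 — in the range reported for AF
  ventricular response — giving high variability and near-zero lag-1
  autocorrelation.
* **Cohort:** 23 subjects, 5,000 beats each, AF occupying ≈ 45% of recorded
  time, matching the class-time structure of an AF-screening Holter
  database. Values are clipped to [0.3, 1.8] s so every generated interval
  survives the plausibility filter; the filter itself is exercised by
  dedicated edge-case fixtures.

These are statistical stand-ins, not physiology: there is no AV-node model,
no ectopy, no f-waves, and the synthetic ECG is a bare train of Gaussian
QRS-like peaks on a slow baseline, sufficient for buffer-alignment and
playback tests only. Consequently, passing the synthetic end-to-end checks
demonstrates that the pipeline is wired correctly and that the network can
learn the irregularity contrast; it does *not* certify clinical performance,
which must be established on real annotated recordings.

## Problem sizes and determinism in the tests

The test suite trains real models, sized to stay desk-scale: module tests
use an 8-subject cohort at window length 25; the end-to-end acceptance test
uses the full default cohort (23 subjects × 5,000 beats) at lengths 25 and
100, training fold 1 of the standard 5-fold geometry. Every stochastic step
— cohort draw, fold draw, balancing, weight initialization, shuffling,
dropout, calibration sampling — derives from explicit seeds, and
byte-identical reruns of dataset export and payload emission are asserted.

## Reproducing the clinical-database analysis

The full reproduction requires the MIT-BIH Atrial Fibrillation Database
(PhysioNet, `afdb`, v1.0.0), which cannot be shipped here. The recipe:

1. Download the 25 records; `afdb_records()` lists them. Records 00735 and
   03665 carry rhythm annotations but no signal/beat data and are excluded,
   leaving 23 — `usable_records(afdb_records())` encodes exactly that rule.
2. Run `read_record_rr(data_dir, record)` per record (beat annotations
   `.qrs`, rhythm annotations `.atr`): with the [0.25, 2] s filter the
   retained segments total roughly 113 h of SR and 91 h of AF.
3. `build_rr_datasets()` + `run_af_pipeline()` with a recorded seed trains
   all lengths and folds. Because the original fold triples were random and
   unpublished, per-fold numbers will differ in the third decimal; test
   accuracy at N = 100 is expected near 0.98 with a spread of ~0.02 across
   folds.

## Known limitations

* The AF generator's i.i.d. Gamma model has no autocorrelation structure at
  all; real AF shows weak short-range dependence. This makes the synthetic
  task somewhat easier than the clinical one.
* Windows shorter than `N` beats at the end of a segment are discarded, so
  very short AF episodes (< N beats) are invisible at that window length —
  an inherent trade-off of the windowing design, not of this implementation.
* The INT8 path quantizes per-tensor; per-channel weight quantization would
  recover a little accuracy on less well-conditioned networks but is
  unnecessary here.
* The simulator models the decision logic and payload contract, not timing,
  power, or the hardware QRS detector.
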