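---
title: "Edge-oriented ECG screening for type 1 diabetes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-oriented ECG screening for type 1 diabetes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgedge)
```

## The problem

Type 1 diabetes leaves measurable traces in the surface ECG: ST-segment
deviation, a flatter and more asymmetric T wave, and QT prolongation. A
wearable device that screens for these patterns must run its entire
analysis chain — denoising, signal-quality gating, feature extraction and
classification — on a microcontroller with a few hundred kilobytes of
flash and under 100 kB of RAM. `ecgedge` implements that chain at desk
scale so every stage can be tested, and pairs it with a synthetic cohort
generator so the statistical behaviour of the pipeline can be studied
without access to clinical recordings.

The stages, in execution order:

1. **Synthetic cohort** — class-conditional single-lead ECG per patient.
2. **Denoising** — 50 Hz IIR notch, fourth-order 0.5–40 Hz Butterworth
   bandpass, both zero-phase.
3. **Quality screen** — per-second skewness/kurtosis thresholds with a
   violation budget per minute.
4. **Dataset building** — 5 s windows (1 s overlap), patient-disjoint
   train/validation/test assignment, class balancing.
5. **Spectrogram features** — 0.7 s frames, 10% stride, 256-point FFT,
   −50 dB noise floor: 60 × 129 = 7740 features per window.
6. **Classifier** — a compact two-conv/two-dense 1D CNN with Swish
   activations, average pooling, dropout; Adam, early stopping.
7. **Deployment analysis** — post-training int8 quantization,
   flash/RAM footprint against an STM32F401-class budget, and a
   figure-of-merit ranking of candidate MCUs.

## The synthetic cohort generator

Each beat is a sum of Gaussian bumps, one per PQRST wave, rendered over an
RR interval drawn per beat from a normal heart-rate distribution
(default 75 ± 3 bpm with ±2% multiplicative jitter). The T wave is built
from two half-Gaussians so its right/left width ratio (`t_asymmetry`) is a
free parameter, an `st_offset` plateau (with 20 ms cosine ramps) spans the
interval between the S-wave end and the T-wave onset, and `qt_scale`
stretches the T latency. The diabetic class differs from the healthy class
by default in exactly the features reported for T1D: ST depression of
0.05 mV, T amplitude reduced to 70%, T width ratio 1.8, T latency × 1.08.
These magnitudes are emulation parameters chosen to be visually plausible,
not clinically calibrated effect sizes; the package's recovery experiments
therefore measure whether the pipeline can detect a *controlled* class
difference, not the clinical effect size.

Contaminants reproduce what wearable acquisition adds: a 0.25 Hz baseline
wander sinusoid (0.1 mV), 50 Hz mains pickup (0.02 mV), white noise
(0.02 mV), and Poisson electrode-motion transients (2/min at 5 mV with
random sign — the amplitude of an electrode pop near the edge of a typical
analog front-end's dynamic range). Under these defaults roughly 85–95% of
minutes pass the quality screen, so the screen exercises both verdicts on
default data.

What the generator does **not** emulate: respiration-coupled amplitude
modulation, heart-rate variability structure beyond white RR jitter,
ectopic beats, electrode drop-outs, or any within-class morphological
diversity beyond RR variation. Consequently the classes are cleanly
separable by design, and a classifier reaching ~100% held-out accuracy on
the default cohort demonstrates pipeline correctness (no leakage, working
features, converging optimizer) — it says nothing about accuracy on
clinical data.

Determinism: every stochastic step derives its seed from
`(seed, patient_index, label)` through an integer hash, so cohorts are
reproducible patient by patient and identical configurations regenerate
bit-identical data.

## Denoising

The notch is an RBJ biquad at 50 Hz. Its quality factor is not dictated by
the method description we follow, so the package fixes Q = 30 (≈1.7 Hz
−3 dB bandwidth): narrow enough to leave the 40 Hz band edge untouched,
wide enough to be robust to small mains drift. The bandpass is a
`signal::butter(4, c(0.5, 40)/(fs/2))` design. Both run forward–backward
(`filtfilt`), a choice made because downstream classification relies on
ST/T timing, which phase distortion would shift; the cost is that the
effective magnitude response is squared, which `filter_response()` accounts
for when reporting analytic gains. The forward–backward edge transient of
the 0.5 Hz highpass decays over tens of seconds, which is why response
measurements in the tests probe the middle of ≥60 s records.

## The quality screen

Skewness `m3/m2^1.5` and Pearson (non-excess) kurtosis `m4/m2^2` are
computed from biased central moments on non-overlapping 1 s subsegments.
A subsegment violates if skewness leaves [0, 5] or kurtosis leaves
[3, 30]; a minute is clean if at most 3 of its 60 subsegments violate.
Three readings are deliberate and documented:

* **Kurtosis is non-excess** — an acceptance range starting exactly at the
  Gaussian value 3 forces this convention.
* **Skewness is signed** — the lower bound 0 implicitly assumes upright
  R waves, so an inverted lead is rejected wholesale. This polarity
  sensitivity is tested; `quality_config(abs_skew = TRUE)` switches to
  `|skewness|` for users with uncertain electrode orientation.
* **A zero-variance subsegment is a violation, not an exception** —
  screening must survive flat-lined wearable data.

Because both statistics are location/scale-invariant, screening commutes
with any positive affine rescaling, so it does not matter whether it runs
before or after normalization; the pipeline screens un-normalized minutes
and z-scores the survivors (per minute, mean 0/sd 1).

## Dataset construction

Windows are 5 s with 1 s overlap (stride 4 s), tiled within each minute
independently — minutes are screened independently, so a window must never
straddle a rejected boundary. One minute yields `floor((60−5)/4)+1 = 14`
windows.

The split assigns **patients**, not windows. Within each class, patients
are taken largest-first into training while that moves the class's window
share closer to the 80% target (always at least one, never all, of a
class's patients). The residual patients alternate test-first between test
and validation, followed by a repair swap that restores class
representation where the pool allows. The procedure is deterministic and
auditable; with fewer than two patients in a class it refuses to run,
since patient-disjointness would be impossible. The validation/test
proportions inside the held-out 20% are a package choice (the split we
follow only fixes the 80/20 boundary and patient disjointness).

Class balancing subsamples majority-class *training* windows, spreading
removals across patients by largest-remainder apportionment with uniform
sampling within a patient, until training class counts differ by at most
one. A patient-level label-shuffling probe (`shuffle_labels_by_patient()`)
is included as the standard leakage control: after shuffling, held-out
accuracy should be at chance.

## Spectrogram features

Frames of 0.7 s advance by 10% of the frame. Both are converted to samples
with **round-half-up**: at 250 Hz the stride is `round(17.5) = 18`
samples, giving exactly 60 frames per 5 s window and 60 × 129 = 7740
features. This rounding is load-bearing — flooring to 17 would give 64
frames and a different feature length — and is the only sample-domain
reading consistent with the published geometry. A 1 ns-scale epsilon
guards the rounding against floating-point dust in `0.7 × 0.1 × 250`.

Each 175-sample frame is zero-padded to 256, transformed with a real FFT
(no taper by default; Hann available), and converted to one-sided power
`(|X_k|/256)^2`. Power maps to dB as `10·log10(p + 1e−12)`, is clipped at
the −50 dB noise floor, and rescales affinely so the floor is 0 and 0 dB
is 1. The exact dB reference of the originating embedded toolchain is not
published; this affine convention is the package's own, chosen so "noise
floor" has a concrete meaning (an all-zero frame maps to exactly 0). The
FFT path is verified against an O(n²) direct DFT oracle in the tests.

## The classifier

Architecture: `conv(8, k=3, swish) → avgpool(2) → conv(16, k=3, swish) →
avgpool(2) → flatten → dropout(0.25) → dense(20, swish) → dense(2,
softmax)`, convolving along the 60-frame time axis with the 129 spectral
bins as channels — each 0.7 s frame spans about one heartbeat, so frames
are the natural sequence elements. The transposed orientation is available
via `cnn_config(time_axis = "bins")` for ablation. Filter counts, kernel
width and dense width are package choices (the published description fixes
the layer types but not their widths); the defaults give 8366 parameters,
consistent with the deployment constraints below.

Training uses Adam at learning rate 5e−4, batch size 128, up to 500
epochs, early stopping on validation loss with patience 50 and best-weight
restoration. The learning rate is read as 5 × 10⁻⁴; the corresponding
printed value in the source description lacks the minus sign, but a
learning rate of 5 × 10⁴ diverges immediately, so the negative exponent is
the only functional reading. Validation loss (not training loss) is
monitored because early stopping exists here to prevent overfitting to the
small patient pool; with no validation set the fit falls back to training
loss. The forward/backward passes are hand-implemented vectorized
matrix arithmetic (im2col-style convolution); analytic gradients are
verified against central finite differences in the tests.

Evaluation reports the confusion matrix, accuracy, support-weighted
precision/recall/F1 and the ROC AUC of the diabetic-class probability
(via pROC). Zero-support classes yield 0 with a flag rather than NaN.

## Quantization and deployment analysis

Weights are quantized per tensor, symmetrically: `scale = max|w|/127`,
zero point 0, values rounded and clamped to ±127 (an all-zero tensor gets
scale 1). Activations are calibrated with min/max ranges over a
representative set and inference emulates int8 by fake-quantizing
(round–clamp–dequantize) weights and the checkpoint activations. Each
weight therefore moves by at most half a quantization step, a bound the
tests check exhaustively.

The footprint model is deliberately analytic: flash = parameter payload
(4 B or 1 B per weight) + 1 kB fixed overhead; RAM = the largest
input+output activation-buffer pair + 2 kB arena overhead. Real toolchains
add runtime structures that this model does not imitate, so the package
asserts only *ordering* (int8 ≈ 4× smaller than float minus overhead
effects) and *budget fit* (512 kB flash / 96 kB RAM, the STM32F401-class
budget), never kilobyte equality with any toolchain report.

MCU candidates are ranked by `FOM = 1/(t_i · f_clk²)` in (ms·MHz²)⁻¹:
latency trades against dynamic power, which scales with the clock squared.
The six bundled profiles (`mcu_profiles()`) are opaque benchmark inputs;
on them the 84 MHz F4 part ranks first despite the slowest inference time.

## Numerical choices and degenerate inputs

* Round-half-up (with a 1e−9 guard) for all sample-domain geometry.
* `log(p + 1e−12)` guards the dB conversion; softmax subtracts the row
  maximum; cross-entropy adds 1e−12 inside the log.
* Early-stopping improvements must exceed 1e−6 to reset patience.
* Ties in patient assignment and FOM ranking break by identifier, so both
  are fully deterministic.
* Degenerate inputs have defined behaviour: flat segments are screening
  violations but normalization errors; single-class training sets,
  overlapping train/validation patients, empty calibration sets and
  non-positive FOM inputs all raise informative errors; single-class test
  sets report `NA` AUC.

## Problem sizes used by the checks

The bundled verification experiments run the full pipeline on the default
cohort — 8 healthy + 8 diabetic patients, 10 minutes each at 250 Hz
(~2.4 M samples, ~2200 windows) — for three seeds, and the chance-level
shuffle control on an 8 + 8 × 2-minute cohort with a 50% training share
(so that eight patients are held out, keeping the patient-block variance
of the chance estimate small). These sizes were chosen as the smallest
cohorts at which patient-level effects (block variance, split repair,
balancing) are all exercised.

## Known limitations

* The synthetic classes are separable by construction; synthetic recovery
  accuracy does not transfer to clinical performance.
* The quality thresholds were adopted verbatim from their source; they
  assume upright R waves and 250 Hz-class sampling rates.
* The int8 emulation models per-tensor affine quantization only — no
  per-channel scales, no integer-only rescaling arithmetic.
* Footprint estimates exclude toolchain runtime overhead by design.
* The WFDB adapter reads the text header plus plain-text sample files
  only, not binary signal formats.
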