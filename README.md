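# ecgedge

Desk-scale R implementation of an edge-AI pipeline that screens
single-lead ECG for type 1 diabetes. The package is aimed at biosignal /
TinyML researchers who want to study the *statistical* behaviour of such a
pipeline — signal-quality gating, patient-independent evaluation,
quantization cost — without clinical data or embedded hardware: a
class-conditional synthetic ECG cohort generator stands in for a clinical
cohort, and an analytic memory model stands in for an embedded toolchain.

## What it implements

ECG changes associated with type 1 diabetes include ST-segment deviation
and a flatter, asymmetric T wave. The pipeline detects them as follows:

1. **Synthetic cohort** — per-patient single-lead ECG built from
   Gaussian-bump PQRST beats; the diabetic class differs in ST offset, T
   amplitude, T asymmetry and T latency. Contaminants: baseline wander,
   50 Hz mains, electrode-motion spikes, white noise.
2. **Denoising** — zero-phase 50 Hz IIR notch (Q = 30) and fourth-order
   0.5–40 Hz Butterworth bandpass.
3. **Quality screen** — per-second skewness/kurtosis on each 1-minute
   segment; a second *violates* if skewness ∉ [0, 5] or (non-excess)
   kurtosis ∉ [3, 30]; a minute is clean if ≤ 3 of its 60 seconds violate.
4. **Dataset** — z-scored minutes cut into 5 s windows (1 s overlap);
   patients (never windows) assigned to train/validation/test near an
   80/20 split; majority-class training windows subsampled to balance.
5. **Features** — short-time spectrogram per window: 0.7 s frames, 10%
   stride (round-half-up: 18 samples at 250 Hz), 256-point FFT, −50 dB
   noise floor, rescaled to [0, 1] — exactly 60 frames × 129 bins = 7740
   features.
6. **Classifier** — compact 1D CNN (two Swish conv layers with average
   pooling, dropout, dense-20, 2-way softmax; 8366 parameters), convolving
   along the frame axis with spectral bins as channels. Trained with Adam
   (lr 5e−4, batch 128, ≤ 500 epochs, early stopping patience 50 on
   validation loss). Forward/backward passes are hand-implemented
   vectorized R, verified against finite differences.
7. **Deployment** — post-training symmetric int8 quantization with
   min/max activation calibration and emulated-int8 inference; analytic
   flash/RAM footprints against the STM32F401 budget (512 kB / 96 kB);
   MCU ranking by the figure of merit `FOM = 1/(t_i · f_clk²)`.

## Worked example

```r
library(ecgedge)

cfg <- pipeline_config(
  cohort = cohort_config(n_patients_per_class = 8, minutes_per_patient = 2),
  seed = 42)
report <- run_ecg_pipeline(cfg)
print(report)
```

```
=== ECG screening pipeline run (seed 42 ) ===
cohort: 16 records
screening: 29/32 minutes clean
windows: 406 (train share 0.828)

float32 model:
Evaluation on 42 windows
          predicted
true       diabetic healthy
  diabetic       14       0
  healthy         0      28
accuracy 1.0000  weighted P 1.0000  R 1.0000  F1 1.0000  AUC 1.0000
flash 33.7 kB / 512 kB (fits)   ram 34.1 kB / 96 kB (fits)

int8 model:
Evaluation on 42 windows
          predicted
true       diabetic healthy
  diabetic       14       0
  healthy         0      28
accuracy 1.0000  weighted P 1.0000  R 1.0000  F1 1.0000  AUC 1.0000
flash 9.2 kB / 512 kB (fits)   ram 10.0 kB / 96 kB (fits)
accuracy drop after quantization: 0.0000

MCU ranking:
    name f_clk_mhz t_i_ms       fom rank
 STM32F4        84  52.80 2.684e-06    1
 B-U5U5I       160  23.90 1.634e-06    2
 STM32F7       216  13.85 1.548e-06    3
 STM32G4       170  27.35 1.265e-06    4
 STM32H5       250  15.63 1.024e-06    5
 STM32H7       480   6.28 6.911e-07    6
```

Reading the output: 3 of 32 minutes were rejected by the quality screen
(electrode-motion artifacts); the surviving minutes produced 406 windows,
of which the windows of two held-out patients (one per class) form the
test set. The classifier separates the two synthetic morphologies
perfectly — expected, since the synthetic class difference is controlled
and clean (see the vignette for why this validates the pipeline rather
than predicting clinical accuracy). Quantization costs no accuracy here
and shrinks flash ~3.7× (9.2 kB vs 33.7 kB; the fixed overhead keeps it
under 4×). The 84 MHz STM32F4 wins the FOM ranking despite the slowest
inference time, because power grows with the square of the clock.

```r
print(summary(report$model))
#             layer  output parameters
#     conv1 (swish)  60 x 8       3104
#          avgpool1  30 x 8          0
#     conv2 (swish) 30 x 16        400
#          avgpool2 15 x 16          0
#   flatten+dropout     240          0
#    dense1 (swish)      20       4820
#  dense2 (softmax)       2         42
# total parameters: 8366; best epoch 210 of 260
```

A thin CLI wraps the same functions (installed under `exec/`):

```sh
ecg-t1d generate --out cohort_dir --patients 8 --minutes 10 --seed 1
ecg-t1d screen --in cohort_dir --report screen_report.csv
ecg-t1d run --seed 1
ecg-t1d rank-mcu
```

## Package layout

- `R/cohort.R`, `R/morphology.R` — synthetic cohort generator
- `R/preprocess.R` — filters, segmentation, normalization
- `R/quality.R` — skewness/kurtosis screen
- `R/dataset.R` — windowing, patient-disjoint split, balancing, shuffle probe
- `R/spectrogram.R` — framing, FFT power, noise-floor scaling
- `R/cnn.R`, `R/metrics.R` — the classifier (fit / predict / summary /
  plot) and evaluation metrics
- `R/quantize.R`, `R/fom.R` — int8 quantization, footprints, MCU ranking
- `R/pipeline.R` — end-to-end orchestration (`run_ecg_pipeline()`)
- `vignettes/ecg-t1d-screening.Rmd` — methods, design decisions, limitations
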