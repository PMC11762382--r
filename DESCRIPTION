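Package: ecgedge
Title: Edge-Oriented ECG Screening Pipeline for Type 1 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale implementation of an edge-AI screening pipeline that
    classifies single-lead ECG as healthy or type 1 diabetic. Provides a
    class-conditional synthetic ECG cohort generator (Gaussian-bump PQRST
    morphology with ST deviation and asymmetric T waves, plus realistic
    contaminants), IIR notch and Butterworth bandpass denoising, a
    skewness/kurtosis signal-quality screen, patient-independent dataset
    partitioning with class balancing, short-time spectrogram feature
    extraction, a compact 1D convolutional neural network classifier trained
    with Adam and early stopping, post-training int8 quantization with
    flash/RAM footprint estimation against a microcontroller budget, and a
    figure-of-merit ranking of candidate microcontrollers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pROC,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
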