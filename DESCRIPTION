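Package: ppg2abp
Title: Continuous Blood Pressure Waveforms from Photoplethysmography by
    LSTM Signal-to-Signal Translation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Cuff-less continuous blood pressure estimation by translating
    photoplethysmography (PPG) waveforms into arterial blood pressure (ABP)
    waveforms.  Provides a synthetic paired-waveform generator with known
    ground truth, waveform input/output and segmentation, preprocessing
    (third-order Butterworth bandpass denoising, z-score normalization,
    cross-correlation phase alignment, derivative feature channels),
    four-rule signal quality control, a two-stage transfer-learned LSTM
    autoencoder (PPG reconstruction followed by frozen-encoder PPG-to-ABP
    translation), and evaluation of systolic/diastolic errors against the
    British Hypertension Society grading and the AAMI criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    digest,
    graphics,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
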