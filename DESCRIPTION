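Package: emgonset
Title: Detection of Muscle Activation Onset and Offset from Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation, detection and evaluation of muscle-activation timing
    in surface electromyography (sEMG). Generates ground-truth-labeled
    synthetic sEMG as band-limited bursts under a truncated Gaussian envelope
    at controlled signal-to-noise ratio; extracts linear-envelope, RMS and
    Morse-wavelet scalogram features over sliding sample windows; trains a
    shallow neural network (or a linear SVM) to classify each sample as
    active or silent; converts per-sample predictions into onset/offset
    events with run-length cleaning; and scores detections by tolerance
    matching (precision, recall, F1), mean absolute timing error and bias,
    stratified by SNR and burst shape. A classical double-threshold
    statistical detector is included as a baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
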