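Package: fnirseffort
Title: Listening-Effort fNIRS Analysis: Preprocessing, Simulation and
    Multilevel Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis of prefrontal functional near-infrared
    spectroscopy (fNIRS) recordings from speech-in-noise listening-effort
    experiments. Implements a continuous-wave preprocessing stream
    (step-artifact removal, scalp-coupling-index channel rejection,
    optical density, wavelet motion correction, modified Beer-Lambert
    conversion, band-pass filtering, short-separation channel regression),
    event-related averaging of cerebral oxygen exchange (HbDiff) by
    prefrontal subregion, an adaptive SNR-50 staircase with a simulated
    listener, rationalized-arcsine behavioural statistics, and nested
    multilevel-model inference with likelihood-ratio comparison and
    simple-slopes analysis. A synthetic-data generator with known
    hemodynamic ground truth drives validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    rhdf5,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
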