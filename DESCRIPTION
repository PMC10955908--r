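Package: lfpsleep
Title: Sleep-Stage Classification from Subthalamic Local Field Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing, classification and attribution tools for
    sleep staging from deep-brain-stimulation local field potential (LFP)
    recordings. Includes a synthetic generator of multi-contact subthalamic LFP
    with stage-dependent spectral content and Parkinsonian stage prevalences;
    spectral band-power feature extraction (bipolar referencing, Hamming-window
    spectrograms, per-subject normalization, Nyquist-aware downsampling);
    feedforward softmax classifiers of two capacities trained with
    inverse-frequency-weighted cross-entropy; exact Shapley attribution of
    frequency bands to class probabilities by power-set enumeration; and an
    evaluation suite (confusion summaries, per-subject error, sub-band and
    sampling-rate ablations, leave-one-subject-out validation).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    signal,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
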