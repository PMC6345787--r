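Package: dfcstates
Title: EEG-Informed Dynamic Functional Connectivity State Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identification and characterization of dynamic functional
    connectivity (dFC) states from simultaneous EEG-fMRI recordings.
    Computes an EEG phase synchronization index (PSI) via Morlet wavelet
    decomposition, estimates sliding-window dFC from ROI-averaged BOLD time
    series, factorizes the dFC matrix into states using k-means clustering
    with l1 distance, PCA, and l0- or l1-regularized dictionary learning,
    selects the model by correlation of state weight time-courses with the
    EEG-PSI metric, assesses state significance with phase-randomized
    surrogates, and characterizes epilepsy-related states against an
    HRF-GLM-derived network.  Includes a seeded synthetic-data generator
    with planted ground-truth states for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
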