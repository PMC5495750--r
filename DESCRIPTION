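Package: templight
Title: Searchlight Representational Similarity Analysis of Preparatory
    Target Templates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end representational similarity analysis (RSA) of
    preparatory target templates in visual search fMRI designs.  Generates
    counterbalanced, jitter-scheduled cueing experiments with Gabor
    conjunction stimuli, builds dimension-weighted and HMAX C1
    stimulus-similarity model dissimilarity matrices, simulates
    multi-subject 4D BOLD data with plantable representational structure,
    estimates condition-wise response amplitudes with an event-related
    double-gamma HRF model, runs spherical searchlight RSA, and performs
    group inference with a bootstrapped permutation cluster-size
    familywise-error procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
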