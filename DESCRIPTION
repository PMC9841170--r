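Package: ldsbeeg
Title: EEG Markers of Brain Lymphatic-Drainage Activation: Spectra, Coherence,
    Cross-Recurrence, Wavelet Patterns and a Neural-Network Similarity Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for discriminating rodent brain states linked to
    activation of the brain's lymphatic drainage (wakefulness, NREM-dominated
    sleep, and sound-induced blood-brain-barrier opening) from two-lead EEG plus
    EMG recordings. Implements Welch power spectral density with Bartlett
    tapering and Daniell frequency-domain smoothing, magnitude coherence,
    band power, rule-based 10-s-epoch sleep staging, Takens delay embedding with
    autocorrelation delay and false-nearest-neighbour dimension selection,
    cross-recurrence analysis with diagonal-line indices (RR, DET, L, MDL, ENTR),
    Morlet continuous-wavelet-transform skeleton extraction and oscillatory
    pattern durations, a signal-to-noise-ratio feature multilayer perceptron
    with the Cs similarity statistic under a leave-one-subject training
    protocol, amplitude-adjusted Fourier transform (AAFT) surrogate significance
    testing, Mann-Whitney-Wilcoxon group contrasts, and a seeded synthetic
    three-state EEG/EMG cohort generator with recorded ground truth so every
    stage is verifiable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
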