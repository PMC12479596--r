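Package: microstatr
Title: Resting-State EEG Microstate Analysis with Synthetic Ground Truth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for resting-state EEG microstate analysis: polarity-invariant
    modified k-means extraction of template topographies at global field power
    peaks, two-level (subject then group) clustering with map merging and a
    multi-criterion choice of the number of maps, back-fitting with temporal
    smoothing, microstate temporal parameters (global explained variance, mean
    duration, time coverage, occurrence), Markov-chain transition analysis with
    observed/expected normalization, topographic permutation tests (TANOVA),
    effective-number-of-tests Sidak correction, bootstrap correlations, and
    Hanning-taper band-power spectra. Includes a semi-Markov synthetic EEG
    generator with planted microstate structure so every stage of the pipeline
    can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
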