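Package: megnet
Title: Spatial-Summary Convolutional Networks for Single-Trial MEG/EEG
    Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Decoding of single trials of multichannel electrophysiology
    (MEG/EEG) with neural networks that factorize channel mixing and
    temporal filtering. Implements the spatial-summary convolutional
    network (SCNN), an attention-augmented recurrent variant (Ra-SCNN),
    cropped-trial data augmentation, subject-wise cross-validated
    training, transfer evaluation with a frozen feature extractor, and an
    interpretation suite: activation maximization under a 1/f prior,
    channel topography maps, activation spectrograms, obscuring profiles
    and baseline-recording controls. A windowed spectral/statistical
    feature pipeline with correlation-based selection is included for
    comparison against feature-based classification, as is a synthetic
    trial generator with 1/f background spectra and class-dependent
    band-limited effects for development and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
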