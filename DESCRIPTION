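Package: snoreacoustics
Title: Snoring Sound Classification and Acoustic Group Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying snoring versus non-snoring sound segments
    and for comparing snore acoustics between patient groups. Implements four
    acoustic feature representations (Mel spectrogram, MFCC, constant-Q
    spectrogram, CENS chroma) with an adaptive filter-bank enhancement that
    boosts high-energy filter channels per frame; an improved ConvNeXt-Tiny
    style classifier with alterable-kernel (offset-sampled) convolution,
    channel-spatial attention (CBAM) and convolutional-modulation blocks,
    including exact parameter accounting for reference backbones; a
    patient-level evaluation harness (confusion-matrix metrics, patient
    bootstrap confidence intervals, majority voting, 5-fold patient
    cross-validation, SNR-controlled noise mixing); and a low-frequency
    energy-ratio statistics pipeline with Mann-Whitney group comparisons and
    exclusion sensitivity analysis. A synthetic snore-audio generator produces
    labeled cohorts with configurable group-level acoustic differences so the
    whole pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
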