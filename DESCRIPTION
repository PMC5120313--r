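Package: nvfs
Title: Nested Variable Frame Size Speech Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments speech into unequal frames at the phase-quadrant
    boundaries of slow oscillations extracted from the Hilbert envelope of
    the waveform. A primary (theta, 4-10 Hz) envelope oscillation defines
    coarse frames; frames whose energy falls inside a relative threshold
    window are re-segmented with a secondary (low-gamma, 25-35 Hz)
    oscillation, yielding a nested oscillatory segmentation reference that
    places short frames on consonant bursts and transitions and long frames
    on steady vowels. Includes the cochlea-scaled spectral entropy (CSE)
    segmentation metric over 33 ERB channels, fixed/random/reversed baseline
    segmenters, variable-frame MFCC features, a left-to-right Gaussian-mixture
    HMM recognition harness with SNR-controlled noise mixing, and a synthetic
    consonant-vowel syllable generator so the whole pipeline runs without
    external speech corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
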