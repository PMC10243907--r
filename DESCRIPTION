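Package: insync
Title: Wavelet-Coherence Analysis of Interpersonal Neural Synchronization
    for fNIRS Hyperscanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing inter-brain coupling in functional
    near-infrared spectroscopy (fNIRS) hyperscanning experiments.
    Implements Morlet wavelet transform coherence (WTC) with scale- and
    time-smoothing, Fisher-z interpersonal neural synchronization (INS)
    with rest-baseline subtraction, time-lagged coupling over a seconds
    lag grid, permutation-based selection of frequency bands of
    interest, paired condition contrasts with Bonferroni correction,
    and pseudo-dyad permutation validation.  Includes motion-artifact
    correction by temporal derivative distribution repair (TDDR) and a
    fully parameterised generator of synthetic dyad recordings (1/f
    background, physiological oscillations, motion artifacts, and
    band-limited, time-lagged inter-brain coupling) with ground truth,
    so every stage of the pipeline is testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
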