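Package: flickerstates
Title: EEG Microstate and Complexity Analysis Under Rhythmic Visual Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multichannel scalp EEG recorded at rest and
    under visual flicker stimulation. Implements common-average referencing,
    zero-phase filtering, multitaper power spectral density with absolute and
    relative band power by scalp region, polarity-invariant modified k-means
    microstate segmentation with back-fitting and short-segment rejection,
    microstate coverage/duration/occurrence metrics, Markov transition
    matrices with and without self-transitions, Lempel-Ziv (LZ76) complexity
    of microstate label sequences, and group statistics (one-way ANOVA,
    two-stage Benjamini-Krieger-Yekutieli FDR, Tukey HSD). Ships a synthetic
    EEG generator that plants ground-truth microstate structure and 40 Hz
    steady-state visually evoked responses so every stage of the pipeline can
    be validated against a known oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
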