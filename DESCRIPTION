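Package: icnet
Title: Alpha-Band Imaginary-Coherence Networks and Divergent-Thinking Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for linking stimulation-induced changes in alpha-band
    (8-12 Hz) imaginary-coherence networks to changes in verbal
    divergent-thinking performance. Computes scout-level imaginary coherence
    from Welch cross-spectra, weighted node degree with z-normalisation and
    frontal-region averaging, pre/post by condition change scores,
    permutation-based paired edge statistics with false-discovery-rate
    correction, and backward-elimination brain-behavior regressions.
    Includes behavioral scoring of alternative-uses and associative-fluency
    responses (fluency, flexibility via embedding distances, originality via
    statistical infrequency) and a synthetic coupled-oscillator generator
    that produces scout-level recordings and verbal-response datasets with
    known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
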