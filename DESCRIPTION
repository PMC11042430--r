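Package: cfcdetect
Title: Absence-Seizure Detection from Power-to-Power Cross-Frequency
    Coupling of Scalp EEG with a Stacked Sparse Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects absence-seizure (spike-and-wave discharge) activity in
    multichannel scalp EEG. Segments are re-referenced to the common average,
    notch filtered, projected onto independent components, and cleaned by a
    probability-based component-rejection rule. For each retained component a
    power-to-power cross-frequency coupling (comodulogram) matrix is computed
    over a log-spaced 2-120 Hz grid from short-time log-power spectra; the
    per-segment average matrix is classified as seizure versus background by
    a stacked sparse autoencoder (two greedily trained sparse encoder stages
    plus a softmax head) implemented from scratch with deterministic
    full-batch optimisation. A synthetic spike-wave EEG generator reproduces
    the spectral and harmonic-comodulation phenomenology of absence seizures
    so the whole pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
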