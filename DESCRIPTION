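Package: ssvepdecode
Title: Decoding Toolbox for SSVEP Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Target-identification methods for steady-state visual evoked
    potential (SSVEP) brain-computer interfaces. Implements a multi-feature
    canonical correlation analysis (CCA) classifier built from an exhaustive
    bank of canonical-variable correlation features with subject-independent
    forward selection, and its weighted ensemble extension fitted by a genetic
    algorithm, alongside the standard reference decoders (standard CCA,
    extended CCA, task-related component analysis in basic and ensemble form).
    Includes zero-phase Chebyshev Type II preprocessing, filter-bank sub-band
    fusion, leave-one-block-out and subject-level k-fold cross-validation,
    information transfer rate metrics, and a synthetic generator for
    joint frequency-phase modulated (JFPM) SSVEP datasets so the whole
    pipeline can be exercised without benchmark recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
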