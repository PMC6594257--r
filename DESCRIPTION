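Package: netdyn
Title: Functional Network Dynamics of Multichannel Rodent EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multichannel hippocampal and cortical
    EEG/LFP recordings: Welch relative power spectra, theta-gamma
    phase-amplitude coupling (modulation index comodulograms, intrasite and
    intersite), magnitude-squared coherence, partial coherence via spectral
    matrix minors, global coherent-network efficiency, and generalized
    (extended) partial directed coherence from multivariate autoregressive
    models. Includes a synthetic two-group cohort generator with known
    ground truth for every metric, group-comparison statistics (two-sample
    t-tests, 95 percent confidence intervals, Watson-Williams circular
    test), and EDF/CSV recording input and output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
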