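Package: conflictMVPA
Title: Simulation and Multivariate Decoding of Conflict-Related EEG Theta Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate epoched multichannel EEG with injected oscillatory
    class effects and realistic artifacts, preprocess it (filtering, re-referencing,
    two-pass amplitude-based artifact rejection, trial selection and class
    balancing), decompose single trials into time-frequency power with Hann-tapered
    complex wavelets, decode trial classes per time-frequency bin with
    cross-validated shrinkage linear discriminant analysis scored by AUC, and draw
    group-level inferences with one-sided t-maps, cluster-based permutation
    correction, region-of-interest summaries including JZS Bayes factors,
    repeated-measures ANOVAs with Greenhouse-Geisser correction, ANCOVA, signal
    detection d-prime, and activation-pattern topographies. Includes an end-to-end
    pipeline runner with deterministic seed provenance and analysis drivers that
    reproduce the full inference chain on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    igraph,
    car,
    optparse
Config/testthat/edition: 3
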