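Package: cotransmitr
Title: Neurotransmitter Phenotype Classification and Co-Expression
    Counting for Single-Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies single cells into neurotransmitter phenotypes from
    species-specific marker-gene panels and quantifies dual- and
    multi-transmitter co-expression as combination-lattice counts (the
    quantity shown in UpSet plots). Provides sparse count-matrix readers,
    log-normalization with a fixed scale factor, a boolean gating-rule
    language for neuron selection, exact inclusive/exclusive subset-count
    (Moebius) transforms, descriptive cross-dataset comparison, and a
    negative-binomial synthetic-data generator with planted co-expression
    structure for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
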