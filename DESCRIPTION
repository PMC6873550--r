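Package: smilescape
Title: SMILES-Variant Generative Models and Chemical-Space Coverage Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for training and evaluating SMILES-based recurrent
    generative models of small molecules. Provides canonical, restricted- and
    unrestricted-randomized SMILES writers with per-epoch data augmentation,
    a rule-exact SMILES tokenizer, DeepSMILES syntax conversion, a stacked
    LSTM/GRU language model trained by teacher forcing with gradient-norm
    clipping, and the chemical-space coverage benchmark built on the
    Uniformity-Completeness Jensen-Shannon divergence (UC-JSD), the
    ideal-sampler recovery expectation phi(k), and the completeness,
    uniformity, closedness and UCC scores. A fully enumerable synthetic
    chemical space with exclusion filters makes every component testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
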