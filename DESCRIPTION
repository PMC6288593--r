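Package: adex
Title: Adverse Drug Event Entity and Relation Extraction from Clinical Narrative
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end extraction of adverse drug events (ADEs) and related
    information from clinical narrative. Implements a recurrent sequence
    labeler with character-level convolution features and a linear-chain CRF
    output layer for nine clinical entity types, an attention-pooled
    recurrent relation classifier for seven relation types (including
    inter-sentence pairs), and three multi-task couplings between the two
    submodels (hard parameter sharing, L2-regularised soft sharing, and task
    relation learning). Ships a standoff-annotation reader/writer, a
    deterministic tokenizer and rule-based part-of-speech tagger, BMES label
    coding, a seeded synthetic-corpus generator emulating a MADE-style
    annotation schema, and micro-averaged end-to-end evaluation. The neural
    layers are built on a small reverse-mode automatic-differentiation tape
    included in the package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
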